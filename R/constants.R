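#' Fixed model constants for a tracer-drug pair
#'
#' Bundles the constants that are held fixed during 5p/7p estimation: the
#' tracer dissociation constant and rate, the drug's plasma and tissue free
#' fractions, dissociation constant and rate, and the blood volume fraction.
#' Defaults are the literature/measured values used for the SV2A tracer with
#' levetiracetam (LEV) or brivaracetam (BRV): tracer KD = 3.4 nmol/L, vB =
#' 0.05, and per drug (fPD, KDD, fNDD, koffD) = (0.90, 21000 nmol/L, 1.0,
#' 4.9/min) for LEV and (0.83, 2000 nmol/L, 0.88, 5.9/min) for BRV. The
#' tracer dissociation rate defaults to 4.9/min for both drugs.
#'
#' @param drug `"LEV"` or `"BRV"`; selects the drug-specific defaults.
#' @param KD Tracer dissociation constant, nmol/L.
#' @param koff Tracer dissociation rate, 1/min.
#' @param vB Blood volume fraction in `[0, 0.2]`.
#' @param fPD Drug plasma free fraction in (0, 1].
#' @param KDD Drug dissociation constant, nmol/L.
#' @param fNDD Drug free fraction in the non-displaceable compartment, (0, 1].
#' @param koffD Drug dissociation rate, 1/min.
#' @return An object of class `fixed_constants` (a named list).
#' @examples
#' fixed_constants("BRV")
#' fixed_constants("LEV", KD = 6.8)  # doubled tracer affinity constant
#' @export
fixed_constants <- function(drug = c("LEV", "BRV"),
                            KD = 3.4, koff = 4.9, vB = 0.05,
                            fPD = NULL, KDD = NULL, fNDD = NULL,
                            koffD = NULL) {
  drug <- match.arg(drug)
  defaults <- switch(drug,
    LEV = list(fPD = 0.90, KDD = 21000, fNDD = 1.0,  koffD = 4.9),
    BRV = list(fPD = 0.83, KDD = 2000,  fNDD = 0.88, koffD = 5.9))
  if (is.null(fPD))   fPD   <- defaults$fPD
  if (is.null(KDD))   KDD   <- defaults$KDD
  if (is.null(fNDD))  fNDD  <- defaults$fNDD
  if (is.null(koffD)) koffD <- defaults$koffD

  x <- list(drug = drug, KD = KD, koff = koff, vB = vB,
            fPD = fPD, KDD = KDD, fNDD = fNDD, koffD = koffD)
  validate_fixed_constants(x)
  structure(x, class = "fixed_constants")
}

validate_fixed_constants <- function(x) {
  num <- c("KD", "koff", "fPD", "KDD", "fNDD", "koffD")
  for (nm in num) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("fixed constant '%s' must be a single positive number", nm))
  }
  if (x$fPD > 1)  stop("fPD must be <= 1")
  if (x$fNDD > 1) stop("fNDD must be <= 1")
  if (!is.numeric(x$vB) || x$vB < 0 || x$vB > 0.2)
    stop("vB (blood volume fraction) must lie in [0, 0.2]")
  invisible(x)
}

#' @export
print.fixed_constants <- function(x, ...) {
  cat(sprintf("Fixed constants (%s):\n", x$drug))
  cat(sprintf("  tracer: KD = %.3g nmol/L, koff = %.3g /min, vB = %.3g\n",
              x$KD, x$koff, x$vB))
  cat(sprintf("  drug:   fPD = %.3g, KDD = %.4g nmol/L, fNDD = %.3g, koffD = %.3g /min\n",
              x$fPD, x$KDD, x$fNDD, x$koffD))
  invisible(x)
}
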