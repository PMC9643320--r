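#' Kinetic parameter set for the competition model
#'
#' The estimable parameters of the joint displacement + post-dose model:
#' tracer delivery `K1` and plasma free fraction `fP` for each scan, the
#' tracer distribution volume `VT` and tissue free fraction `fND`, and the
#' drug delivery rate `K1D`, together with a [fixed_constants()] set.
#' `K1` and `K1D` are stored in mL plasma/min/cm^3 tissue; `K1D` is
#' conventionally reported multiplied by 1000 (uL/cm^3/min), see
#' [k1d_to_uL()].
#'
#' @param K1_disp,K1_post Tracer plasma-to-tissue rate per scan,
#'   mL/min/cm^3.
#' @param VT Tracer distribution volume, mL/cm^3.
#' @param fND Tracer free fraction in the non-displaceable compartment,
#'   (0, 1].
#' @param K1D Drug plasma-to-tissue rate, mL/min/cm^3.
#' @param fP_disp,fP_post Tracer plasma free fraction per scan, (0, 1].
#' @param constants A [fixed_constants()] object.
#' @return Object of class `kinetic_parameters`.
#' @examples
#' kinetic_parameters(K1_disp = 0.47, K1_post = 0.49, VT = 21.6,
#'                    fND = 0.076, K1D = 5.2e-3,
#'                    constants = fixed_constants("LEV"))
#' @export
kinetic_parameters <- function(K1_disp, K1_post, VT, fND, K1D,
                               fP_disp = 0.30, fP_post = 0.30,
                               constants = fixed_constants("LEV")) {
  x <- list(K1_disp = K1_disp, K1_post = K1_post, VT = VT, fND = fND,
            K1D = K1D, fP_disp = fP_disp, fP_post = fP_post,
            constants = constants)
  validate_kinetic_parameters(x)
  structure(x, class = "kinetic_parameters")
}

validate_kinetic_parameters <- function(x) {
  num <- c("K1_disp", "K1_post", "VT", "fND", "K1D", "fP_disp", "fP_post")
  for (nm in num) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single positive number", nm))
  }
  if (x$fND > 1) stop("fND must be <= 1")
  if (x$fP_disp > 1 || x$fP_post > 1) stop("fP must be <= 1")
  validate_fixed_constants(x$constants)
  for (scan in c("disp", "post")) {
    fP <- x[[paste0("fP_", scan)]]
    if (x$VT * x$fND / fP < 1)
      stop(sprintf(
        paste0("VT * fND / fP = %.4g * %.4g / %.4g = %.4g < 1 (%s scan): ",
               "the specific binding capacity would be negative"),
        x$VT, x$fND, fP, x$VT * x$fND / fP, scan))
  }
  invisible(x)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters:\n")
  cat(sprintf("  K1 (disp/post) = %.4g / %.4g mL/min/cm^3, fP = %.3g / %.3g\n",
              x$K1_disp, x$K1_post, x$fP_disp, x$fP_post))
  cat(sprintf("  VT = %.4g mL/cm^3, fND = %.4g\n", x$VT, x$fND))
  cat(sprintf("  K1D = %.4g uL/cm^3/min (%s)\n",
              k1d_to_uL(x$K1D), x$constants$drug))
  invisible(x)
}

#' Convert drug delivery rate between internal and reported units
#'
#' `K1D` is stored in mL plasma/min/cm^3 tissue and reported in
#' uL/cm^3/min (a factor of 1000).
#'
#' @param K1D Rate in mL/cm^3/min.
#' @param K1D_uL Rate in uL/cm^3/min.
#' @return The converted value.
#' @export
k1d_to_uL <- function(K1D) 1000 * K1D

#' @rdname k1d_to_uL
#' @export
k1d_from_uL <- function(K1D_uL) K1D_uL / 1000

#' Derive mechanistic (secondary) parameters
#'
#' Maps the estimable parameterization (`K1`, `fP`, `VT`, `fND`, `K1D` plus
#' fixed constants) back to the mechanistic rate constants of the underlying
#' bimolecular binding model: tissue-to-plasma rates `k2 = K1 fND / fP` and
#' `k2D = K1D fNDD / fPD`, the total target concentration
#' `Bmax = KD (VT fND / fP - 1) / fND`, and the association rates
#' `kon = koff / KD`, `konD = koffD / KDD`.
#'
#' @param params A [kinetic_parameters()] object.
#' @param scan `"disp"` or `"post"`: which scan's `K1`/`fP` to use for the
#'   scan-dependent quantities.
#' @return A list with elements `k2`, `k2D`, `Bmax` (nmol/L), `kon`, `konD`
#'   (1/(nmol/L)/min) and `bterm = VT fND / fP - 1` (dimensionless).
#' @examples
#' p <- kinetic_parameters(0.47, 0.49, VT = 20, fND = 0.1, K1D = 5e-3,
#'                         fP_disp = 0.4, fP_post = 0.4,
#'                         constants = fixed_constants("LEV"))
#' derive_secondary(p)$Bmax  # 3.4 * (20 * 0.25 - 1) / 0.1 = 136 nmol/L
#' @export
derive_secondary <- function(params, scan = c("disp", "post")) {
  stopifnot(inherits(params, "kinetic_parameters"))
  scan <- match.arg(scan)
  validate_kinetic_parameters(params)
  k  <- params$constants
  K1 <- params[[paste0("K1_", scan)]]
  fP <- params[[paste0("fP_", scan)]]
  bterm <- params$VT * params$fND / fP - 1
  list(
    k2    = K1 * params$fND / fP,
    k2D   = params$K1D * k$fNDD / k$fPD,
    Bmax  = k$KD * bterm / params$fND,
    kon   = k$koff / k$KD,
    konD  = k$koffD / k$KDD,
    bterm = bterm
  )
}

#' Solver-facing parameter vector for one scan segment (no validation: hot
#' path of the fit objective)
#' @noRd
segment_parms <- function(params, scan) {
  k <- params$constants
  K1 <- if (scan == "disp2") {
    # post-displacement tracer delivery of the split-K1 model variant
    if (is.null(params$K1_disp2) || is.na(params$K1_disp2))
      params$K1_disp else params$K1_disp2
  } else params[[paste0("K1_", scan)]]
  fP <- params[[paste0("fP_", if (scan == "post") "post" else "disp")]]
  bterm <- params$VT * params$fND / fP - 1
  c(K1 = K1, k2 = K1 * params$fND / fP, koff = k$koff, bterm = bterm,
    K1D = params$K1D, k2D = params$K1D * k$fNDD / k$fPD, koffD = k$koffD,
    Bmax = k$KD * bterm / params$fND, ratioD = k$fNDD / k$KDD)
}
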