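#' F test between nested least-squares fits
#'
#' Compares the residual sum of squares of a reduced model against a full
#' model in which it is nested:
#' `F = ((ss_reduced - ss_full) / (p_full - p_reduced)) / (ss_full / (n - p_full))`
#' with `(p_full - p_reduced, n - p_full)` degrees of freedom.
#'
#' @param ss_reduced,ss_full Residual sums of squares (reduced >= full).
#' @param p_reduced,p_full Numbers of estimated parameters.
#' @param n Number of fitted data points.
#' @return List with `F`, `p_value`, `df1`, `df2`.
#' @examples
#' f_test(120, 100, 5, 7, 66)  # F = (20/2)/(100/59) = 5.9
#' @export
f_test <- function(ss_reduced, ss_full, p_reduced, p_full, n) {
  if (p_full <= p_reduced) stop("p_full must exceed p_reduced (nesting)")
  if (n <= p_full) stop("n must exceed p_full")
  if (ss_full < 0 || ss_reduced < 0) stop("sums of squares must be >= 0")
  if (ss_reduced < ss_full - 1e-9 * max(ss_full, 1))
    stop("ss_reduced < ss_full: models are not nested as stated")
  df1 <- p_full - p_reduced
  df2 <- n - p_full
  Fv <- max(ss_reduced - ss_full, 0) / df1 / (ss_full / df2)
  list(F = Fv, p_value = pf(Fv, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Signed test-retest difference
#'
#' The reproducibility measure `2 (test - retest) / (test + retest)`:
#' antisymmetric in its arguments and zero for equal values.
#'
#' @param test,retest Positive values (vectorized).
#' @return Signed fractional difference.
#' @export
test_retest <- function(test, retest) {
  if (any(test + retest <= 0))
    stop("test + retest must be positive")
  2 * (test - retest) / (test + retest)
}

#' Conservative bound on the drug delivery rate by pooled F test
#'
#' For each candidate fixed value of `K1D` on a grid, refits the remaining
#' 5p parameters for every subject, pools the residual sums of squares, and
#' compares them with the pooled unconstrained 5p fits by F test (one
#' constrained parameter per subject). The bound is the most extreme fixed
#' value in the search direction that is still statistically consistent with
#' the data (p >= alpha); values beyond it are rejected. The boundary is
#' optionally refined by bisection. The lower bound on the BRV/LEV delivery
#' ratio is then `lower bound(BRV K1D) / upper bound(LEV K1D)`, see
#' [k1d_ratio_bound()].
#'
#' @param datasets List of [subject_dataset()] for one drug (one per
#'   subject).
#' @param region Region label.
#' @param direction `"lower"` (smallest feasible value, used for the faster
#'   drug) or `"upper"` (largest feasible value, used for the slower drug).
#' @param grid Candidate fixed `K1D` values in uL/cm^3/min (e.g. 30-100 for
#'   BRV, 5-10 for LEV). `NULL` (default) anchors the grid at the median
#'   unconstrained estimate (multiples 0.25-1 for a lower search, 1-4 for an
#'   upper search, denser near the anchor), mirroring how published grids
#'   bracket the unconstrained estimates.
#' @param alpha Rejection level (default 0.05).
#' @param refine Bisect the boundary interval down to `refine_tol`.
#' @param refine_tol Refinement resolution, uL/cm^3/min.
#' @param ... Passed to [fit_joint()] (e.g. `weights`, tolerances).
#' @return Object of class `bound_search_result`: the grid trace (pooled SS,
#'   F, p per grid value), the pooled unconstrained SS and per-subject
#'   estimates, and `bound` (uL/cm^3/min; `NA` with a warning when every
#'   grid value is rejected).
#' @export
k1d_bound_search <- function(datasets, region,
                             direction = c("lower", "upper"),
                             grid = NULL, alpha = 0.05, refine = TRUE,
                             refine_tol = 0.1, ...) {
  direction <- match.arg(direction)
  stopifnot(length(datasets) >= 1, all(vapply(datasets, inherits, TRUE,
                                              "subject_dataset")))
  m <- length(datasets)

  free <- lapply(datasets, fit_joint, region = region,
                 config = model_config("5p"), ...)
  ss_full <- sum(vapply(free, `[[`, 1, "SS"))
  n_tot <- sum(vapply(free, `[[`, 1L, "n"))
  p_full <- 5L * m
  est_k1d <- vapply(free, function(f) f$estimates[["K1D"]], 1)

  if (is.null(grid)) {
    # anchored at the median unconstrained estimate, denser near it (the
    # acceptance region is typically within ~2 standard errors of the
    # anchor) and always including the anchor itself
    anchor <- median(k1d_to_uL(est_k1d))
    grid <- if (direction == "lower")
      anchor * c(0.25, 0.35, 0.5, 0.65, 0.8, 0.9, 1)
    else anchor * c(1, 1.15, 1.35, 1.6, 2, 3, 4)
  }
  grid <- sort(grid)

  # warm starts: per-subject estimates from the nearest previously solved
  # grid value (falling back to the unconstrained estimates)
  warm <- lapply(free, function(f)
    as.list(f$estimates[c("K1_disp", "K1_post", "VT", "fND")]))
  eval_fixed <- function(g_uL, update_warm = FALSE) {
    ss <- 0
    for (i in seq_len(m)) {
      f <- fit_joint(datasets[[i]], region, config = model_config("5p"),
                     fixed = list(K1D = k1d_from_uL(g_uL)),
                     start = warm[[i]], ...)
      if (update_warm)
        warm[[i]] <<- as.list(f$estimates[c("K1_disp", "K1_post",
                                            "VT", "fND")])
      ss <- ss + f$SS
    }
    ss
  }

  # evaluate the grid walking away from the unconstrained optimum so each
  # fit starts from the neighbouring solution
  ord <- if (direction == "lower") rev(seq_along(grid)) else seq_along(grid)
  ss_grid <- numeric(length(grid))
  for (j in ord) ss_grid[j] <- eval_fixed(grid[j], update_warm = TRUE)
  tests <- lapply(ss_grid, function(ss)
    f_test(ss, ss_full, p_full - m, p_full, n_tot))
  p_vals <- vapply(tests, `[[`, 1, "p_value")
  F_vals <- vapply(tests, `[[`, 1, "F")
  accepted <- p_vals >= alpha

  # p should fall as the fixed value moves away from the constrained optimum
  # (unimodal SS profile); tolerate small non-monotonicity from fit jitter
  i_top <- which.max(p_vals)
  tol <- 0.005
  mono_ok <- TRUE
  if (i_top < length(p_vals))
    mono_ok <- mono_ok && all(diff(p_vals[i_top:length(p_vals)]) <= tol)
  if (i_top > 1L)
    mono_ok <- mono_ok && all(diff(rev(p_vals[1:i_top])) <= tol)
  if (!mono_ok)
    warning("p-values are not unimodal along the grid; ",
            "the constrained SS profile may be multimodal")

  bound <- NA_real_
  bracket <- NULL
  if (!any(accepted)) {
    warning("all grid values rejected; bound lies outside the grid (",
            if (direction == "lower") "above " else "below ",
            if (direction == "lower") max(grid) else min(grid), ")")
  } else if (direction == "lower") {
    bound <- min(grid[accepted])
    i <- which(grid == bound)
    if (i > 1L && !accepted[i - 1L]) bracket <- c(grid[i - 1L], bound)
  } else {
    bound <- max(grid[accepted])
    i <- which(grid == bound)
    if (i < length(grid) && !accepted[i + 1L]) bracket <- c(bound, grid[i + 1L])
  }

  if (refine && !is.null(bracket)) {
    lo <- bracket[1]; hi <- bracket[2]
    # invariant: for "lower", lo rejected / hi accepted; mirrored for "upper"
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      ok <- f_test(eval_fixed(mid), ss_full, p_full - m, p_full,
                   n_tot)$p_value >= alpha
      if (direction == "lower") {
        if (ok) hi <- mid else lo <- mid
      } else {
        if (ok) lo <- mid else hi <- mid
      }
    }
    bound <- if (direction == "lower") hi else lo
  }

  structure(list(
    region = region, direction = direction, alpha = alpha,
    grid = grid, pooled_ss = ss_grid, F = F_vals, p = p_vals,
    accepted = accepted, bound = bound,
    unconstrained = list(pooled_ss = ss_full, n = n_tot, p = p_full,
                         K1D_uL = k1d_to_uL(est_k1d)),
    n_subjects = m),
    class = "bound_search_result")
}

#' @export
print.bound_search_result <- function(x, ...) {
  cat(sprintf("K1D %s bound search, region %s (%d subjects)\n",
              x$direction, x$region, x$n_subjects))
  print(data.frame(K1D_uL = x$grid, pooled_SS = signif(x$pooled_ss, 6),
                   F = signif(x$F, 4), p = signif(x$p, 3),
                   accepted = x$accepted), row.names = FALSE)
  cat(sprintf("bound: %s uL/cm^3/min (alpha = %g)\n",
              format(x$bound), x$alpha))
  invisible(x)
}

#' Conservative lower bound on the BRV/LEV delivery-rate ratio
#'
#' @param brv_lower A `"lower"`-direction [k1d_bound_search()] result for the
#'   faster drug.
#' @param lev_upper An `"upper"`-direction result for the slower drug.
#' @return The ratio lower bound (dimensionless).
#' @export
k1d_ratio_bound <- function(brv_lower, lev_upper) {
  stopifnot(inherits(brv_lower, "bound_search_result"),
            inherits(lev_upper, "bound_search_result"),
            brv_lower$direction == "lower", lev_upper$direction == "upper")
  brv_lower$bound / lev_upper$bound
}

#' Sensitivity of the 5p fit to errors in the fixed constants
#'
#' Refits the 5p model with one fixed constant multiplied by `factor`
#' (50%/200% in the standard design) and reports the percent change of each
#' estimate and of the residual sum of squares relative to the reference 5p
#' fit. Positive values mean the perturbed fit is higher.
#'
#' @param dataset A [subject_dataset()].
#' @param region Region label.
#' @param param One of `koff`, `koffD`, `KD`, `KDD`, `fPD`, `fNDD`.
#' @param factor Multipliers of the fixed value (default `c(0.5, 2)`).
#' @param reference Optional precomputed reference 5p [fit_joint()] result.
#' @param ... Passed to [fit_joint()].
#' @return Data frame with columns `param`, `factor`, `quantity`,
#'   `pct_change`, covering `VT`, `fND`, `K1_disp`, `K1_post`, `K1D`, `SS`.
#' @export
sensitivity_fixed_params <- function(dataset, region,
                                     param = c("koff", "koffD", "KD", "KDD",
                                               "fPD", "fNDD"),
                                     factor = c(0.5, 2),
                                     reference = NULL, ...) {
  param <- match.arg(param)
  if (is.null(reference))
    reference <- fit_joint(dataset, region, config = model_config("5p"), ...)
  if (!reference$converged) stop("reference 5p fit did not converge")
  quantities <- c("VT", "fND", "K1_disp", "K1_post", "K1D", "SS")
  ref_vals <- c(reference$estimates[c("VT", "fND", "K1_disp", "K1_post",
                                      "K1D")], SS = reference$SS)
  base_val <- reference$fixed[[param]]
  out <- list()
  for (f in factor) {
    if (f == 1) {
      pert_vals <- ref_vals
    } else {
      st <- as.list(reference$estimates)
      fit <- fit_joint(dataset, region, config = model_config("5p"),
                       fixed = setNames(list(base_val * f), param),
                       start = st, ...)
      pert_vals <- c(fit$estimates[c("VT", "fND", "K1_disp", "K1_post",
                                     "K1D")], SS = fit$SS)
    }
    out[[length(out) + 1L]] <- data.frame(
      param = param, factor = f, quantity = quantities,
      pct_change = 100 * (pert_vals - ref_vals) / ref_vals,
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' One extra floating parameter (6p model) with F test against 5p
#'
#' Fits the 6p configuration that floats `extra_param` in addition to the
#' five primary parameters and compares it with the reference 5p fit by
#' [f_test()].
#'
#' @param dataset A [subject_dataset()].
#' @param region Region label.
#' @param extra_param One of `fPD`, `fNDD`, `KD`, `KDD`, `koff`, `koffD`.
#' @param reference Optional precomputed 5p [fit_joint()] result.
#' @param ... Passed to [fit_joint()].
#' @return List with `fit6` (the 6p `fit_result`), `fit5` and `ftest`.
#' @export
sensitivity_one_extra <- function(dataset, region, extra_param,
                                  reference = NULL, ...) {
  if (is.null(reference))
    reference <- fit_joint(dataset, region, config = model_config("5p"), ...)
  st <- as.list(reference$estimates)
  st[[extra_param]] <- reference$fixed[[extra_param]]
  fit6 <- fit_joint(dataset, region,
                    config = model_config(paste0("6p:", extra_param)),
                    start = st, ...)
  # the 6p optimum can be no worse than 5p; guard against optimizer jitter
  ss6 <- min(fit6$SS, reference$SS)
  ft <- f_test(reference$SS, ss6, 5, 6, reference$n)
  list(fit6 = fit6, fit5 = reference, ftest = ft)
}
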