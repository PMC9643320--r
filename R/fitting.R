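#' Model configuration: which parameters float
#'
#' Named configurations of the joint displacement + post-dose fit:
#' * `"5p"` floats `K1_disp`, `K1_post`, `VT`, `fND`, `K1D` (the default
#'   analysis model; `koff`/`koffD` fixed to study-average values),
#' * `"7p"` additionally floats `koff` and `koffD`,
#' * `"6p:<param>"` is 5p plus exactly one of `fPD`, `fNDD`, `KD`, `KDD`,
#'   `koff`, `koffD`,
#' * `"13p"` floats everything including per-scan `fP` and all drug
#'   constants.
#'
#' @param id Configuration id string.
#' @param split_K1_disp If `TRUE`, allow the displacement-scan tracer `K1` to
#'   change at the drug infusion time (a tested-and-rejected model variant;
#'   off by default).
#' @return Object of class `model_config`.
#' @export
model_config <- function(id = "5p", split_K1_disp = FALSE) {
  base5 <- c("K1_disp", "K1_post", "VT", "fND", "K1D")
  extras6 <- c("fPD", "fNDD", "KD", "KDD", "koff", "koffD")
  if (grepl("^6p:", id)) {
    extra <- sub("^6p:", "", id)
    if (!extra %in% extras6)
      stop("6p extra parameter must be one of: ",
           paste(extras6, collapse = ", "))
    floating <- c(base5, extra)
  } else {
    floating <- switch(id,
      "5p" = base5,
      "7p" = c(base5, "koff", "koffD"),
      "13p" = c(base5, "koff", "koffD", "fP_disp", "fP_post",
                "fPD", "fNDD", "KD", "KDD"),
      stop("unknown model configuration: ", id))
  }
  structure(list(id = id, floating = floating,
                 split_K1_disp = isTRUE(split_K1_disp)),
            class = "model_config")
}

# parameters bounded above by 1 (fractions)
.frac_params <- c("fND", "fP_disp", "fP_post", "fPD", "fNDD")
.const_params <- c("koff", "koffD", "fPD", "fNDD", "KD", "KDD")

#' Assemble kinetic_parameters from floating values + fixed context
#' @noRd
build_params <- function(values, fixed) {
  v <- modifyList(fixed, as.list(values))
  structure(list(
    K1_disp = v$K1_disp, K1_post = v$K1_post, VT = v$VT, fND = v$fND,
    K1D = v$K1D, K1_disp2 = v$K1_disp2,
    fP_disp = v$fP_disp, fP_post = v$fP_post,
    constants = structure(list(drug = v$drug, KD = v$KD, koff = v$koff,
                               vB = v$vB, fPD = v$fPD, KDD = v$KDD,
                               fNDD = v$fNDD, koffD = v$koffD),
                          class = "fixed_constants")),
    class = "kinetic_parameters")
}

#' Precompute everything the fit objective reuses
#' @noRd
make_fit_context <- function(dataset, region, weights = "duration",
                             points_per_frame = 11, rtol = 1e-8,
                             atol = 1e-10, split_disp_at = NULL) {
  stopifnot(inherits(dataset, "subject_dataset"))
  if (!region %in% names(dataset$disp$tacs))
    stop("region '", region, "' not present in the dataset")
  tl <- dataset_timeline(dataset)
  frames <- list(disp = dataset$disp$frames, post = dataset$post$frames)
  offs <- c(disp = dataset$disp$injection_time,
            post = dataset$post$injection_time)
  grid <- sort(unique(c(
    frame_grid(frames$disp, offs["disp"], points_per_frame),
    frame_grid(frames$post, offs["post"], points_per_frame),
    seq(tl$scan1_end, tl$inj_post, by = 5))))
  plan <- make_sim_plan(list(disp = dataset$disp$plasma,
                             post = dataset$post$plasma),
                        dataset$drug_input, tl, grid,
                        split_disp_at = split_disp_at)
  y <- c(dataset$disp$tacs[[region]], dataset$post$tacs[[region]])
  dur <- c(frames$disp$duration, frames$post$duration)
  w <- switch(match.arg(weights, c("duration", "uniform", "counts")),
              duration = dur / mean(dur),
              uniform = rep(1, length(dur)),
              counts = {
                # inverse of the count-statistics variance of decay-corrected
                # frames: var ~ value * exp(lambda t_mid) / duration
                lam <- log(2) / 20.4
                mid <- c(frames$disp$mid, frames$post$mid)
                v <- pmax(y, 0.05 * max(y)) * exp(lam * mid) / dur
                (1 / v) / mean(1 / v)
              })
  fixed <- list(
    K1_disp = NA_real_, K1_post = NA_real_, VT = NA_real_, fND = NA_real_,
    K1D = NA_real_, K1_disp2 = NA_real_,
    fP_disp = dataset$disp$fP, fP_post = dataset$post$fP,
    drug = dataset$constants$drug, KD = dataset$constants$KD,
    koff = dataset$constants$koff, vB = dataset$constants$vB,
    fPD = dataset$constants$fPD, KDD = dataset$constants$KDD,
    fNDD = dataset$constants$fNDD, koffD = dataset$constants$koffD)
  list(dataset = dataset, region = region, tl = tl, frames = frames,
       offs = offs, plan = plan, y = y, w = w, fixed = fixed,
       points_per_frame = points_per_frame, rtol = rtol, atol = atol,
       vB = dataset$constants$vB,
       wb = list(disp = dataset$disp$whole_blood,
                 post = dataset$post$whole_blood))
}

#' Model TAC prediction for a parameter vector within a fit context
#' @noRd
predict_context <- function(values, ctx) {
  params <- build_params(values, ctx$fixed)
  traj <- run_sim_plan(params, ctx$plan, rtol = ctx$rtol, atol = ctx$atol)
  traj <- structure(traj, class = c("state_trajectory", "data.frame"))
  c(predict_pet(traj, ctx$wb$disp, ctx$frames$disp, vB = ctx$vB,
                t_offset = ctx$offs["disp"],
                points_per_frame = ctx$points_per_frame),
    predict_pet(traj, ctx$wb$post, ctx$frames$post, vB = ctx$vB,
                t_offset = ctx$offs["post"],
                points_per_frame = ctx$points_per_frame))
}

#' Jointly fit the competition model to a displacement + post-dose pair
#'
#' Weighted nonlinear least squares over the frames of both scans
#' simultaneously: the drug states are shared across scans on the absolute
#' clock while the tracer states restart at the second injection.
#' Optimization runs on log-transformed parameters (all parameters positive,
#' free fractions capped at 1) with a multi-start over the poorly
#' identifiable drug delivery rate `K1D`; ties are broken by the smaller
#' parameter vector norm. Standard errors come from the finite-difference
#' Jacobian of the model at the optimum (scaled inverse of the weighted
#' normal matrix), reported as percent of the estimate (rSE).
#'
#' @param dataset A [subject_dataset()].
#' @param region Region label, e.g. `"putamen"`.
#' @param config A [model_config()].
#' @param weights `"duration"` (per-frame weight proportional to frame
#'   duration; default), `"uniform"`, or `"counts"` (inverse of the
#'   count-statistics variance of decay-corrected frames,
#'   `value * exp(lambda t_mid) / duration` with the carbon-11 decay
#'   constant; the usual choice when residual variance must be comparable
#'   across frames, e.g. for pooled F tests).
#' @param start Optional named list of starting values (natural scale)
#'   overriding the default initialization (tracer parameters from a
#'   preliminary 1TC fit, `fND = 0.1`, `K1D` multi-start).
#' @param multistart_K1D Starting values for `K1D`, mL/cm^3/min.
#' @param fixed Optional named list overriding fixed values (e.g.
#'   `list(K1D = 0.05)` fixes the drug delivery rate, as in the bound
#'   search; overridden names are dropped from the floating set).
#' @param points_per_frame Quadrature points per frame.
#' @param rtol,atol ODE solver tolerances.
#' @param control A [minpack.lm::nls.lm.control()] list.
#' @return Object of class `fit_result`: `estimates`, `se`, `rse` (percent),
#'   `SS` (weighted residual sum of squares), `n`, `converged`, `fitted`
#'   and `residuals` per scan, plus the configuration and region.
#' @export
fit_joint <- function(dataset, region, config = model_config("5p"),
                      weights = "duration", start = NULL,
                      multistart_K1D = c(0.001, 0.01, 0.1), fixed = NULL,
                      points_per_frame = 11, rtol = 1e-8, atol = 1e-10,
                      control = minpack.lm::nls.lm.control(maxiter = 200,
                                                           epsfcn = 1e-8)) {
  stopifnot(inherits(config, "model_config"))
  ctx <- make_fit_context(dataset, region, weights = weights,
                          points_per_frame = points_per_frame,
                          rtol = rtol, atol = atol,
                          split_disp_at = if (config$split_K1_disp)
                            dataset$dose$infusion_start)
  floating <- config$floating
  if (config$split_K1_disp) floating <- c(floating, "K1_disp2")
  if (!is.null(fixed)) {
    ctx$fixed[names(fixed)] <- fixed
    floating <- setdiff(floating, names(fixed))
  }

  # initialization: preliminary 1TC on the pre-drug displacement data
  init <- fit_context_init(ctx)
  starts <- list()
  k1d_starts <- if ("K1D" %in% floating) multistart_K1D else NA
  for (k1d0 in k1d_starts) {
    s <- init
    if (!is.na(k1d0)) s$K1D <- k1d0
    if (!is.null(start)) s[names(start)] <- start
    starts[[length(starts) + 1L]] <- unlist(s[floating])
  }

  sw <- sqrt(ctx$w)
  resid_fn <- function(theta_log) {
    vals <- exp(theta_log)
    names(vals) <- floating
    p <- modifyList(ctx$fixed, as.list(vals))
    if (p$VT * p$fND / min(p$fP_disp, p$fP_post) <= 1 + 1e-10)
      return(rep(1e6, length(ctx$y)))   # negative binding capacity: penalize
    yhat <- tryCatch(predict_context(vals, ctx),
                     error = function(e) NULL)
    if (is.null(yhat)) return(rep(1e6, length(ctx$y)))
    sw * (yhat - ctx$y)
  }

  lower <- rep(log(1e-6), length(floating))
  upper <- ifelse(floating %in% .frac_params, 0, log(1e5))
  best <- NULL
  for (s in starts) {
    theta0 <- pmin(pmax(log(s), lower + 1e-9), upper - 1e-9)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                         fn = resid_fn, control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- fit$deviance
    if (is.null(best) || ss < best$ss - 1e-12 ||
        (abs(ss - best$ss) <= 1e-12 &&
         sum(exp(fit$par)^2) < sum(exp(best$fit$par)^2)))
      best <- list(fit = fit, ss = ss)
  }
  if (is.null(best))
    stop("fit_joint: no start converged for region '", region, "'")

  fit <- best$fit
  est <- exp(fit$par)
  names(est) <- floating
  at_bound <- fit$par <= lower + 1e-7 | fit$par >= upper - 1e-7
  yhat <- predict_context(est, ctx)
  res <- ctx$y - yhat
  nfr <- nrow(ctx$frames$disp)

  J <- fd_jacobian(function(v) predict_context(v, ctx), est)
  se_out <- standard_errors(J, res, ctx$w, estimates = est)

  structure(list(
    estimates = est, se = se_out$se, rse = se_out$rse,
    SS = sum(ctx$w * res^2), n = length(ctx$y), npar = length(floating),
    converged = fit$info %in% 1:4, info = fit$info,
    message = fit$message, at_bound = at_bound,
    singular = se_out$singular,
    fitted = list(disp = yhat[seq_len(nfr)], post = yhat[-seq_len(nfr)]),
    residuals = list(disp = res[seq_len(nfr)] * sqrt(ctx$w)[seq_len(nfr)],
                     post = res[-seq_len(nfr)] * sqrt(ctx$w)[-seq_len(nfr)]),
    config = config, region = region, weights = weights,
    fixed = ctx$fixed, dataset_id = dataset$id),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Joint fit [%s] region %s (%s): SS = %.5g, n = %d, %s\n",
              x$config$id, x$region, x$dataset_id, x$SS, x$n,
              if (x$converged) "converged" else "NOT converged"))
  est <- x$estimates
  disp <- ifelse(names(est) == "K1D",
                 sprintf("%.4g uL/cm^3/min", 1000 * est),
                 sprintf("%.4g", est))
  for (i in seq_along(est))
    cat(sprintf("  %-8s %s (rSE %.3g%%)\n", names(est)[i], disp[i], x$rse[i]))
  invisible(x)
}

#' Default initialization from a preliminary 1TC fit
#' @noRd
fit_context_init <- function(ctx) {
  ds <- ctx$dataset
  init <- list(K1_disp = 0.4, K1_post = 0.4, VT = 15, fND = 0.1,
               K1D = 0.01, koff = ctx$fixed$koff, koffD = ctx$fixed$koffD,
               fP_disp = ctx$fixed$fP_disp, fP_post = ctx$fixed$fP_post,
               fPD = ctx$fixed$fPD, fNDD = ctx$fixed$fNDD,
               KD = ctx$fixed$KD, KDD = ctx$fixed$KDD)
  pre <- tryCatch(
    fit_1tc(ds$disp$tacs[[ctx$region]], ds$disp$frames, ds$disp$plasma,
            ds$disp$whole_blood, vB = ctx$vB,
            t_inj = ds$disp$injection_time,
            tmax = min(60, ds$dose$infusion_start - ds$disp$injection_time)),
    error = function(e) NULL)
  if (!is.null(pre) && is.finite(pre$K1) && is.finite(pre$VT)) {
    init$K1_disp <- pre$K1
    init$K1_post <- pre$K1
    init$VT <- pre$VT
  }
  init$K1_disp2 <- init$K1_disp
  # keep the starting point inside the positive-binding region
  if (init$VT * init$fND / min(init$fP_disp, init$fP_post) <= 1.2)
    init$fND <- min(1, 1.5 * init$fP_disp / init$VT)
  init
}

#' Forward finite-difference Jacobian on the natural scale
#' @noRd
fd_jacobian <- function(f, x, rel_step = 1e-4) {
  f0 <- f(x)
  J <- matrix(NA_real_, nrow = length(f0), ncol = length(x))
  for (j in seq_along(x)) {
    h <- rel_step * max(abs(x[j]), 1e-12)
    xp <- x; xp[j] <- x[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  colnames(J) <- names(x)
  J
}

#' Standard errors from the weighted normal matrix
#'
#' Given the model Jacobian `J` (n x p, natural parameter scale), the raw
#' residuals and the frame weights, computes `cov = s2 * (J' W J)^-1` with
#' `s2 = sum(w r^2) / (n - p)`, and the percent standard error
#' `rSE = 100 SE / |estimate|`.
#'
#' @param jacobian n x p model Jacobian at the optimum.
#' @param residuals Raw (unweighted) residuals, length n.
#' @param weights Frame weights, length n (`NULL` for uniform).
#' @param estimates Parameter estimates (for rSE; optional).
#' @return List with `se`, `rse`, `cov`, `singular`. When the normal matrix
#'   is singular the standard errors are reported as `NA` with
#'   `singular = TRUE` rather than a hard failure.
#' @export
standard_errors <- function(jacobian, residuals, weights = NULL,
                            estimates = NULL) {
  J <- as.matrix(jacobian)
  n <- nrow(J); p <- ncol(J)
  if (length(residuals) != n) stop("residuals length must match nrow(jacobian)")
  if (is.null(weights)) weights <- rep(1, n)
  if (n <= p) stop("need more observations than parameters")
  s2 <- sum(weights * residuals^2) / (n - p)
  JtWJ <- crossprod(J * sqrt(weights))
  cov <- tryCatch(solve(JtWJ) * s2, error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    se <- rep(NA_real_, p)
    return(list(se = se, rse = se, cov = NULL, singular = TRUE))
  }
  se <- sqrt(diag(cov))
  rse <- if (is.null(estimates)) rep(NA_real_, p) else 100 * se / abs(estimates)
  names(se) <- colnames(J)
  if (!is.null(names(se))) names(rse) <- names(se)
  list(se = se, rse = rse, cov = cov, singular = FALSE)
}

#' One-tissue compartment fit of early displacement data
#'
#' The conventional comparator: fits the linear one-tissue compartment model
#' `dC_T/dt = K1 C_P - (K1/VT) C_T` to the frames of the first `tmax`
#' minutes (before drug administration), with the same frame weighting and
#' blood-volume treatment as the joint fit. The tissue curve is computed by
#' exponential convolution of the plasma input on a fine grid.
#'
#' @param tac Frame values of one region, Bq/cm^3.
#' @param frames [frame_schedule()] (relative to this scan's injection).
#' @param tracer_input Parent plasma [sampled_curve()], absolute clock.
#' @param whole_blood Whole-blood [sampled_curve()] (or number), absolute
#'   clock.
#' @param vB Blood volume fraction (fixed unless `float_vB`).
#' @param t_inj Injection time on the absolute clock.
#' @param tmax Use frames ending at or before this time (minutes
#'   post-injection).
#' @param weights `"duration"` or `"uniform"`.
#' @param float_vB Also estimate the blood volume fraction.
#' @param dt Convolution grid step, minutes.
#' @return List with `K1`, `VT`, `k2`, `vB`, `se`, `rse`, `SS`, `n`,
#'   `converged`, `fitted`.
#' @export
fit_1tc <- function(tac, frames, tracer_input, whole_blood, vB = 0.05,
                    t_inj = 0, tmax = 60, weights = "duration",
                    float_vB = FALSE, dt = 0.05) {
  keep <- which(frames$start + frames$duration <= tmax + 1e-9)
  if (length(keep) < 10)
    stop("need at least 10 frames before ", tmax, " min; got ", length(keep))
  fr <- frames[keep, ]
  y <- tac[keep]
  w <- switch(match.arg(weights, c("duration", "uniform")),
              duration = fr$duration / mean(fr$duration),
              uniform = rep(1, length(keep)))
  tg <- seq(0, max(fr$start + fr$duration), by = dt)
  cp <- interpolate_curve(tracer_input, t_inj + tg)
  wbv <- if (is.numeric(whole_blood)) rep(whole_blood, length(tg))
         else interpolate_curve(whole_blood, t_inj + tg)
  # per-frame quadrature indices on the fine grid
  fidx <- lapply(seq_len(nrow(fr)), function(i) {
    sel <- which(tg >= fr$start[i] - 1e-9 &
                 tg <= fr$start[i] + fr$duration[i] + 1e-9)
    sel
  })
  model_tac <- function(K1, VT, vb) {
    k2 <- K1 / VT
    E <- exp(-k2 * dt)
    inp <- c(0, dt / 2 * (cp[-1] + E * cp[-length(cp)]))
    ct <- K1 * as.numeric(stats::filter(inp, E, method = "recursive"))
    sig <- (1 - vb) * ct + vb * wbv
    vapply(fidx, function(ii) trapz_mean(tg[ii], sig[ii]), numeric(1))
  }
  pnames <- c("K1", "VT", if (float_vB) "vB")
  resid_fn <- function(theta) {
    v <- exp(theta)
    vb <- if (float_vB) v[3] else vB
    sqrt(w) * (model_tac(v[1], v[2], vb) - y)
  }
  theta0 <- log(c(0.4, 15, if (float_vB) max(vB, 1e-3)))
  lower <- rep(log(1e-6), length(theta0))
  upper <- c(log(10), log(200), if (float_vB) log(0.2))
  fit <- minpack.lm::nls.lm(par = theta0, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, epsfcn = 1e-12))
  est <- exp(fit$par)
  names(est) <- pnames
  vb_hat <- if (float_vB) est[["vB"]] else vB
  yhat <- model_tac(est[["K1"]], est[["VT"]], vb_hat)
  res <- y - yhat
  J <- fd_jacobian(function(v)
    model_tac(v[["K1"]], v[["VT"]], if (float_vB) v[["vB"]] else vB), est)
  se_out <- standard_errors(J, res, w, estimates = est)
  list(K1 = est[["K1"]], VT = est[["VT"]], k2 = est[["K1"]] / est[["VT"]],
       vB = vb_hat, estimates = est, se = se_out$se, rse = se_out$rse,
       SS = sum(w * res^2), n = length(y), npar = length(pnames),
       converged = fit$info %in% 1:4, fitted = yhat)
}
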