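#' Study timeline
#'
#' Event times on the absolute study clock (minutes; the displacement-scan
#' tracer injection defines t = 0): injection and duration of each scan and
#' the start/duration of the drug infusion. The post-dose scan is optional
#' (set `inj_post = NULL` for a single-scan simulation).
#'
#' @param inj_disp Displacement-scan injection time (min).
#' @param inj_post Post-dose-scan injection time, or `NULL`.
#' @param scan_duration Scan length per scan (min).
#' @param infusion_start Start of the drug infusion (min, absolute clock).
#' @param infusion_duration Drug infusion length (min).
#' @return Object of class `study_timeline`.
#' @export
study_timeline <- function(inj_disp = 0, inj_post = 330, scan_duration = 120,
                           infusion_start = 60, infusion_duration = 5) {
  scan1_end <- inj_disp + scan_duration
  if (!is.null(inj_post) && inj_post < scan1_end)
    stop("post-dose injection must come after the displacement scan ends")
  if (infusion_start < inj_disp || infusion_start + infusion_duration > scan1_end)
    stop("drug infusion must lie inside the displacement scan")
  structure(list(inj_disp = inj_disp, inj_post = inj_post,
                 scan_duration = scan_duration, scan1_end = scan1_end,
                 scan2_end = if (!is.null(inj_post)) inj_post + scan_duration,
                 infusion_start = infusion_start,
                 infusion_duration = infusion_duration),
            class = "study_timeline")
}

#' Build the forcing table for one integration segment
#' @noRd
segment_forcing <- function(curve, t0, t1, zero = FALSE) {
  if (zero || is.null(curve))
    return(cbind(c(t0, t1), c(0, 0)))
  tt <- sort(unique(c(t0, curve$times[curve$times > t0 & curve$times < t1], t1)))
  cbind(tt, interpolate_curve(curve, tt))
}

#' Default output grid: fine within scans, coarse in the gap
#' @noRd
default_sim_grid <- function(timeline, dt_scan = 0.25, dt_gap = 5) {
  g <- seq(timeline$inj_disp, timeline$scan1_end, by = dt_scan)
  if (!is.null(timeline$inj_post)) {
    g <- c(g, seq(timeline$scan1_end, timeline$inj_post, by = dt_gap),
           seq(timeline$inj_post, timeline$scan2_end, by = dt_scan))
  }
  sort(unique(c(g, timeline$infusion_start,
                timeline$infusion_start + timeline$infusion_duration)))
}

#' Integration plan shared by simulation and fitting
#'
#' Precomputes segment boundaries, output times and drug forcing tables so
#' repeated simulations during fitting only swap parameter vectors.
#' @noRd
make_sim_plan <- function(tracer_input, drug_input, timeline, grid,
                          split_disp_at = NULL) {
  grid <- sort(unique(grid))
  if (grid[1] < timeline$inj_disp - 1e-9)
    stop("output grid starts before the first injection")
  two_scans <- !is.null(timeline$inj_post)
  # tracer_input: single curve on the absolute clock, or list(disp=, post=)
  if (inherits(tracer_input, "sampled_curve"))
    tracer_input <- list(disp = tracer_input, post = tracer_input)

  scan1_end <- if (two_scans) timeline$scan1_end
               else max(grid, timeline$scan1_end)
  if (!is.null(split_disp_at) &&
      (split_disp_at <= timeline$inj_disp || split_disp_at >= scan1_end))
    stop("split_disp_at must lie inside the displacement scan")
  specs <- if (is.null(split_disp_at)) {
    list(list(t0 = timeline$inj_disp, t1 = scan1_end, scan = "disp",
              reset = TRUE, zero = FALSE))
  } else {
    # mid-scan tracer-K1 switch (the "K1 allowed to change at displacement"
    # model variant): same states, new delivery parameters
    list(list(t0 = timeline$inj_disp, t1 = split_disp_at, scan = "disp",
              reset = TRUE, zero = FALSE),
         list(t0 = split_disp_at, t1 = scan1_end, scan = "disp2",
              reset = FALSE, zero = FALSE))
  }
  if (two_scans)
    specs <- c(specs,
               list(list(t0 = timeline$scan1_end, t1 = timeline$inj_post,
                         scan = "disp", reset = FALSE, zero = TRUE),
                    list(t0 = timeline$inj_post, t1 = timeline$scan2_end,
                         scan = "post", reset = TRUE, zero = FALSE)))
  segs <- list()
  for (sp in specs) {
    if (sp$t1 <= sp$t0 + 1e-9) next
    curve_key <- if (sp$scan == "post") "post" else "disp"
    times <- sort(unique(c(sp$t0, grid[grid > sp$t0 & grid < sp$t1], sp$t1)))
    segs[[length(segs) + 1L]] <- list(
      times = times, scan = sp$scan,
      reset_tracer = sp$reset,
      cp = segment_forcing(tracer_input[[curve_key]], sp$t0, sp$t1,
                           zero = sp$zero),
      dp = segment_forcing(drug_input, sp$t0, sp$t1,
                           zero = is.null(drug_input)))
  }
  list(segments = segs, grid = grid, timeline = timeline)
}

#' Run the compiled competition model over a prepared plan
#' @noRd
run_sim_plan <- function(params, plan, rtol = 1e-8, atol = 1e-10,
                         method = "lsoda") {
  y <- c(C_ND = 0, C_S = 0, D_ND = 0, O = 0)
  out <- NULL
  for (seg in plan$segments) {
    if (seg$reset_tracer) y[c("C_ND", "C_S")] <- 0
    sol <- tryCatch(
      deSolve::ode(y = y, times = seg$times, func = "sv2a_derivs",
                   parms = segment_parms(params, seg$scan),
                   dllname = "sv2akin", initfunc = "sv2a_initmod",
                   initforc = "sv2a_initforc",
                   forcings = list(seg$cp, seg$dp),
                   fcontrol = list(method = "linear", rule = 2),
                   rtol = rtol, atol = atol, method = method),
      warning = function(w) stop(
        "ODE solver failed (", conditionMessage(w), ") with K1D = ",
        signif(params$K1D, 4), ", VT = ", signif(params$VT, 4),
        ", fND = ", signif(params$fND, 4), call. = FALSE))
    y <- sol[nrow(sol), -1]
    names(y) <- c("C_ND", "C_S", "D_ND", "O")
    out <- if (is.null(out)) sol else rbind(out[-nrow(out), , drop = FALSE], sol)
  }
  df <- as.data.frame(out)
  names(df) <- c("t", "C_ND", "C_S", "D_ND", "O")
  df
}

#' Simulate the tracer-drug competition model
#'
#' Integrates the four-state competition system -- non-displaceable tracer
#' `C_ND`, specifically bound tracer `C_S`, non-displaceable drug `D_ND` and
#' target occupancy `O` -- driven by the tracer parent plasma input `C_P` and
#' the drug plasma input `D_P`. Tracer states start at zero at each
#' injection; drug states are carried continuously across the inter-scan gap
#' on the absolute study clock. A stiff-capable solver is used (the fixed
#' dissociation rates near 5/min make the binding exchange much faster than
#' the 120-min scan).
#'
#' @param params A [kinetic_parameters()] object.
#' @param tracer_input A [sampled_curve()] of parent plasma tracer on the
#'   absolute clock (zero between scans), or a list with elements `disp` and
#'   `post`, one curve per scan.
#' @param drug_input A [sampled_curve()] of drug plasma concentration
#'   (nmol/L), or `NULL` for a tracer-only simulation.
#' @param timeline A [study_timeline()].
#' @param grid Output times (absolute minutes); default: 0.25-min steps
#'   within scans, 5-min steps in the gap.
#' @param rtol,atol Solver tolerances.
#' @param method deSolve integration method (default `"lsoda"`).
#' @return A data frame of class `state_trajectory` with columns `t`,
#'   `C_ND`, `C_S` (Bq/cm^3), `D_ND` (nmol/L) and `O` (fraction).
#' @examples
#' p <- reference_truth("LEV", "putamen")
#' tl <- study_timeline(inj_post = NULL)
#' cp <- bolus_infusion_input()
#' traj <- simulate_system(p, cp, NULL, tl)
#' max(traj$O)  # 0: no drug given
#' @export
simulate_system <- function(params, tracer_input, drug_input, timeline,
                            grid = NULL, rtol = 1e-8, atol = 1e-10,
                            method = "lsoda") {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(timeline, "study_timeline"))
  if (is.null(grid)) grid <- default_sim_grid(timeline)
  plan <- make_sim_plan(tracer_input, drug_input, timeline, grid)
  for (seg in plan$segments)
    if (any(seg$cp[, 2] < 0) || any(seg$dp[, 2] < 0))
      stop("negative interpolated input values")
  df <- run_sim_plan(params, plan, rtol = rtol, atol = atol, method = method)
  structure(df, class = c("state_trajectory", "data.frame"),
            timeline = timeline)
}

#' Simulate the mechanistic (bimolecular) form of the model
#'
#' Integrates the competition model written in terms of the mechanistic rate
#' constants (`kon`, `koff`, `Bmax`, bound drug `D_S`) rather than the
#' reduced occupancy form. The tracer-mass term `C_S/M` is treated as
#' negligible, as in the reduced form. Used as an independent equivalence
#' check of the parameter transformation: both forms must produce the same
#' trajectories.
#'
#' @inheritParams simulate_system
#' @return A `state_trajectory` data frame (with `O = D_S / Bmax`).
#' @export
simulate_mechanistic <- function(params, tracer_input, drug_input, timeline,
                                 grid = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(timeline, "study_timeline"))
  if (is.null(grid)) grid <- default_sim_grid(timeline)
  plan <- make_sim_plan(tracer_input, drug_input, timeline, grid)
  k <- params$constants
  out <- NULL
  y <- c(C_ND = 0, C_S = 0, D_ND = 0, D_S = 0)
  for (seg in plan$segments) {
    if (seg$reset_tracer) y[c("C_ND", "C_S")] <- 0
    d <- derive_secondary(params, seg$scan)
    cp_f <- approx_forcing(seg$cp)
    dp_f <- approx_forcing(seg$dp)
    K1 <- params[[paste0("K1_", seg$scan)]]
    rhs <- function(t, y, p) {
      free <- d$Bmax - y[4]              # C_S/M dropped
      bind_t <- params$fND * d$kon * free * y[1] - k$koff * y[2]
      bind_d <- k$fNDD * d$konD * free * y[3] - k$koffD * y[4]
      list(c(K1 * cp_f(t) - d$k2 * y[1] - bind_t,
             bind_t,
             params$K1D * dp_f(t) - d$k2D * y[3] - bind_d,
             bind_d))
    }
    sol <- deSolve::ode(y = y, times = seg$times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol, method = "lsoda")
    y <- sol[nrow(sol), -1]
    names(y) <- c("C_ND", "C_S", "D_ND", "D_S")
    out <- if (is.null(out)) sol else rbind(out[-nrow(out), , drop = FALSE], sol)
  }
  df <- as.data.frame(out)
  names(df) <- c("t", "C_ND", "C_S", "D_ND", "D_S")
  df$O <- df$D_S / derive_secondary(params, "disp")$Bmax
  structure(df[, c("t", "C_ND", "C_S", "D_ND", "O")],
            class = c("state_trajectory", "data.frame"), timeline = timeline)
}

approx_forcing <- function(tab) {
  if (nrow(tab) == 1L) {
    v <- tab[1, 2]
    return(function(t) rep(v, length(t)))
  }
  function(t) approx(tab[, 1], tab[, 2], xout = t, rule = 2)$y
}

#' Fixed-step fourth-order Runge-Kutta integration of the competition model
#'
#' A deliberately simple fixed-step RK4 integrator for the reduced-form
#' system, independent of the adaptive stiff solver behind
#' [simulate_system()]. Intended as a brute-force cross-check: at a small
#' step (0.001 min) it should agree with the stiff solver to well under 0.1%.
#' Single-scan timelines only.
#'
#' @inheritParams simulate_system
#' @param dt Fixed step size in minutes.
#' @param grid Output times; values are reported at the nearest step.
#' @return A `state_trajectory` data frame.
#' @export
simulate_fixed_step <- function(params, tracer_input, drug_input, timeline,
                                grid = NULL, dt = 0.001) {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(timeline, "study_timeline"))
  if (!is.null(timeline$inj_post))
    stop("simulate_fixed_step supports single-scan timelines only")
  if (is.null(grid)) grid <- default_sim_grid(timeline)
  t0 <- timeline$inj_disp
  t1 <- max(grid)
  n <- ceiling((t1 - t0) / dt)
  # inputs precomputed at half-step resolution
  th <- t0 + seq(0, by = dt / 2, length.out = 2L * n + 1L)
  cpv <- if (is.null(tracer_input)) numeric(2L * n + 1L) else
    interpolate_curve(if (is.list(tracer_input) &&
                          !inherits(tracer_input, "sampled_curve"))
      tracer_input$disp else tracer_input, th)
  dpv <- if (is.null(drug_input)) numeric(2L * n + 1L) else
    interpolate_curve(drug_input, th)

  pp <- segment_parms(params, "disp")
  K1 <- pp[["K1"]]; k2 <- pp[["k2"]]; koff <- pp[["koff"]]
  bterm <- pp[["bterm"]]; K1D <- pp[["K1D"]]; k2D <- pp[["k2D"]]
  koffD <- pp[["koffD"]]; Bmax <- pp[["Bmax"]]; ratioD <- pp[["ratioD"]]
  rhs <- function(y, cp, dp) {
    sb <- bterm * (1 - y[4]) * y[1] - y[2]
    db <- ratioD * (1 - y[4]) * y[3] - y[4]
    c(K1 * cp - k2 * y[1] - koff * sb,
      koff * sb,
      K1D * dp - k2D * y[3] - koffD * Bmax * db,
      koffD * db)
  }
  y <- c(0, 0, 0, 0)
  keep <- matrix(NA_real_, nrow = n + 1L, ncol = 4L)
  keep[1L, ] <- y
  for (i in seq_len(n)) {
    j <- 2L * i - 1L                      # index of t_i in half grid
    k1v <- rhs(y, cpv[j], dpv[j])
    k2v <- rhs(y + dt / 2 * k1v, cpv[j + 1L], dpv[j + 1L])
    k3v <- rhs(y + dt / 2 * k2v, cpv[j + 1L], dpv[j + 1L])
    k4v <- rhs(y + dt * k3v, cpv[j + 2L], dpv[j + 2L])
    y <- y + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    keep[i + 1L, ] <- y
  }
  tfull <- t0 + dt * (0:n)
  idx <- pmin(pmax(round((grid - t0) / dt), 0), n) + 1L
  df <- data.frame(t = tfull[idx], C_ND = keep[idx, 1L], C_S = keep[idx, 2L],
                   D_ND = keep[idx, 3L], O = keep[idx, 4L])
  structure(df, class = c("state_trajectory", "data.frame"),
            timeline = timeline)
}

#' Export a trajectory as tidy CSV
#'
#' @param traj A `state_trajectory`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "state_trajectory"))
  write.csv(as.data.frame(traj), file, row.names = FALSE)
  invisible(file)
}
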