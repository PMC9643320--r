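#' Representative ground-truth parameter sets
#'
#' Median 5p estimates from human SV2A displacement studies, used as
#' realistic ground truth when generating synthetic subjects: for each drug
#' and region, the drug delivery rate `K1D`, tracer `VT`, `fND` and per-scan
#' `K1`. The nominal tracer plasma free fraction is 0.30 for both scans.
#'
#' @param drug `"LEV"` or `"BRV"`.
#' @param region `"putamen"`, `"frontal"` or `"cerebellum"`.
#' @param fP Nominal tracer plasma free fraction for both scans.
#' @param constants Optional [fixed_constants()] override.
#' @return A [kinetic_parameters()] object.
#' @examples
#' reference_truth("BRV", "putamen")
#' @export
reference_truth <- function(drug = c("LEV", "BRV"),
                            region = c("putamen", "frontal", "cerebellum"),
                            fP = 0.30, constants = NULL) {
  drug <- match.arg(drug)
  region <- match.arg(region)
  tab <- reference_truth_table()
  row <- tab[tab$drug == drug & tab$region == region, ]
  if (is.null(constants)) constants <- fixed_constants(drug)
  kinetic_parameters(K1_disp = row$K1_disp, K1_post = row$K1_post,
                     VT = row$VT, fND = row$fND,
                     K1D = k1d_from_uL(row$K1D_uL),
                     fP_disp = fP, fP_post = fP, constants = constants)
}

#' @rdname reference_truth
#' @return `reference_truth_table()`: a data frame with one row per drug and
#'   region (`K1D_uL` in uL/cm^3/min, the rest in the units of
#'   [kinetic_parameters()]).
#' @export
reference_truth_table <- function() {
  data.frame(
    drug   = rep(c("LEV", "BRV"), each = 3),
    region = rep(c("putamen", "frontal", "cerebellum"), 2),
    K1D_uL = c(5.2, 5.1, 4.0, 88.3, 72.9, 43.9),
    VT     = c(21.6, 18.7, 13.7, 21.5, 18.3, 13.5),
    fND    = c(0.076, 0.088, 0.099, 0.089, 0.105, 0.094),
    K1_disp = c(0.47, 0.43, 0.37, 0.46, 0.44, 0.37),
    K1_post = c(0.49, 0.43, 0.36, 0.46, 0.42, 0.35),
    stringsAsFactors = FALSE)
}

#' Two-compartment drug disposition parameters
#'
#' Plausible human disposition parameters for the synthetic drug plasma
#' model (a stand-in: real studies measure drug plasma directly). `V1` in
#' litres, micro rate constants in 1/min, molecular weight in g/mol.
#'
#' @param drug `"LEV"` or `"BRV"`.
#' @return A list with `V1`, `k10`, `k12`, `k21`, `MW`.
#' @export
drug_pk_params <- function(drug = c("LEV", "BRV")) {
  drug <- match.arg(drug)
  switch(drug,
    LEV = list(V1 = 25, k10 = 0.0020, k12 = 0.020, k21 = 0.025, MW = 170.21),
    BRV = list(V1 = 30, k10 = 0.0015, k12 = 0.030, k21 = 0.040, MW = 212.29))
}

#' Synthetic study design
#'
#' The conditions of one synthetic displacement + post-dose study: drug and
#' dose, a 5-min intravenous infusion starting 60 min after tracer injection
#' (80-min variant supported), a post-dose scan 4.5 h after dosing, the
#' 33-frame/120-min schedule, bolus + infusion tracer administration with
#' `Kbol = 150` min, two-compartment drug disposition, count-statistics TAC
#' noise, and a seed fixing all randomness.
#'
#' @param drug `"LEV"` or `"BRV"`.
#' @param dose_mg Drug dose in mg.
#' @param infusion_start Drug infusion start, minutes post-injection.
#' @param infusion_duration Infusion length, minutes.
#' @param post_dose_delay Post-dose injection time, minutes after
#'   `infusion_start` (default 270 = 4.5 h).
#' @param frames [frame_schedule()] per scan.
#' @param Kbol Tracer bolus-to-infusion ratio, minutes.
#' @param tracer_shape [tracer_input_shape()].
#' @param pk [drug_pk_params()] list.
#' @param occupancy_target Equilibrium occupancy implied by the drug plasma
#'   level at the end of the displacement scan; the drug curve amplitude is
#'   calibrated to reach it. `NULL` disables calibration (raw linear PK).
#'   Sensible values lie in 0.6-0.95.
#' @param noise_scale TAC noise scale (0 = noiseless), see [add_noise()].
#' @param fP Nominal tracer plasma free fraction per scan.
#' @param pb_ratio Whole-blood-to-plasma radioactivity ratio used to
#'   synthesize the whole-blood curve from total plasma.
#' @param pf_tail,pf_tau Parent-fraction model `pf(t) = pf_tail +
#'   (1 - pf_tail) exp(-t / pf_tau)` (t minutes since injection).
#' @param seed Integer seed fixing all randomness of [generate_subject()].
#' @return Object of class `study_design`.
#' @export
study_design <- function(drug = c("LEV", "BRV"),
                         dose_mg = if (match.arg(drug) == "LEV") 1500 else 200,
                         infusion_start = 60, infusion_duration = 5,
                         post_dose_delay = 270,
                         frames = frame_schedule(), Kbol = 150,
                         tracer_shape = tracer_input_shape(),
                         pk = drug_pk_params(match.arg(drug)),
                         occupancy_target = 0.85,
                         noise_scale = 3, fP = 0.30, pb_ratio = 0.91,
                         pf_tail = 0.22, pf_tau = 45,
                         seed = 1L) {
  drug <- match.arg(drug)
  scan_duration <- max(frames$start + frames$duration)
  if (infusion_start < 0 || infusion_start + infusion_duration > scan_duration)
    stop("drug infusion must lie inside the displacement scan")
  if (post_dose_delay + infusion_start <= scan_duration)
    stop("post-dose scan must start after the displacement scan ends")
  if (!is.null(occupancy_target) &&
      (occupancy_target <= 0 || occupancy_target >= 1))
    stop("occupancy_target must lie in (0, 1)")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  structure(list(drug = drug, dose_mg = dose_mg,
                 infusion_start = infusion_start,
                 infusion_duration = infusion_duration,
                 post_dose_delay = post_dose_delay,
                 inj_post = infusion_start + post_dose_delay,
                 scan_duration = scan_duration, frames = frames, Kbol = Kbol,
                 tracer_shape = tracer_shape, pk = pk,
                 occupancy_target = occupancy_target,
                 noise_scale = noise_scale, fP = fP, pb_ratio = pb_ratio,
                 pf_tail = pf_tail, pf_tau = pf_tau, seed = seed),
            class = "study_design")
}

#' Timeline implied by a study design
#' @param design A [study_design()].
#' @return A [study_timeline()].
#' @export
design_timeline <- function(design) {
  study_timeline(inj_disp = 0, inj_post = design$inj_post,
                 scan_duration = design$scan_duration,
                 infusion_start = design$infusion_start,
                 infusion_duration = design$infusion_duration)
}

#' Closed-form two-compartment concentration under zero-order infusion
#' @noRd
two_comp_infusion <- function(t, rate_nmol_min, t_start, duration,
                              V1, k10, k12, k21) {
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  A <- (alpha - k21) / (V1 * (alpha - beta))
  B <- (k21 - beta) / (V1 * (alpha - beta))
  tt <- t - t_start
  term <- function(coef, lam) {
    during <- coef / lam * (1 - exp(-lam * pmin(pmax(tt, 0), duration)))
    after <- exp(-lam * pmax(tt - duration, 0))
    during * after
  }
  # rate [nmol/min] * A [1/L] / lam [1/min] -> nmol/L
  rate_nmol_min * (term(A, alpha) + term(B, beta))
}

#' Generate the synthetic drug plasma input
#'
#' Zero-order 5-min infusion into a linear two-compartment disposition model,
#' evaluated in closed form (biexponential). When the design carries an
#' `occupancy_target`, the curve amplitude is rescaled so that the
#' equilibrium occupancy implied by the plasma level at the end of the
#' displacement scan, `fPD D_P / (KDD + fPD D_P)`, equals the target.
#' Observations are sampled at 1, 3, 5, 6, 8, 10, 15, 20, 30, 45 and 60 min
#' after the infusion start plus immediately before, in the middle and at the
#' end of the post-dose scan.
#'
#' @param design A [study_design()].
#' @param constants [fixed_constants()] (used for the calibration target).
#' @return A list with `fun` (continuous concentration, nmol/L, function of
#'   absolute time), `observed` (a drug-plasma [sampled_curve()] at the
#'   sampling schedule), `dense` (a densely sampled curve for simulation) and
#'   `scale` (the calibration factor applied to the linear-PK curve).
#' @export
generate_drug_pk <- function(design, constants = fixed_constants(design$drug)) {
  stopifnot(inherits(design, "study_design"))
  pk <- design$pk
  dose_nmol <- design$dose_mg / pk$MW * 1e6
  rate <- dose_nmol / design$infusion_duration
  base <- function(t) two_comp_infusion(t, rate, design$infusion_start,
                                        design$infusion_duration,
                                        pk$V1, pk$k10, pk$k12, pk$k21)
  scale <- 1
  if (!is.null(design$occupancy_target)) {
    t_cal <- design$scan_duration        # end of the displacement scan
    c_cal <- base(t_cal)
    if (c_cal <= 0)
      stop("drug concentration is zero at the calibration time; ",
           "occupancy target unattainable")
    o <- design$occupancy_target
    d_req <- constants$KDD * o / (constants$fPD * (1 - o))
    scale <- d_req / c_cal
  }
  fun <- function(t) scale * base(t)
  obs_t <- c(design$infusion_start,
             design$infusion_start + c(1, 3, 5, 6, 8, 10, 15, 20, 30, 45, 60),
             design$inj_post + c(0, design$scan_duration / 2,
                                 design$scan_duration))
  observed <- sampled_curve(obs_t, fun(obs_t), kind = "drug-plasma")
  dense_t <- sort(unique(c(
    design$infusion_start,
    seq(design$infusion_start, design$infusion_start + 30, by = 0.25),
    seq(design$infusion_start + 30, design$inj_post + design$scan_duration,
        by = 2))))
  dense <- sampled_curve(dense_t, fun(dense_t), kind = "drug-plasma")
  list(fun = fun, observed = observed, dense = dense, scale = scale)
}

#' Add count-statistics noise to a TAC
#'
#' Independent Gaussian noise per frame with standard deviation
#' `scale * sqrt(value * exp(lambda t_mid) / duration)`, the usual
#' variance surrogate for decay-corrected PET data (`lambda = ln 2 / 20.4`
#' per minute for carbon-11; `t_mid` is the frame midpoint relative to the
#' scan's injection). Negative results are clipped at zero; the number of
#' clipped frames is recorded in attribute `"clipped"`.
#'
#' @param tac Noiseless frame values, Bq/cm^3.
#' @param frames The [frame_schedule()] of the scan.
#' @param scale Noise scale (>= 0; 0 returns `tac` unchanged).
#' @param seed Optional integer seed.
#' @param lambda Isotope decay constant, 1/min.
#' @return Noisy TAC with attribute `"clipped"`.
#' @export
add_noise <- function(tac, frames, scale, seed = NULL,
                      lambda = log(2) / 20.4) {
  stopifnot(inherits(frames, "frame_schedule"), length(tac) == nrow(frames))
  if (scale < 0) stop("noise scale must be >= 0")
  if (scale == 0) return(structure(tac, clipped = 0L))
  if (!is.null(seed)) set.seed(seed)
  sd <- scale * sqrt(pmax(tac, 0) * exp(lambda * frames$mid) / frames$duration)
  noisy <- tac + rnorm(length(tac), 0, sd)
  clipped <- sum(noisy < 0)
  structure(pmax(noisy, 0), clipped = clipped)
}

#' Generate a complete synthetic subject dataset
#'
#' Composes the forward model into a full two-scan dataset: bolus + infusion
#' tracer input per scan (with a declining parent fraction and a whole-blood
#' curve proportional to total plasma), the calibrated drug infusion PK, the
#' frame-averaged model TACs with count-statistics noise, and the ground
#' truth recorded in the `truth` field.
#'
#' @param design A [study_design()].
#' @param truth A [kinetic_parameters()] object, or a named list of them
#'   (one per region). Defaults to the drug's putamen [reference_truth()].
#' @param id Subject identifier.
#' @return A [subject_dataset()] with `truth` attached.
#' @examples
#' \donttest{
#' ds <- generate_subject(study_design("LEV", noise_scale = 0, seed = 7))
#' names(ds$disp$tacs)
#' }
#' @export
generate_subject <- function(design,
                             truth = reference_truth(design$drug, "putamen",
                                                     fP = design$fP),
                             id = paste0(design$drug, "-", design$seed)) {
  stopifnot(inherits(design, "study_design"))
  if (inherits(truth, "kinetic_parameters")) truth <- list(putamen = truth)
  stopifnot(length(truth) > 0, !is.null(names(truth)))
  constants <- truth[[1L]]$constants
  tl <- design_timeline(design)
  set.seed(design$seed)

  drug <- generate_drug_pk(design, constants)

  scans <- list()
  for (scan in c("disp", "post")) {
    inj <- if (scan == "disp") 0 else design$inj_post
    total <- bolus_infusion_input(design$tracer_shape, design$Kbol,
                                  design$scan_duration, t0 = inj)
    pf_t <- total$times - inj
    pf <- sampled_curve(total$times,
                        design$pf_tail +
                          (1 - design$pf_tail) * exp(-pf_t / design$pf_tau),
                        kind = "parent-fraction")
    parent <- metabolite_correct(total, pf)
    wb <- sampled_curve(total$times, design$pb_ratio * total$values,
                        kind = "whole-blood", zero_before = TRUE)
    scans[[scan]] <- list(inj = inj, total = total, pf = pf,
                          parent = parent, wb = wb)
  }

  tracer_input <- list(disp = scans$disp$parent, post = scans$post$parent)
  grid <- sort(unique(c(frame_grid(design$frames, 0),
                        frame_grid(design$frames, design$inj_post),
                        seq(design$scan_duration, design$inj_post, by = 5))))
  tacs <- list(disp = list(), post = list())
  noiseless <- list(disp = list(), post = list())
  # The drug forcing is the linearly interpolated plasma-sample curve: that
  # is the model's definition of D_P on real data too, so noiseless synthetic
  # TACs are exactly representable by the fitted model.
  for (rg in names(truth)) {
    traj <- simulate_system(truth[[rg]], tracer_input, drug$observed, tl,
                            grid = grid)
    for (scan in c("disp", "post")) {
      clean <- predict_pet(traj, scans[[scan]]$wb, design$frames,
                           vB = constants$vB, t_offset = scans[[scan]]$inj)
      noiseless[[scan]][[rg]] <- clean
      tacs[[scan]][[rg]] <- add_noise(clean, design$frames,
                                      design$noise_scale)
    }
  }

  mk_scan <- function(scan, role)
    scan_data(design$frames, tacs[[scan]], scans[[scan]]$parent,
              scans[[scan]]$wb, fP = design$fP,
              injection_time = scans[[scan]]$inj, role = role,
              total_plasma = scans[[scan]]$total,
              parent_fraction = scans[[scan]]$pf)

  ds <- subject_dataset(
    disp = mk_scan("disp", "displacement"),
    post = mk_scan("post", "post-dose"),
    drug_input = drug$observed,
    dose = list(drug = design$drug, dose_mg = design$dose_mg,
                infusion_start = design$infusion_start,
                infusion_duration = design$infusion_duration),
    constants = constants,
    truth = truth, id = id)
  attr(ds, "design") <- design
  attr(ds, "noiseless") <- noiseless
  attr(ds, "drug_dense") <- drug$dense
  ds
}
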