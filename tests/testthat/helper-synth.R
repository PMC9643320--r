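# Shared fixture builders. Everything is generated in code; no stored data.

# constant-valued curve on a wide support
const_curve <- function(value, kind = "tracer-plasma", t_end = 6000) {
  sampled_curve(c(0, t_end), c(value, value), kind = kind,
                zero_before = FALSE)
}

# noiseless synthetic subject from the drug's reference truth (one region)
noiseless_subject <- function(drug, region = "putamen", seed = 11, ...) {
  des <- study_design(drug, noise_scale = 0, seed = seed, ...)
  generate_subject(des, truth = setNames(list(reference_truth(drug, region)),
                                         region))
}

# random but physically valid parameter draw for property tests
random_params <- function(drug = sample(c("LEV", "BRV"), 1)) {
  repeat {
    p <- try(kinetic_parameters(
      K1_disp = runif(1, 0.2, 0.6), K1_post = runif(1, 0.2, 0.6),
      VT = runif(1, 8, 25), fND = runif(1, 0.05, 0.2),
      K1D = 10^runif(1, -3, -1),
      fP_disp = runif(1, 0.2, 0.4), fP_post = runif(1, 0.2, 0.4),
      constants = fixed_constants(drug)), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

# four-subject study with a common true K1D per drug (tracer parameters
# jittered log-normally per subject); used by the bound-search checks
make_bound_study <- function(R_true, seed0, lev_k1d_uL = 5.2) {
  brv_k1d_uL <- R_true * lev_k1d_uL
  mk <- function(drug, k1d_uL, seed) {
    set.seed(seed)
    base <- reference_truth(drug, "putamen")
    jit <- exp(rnorm(3, 0, 0.08))
    tr <- kinetic_parameters(base$K1_disp * jit[1], base$K1_post * jit[1],
                             base$VT * jit[2], base$fND * jit[3],
                             k1d_from_uL(k1d_uL),
                             constants = base$constants)
    generate_subject(study_design(drug, seed = seed),
                     truth = list(putamen = tr), id = paste0(drug, seed))
  }
  list(levs = lapply(1:4, function(i) mk("LEV", lev_k1d_uL, seed0 + i)),
       brvs = lapply(1:4, function(i) mk("BRV", brv_k1d_uL, seed0 + 10 + i)),
       R = R_true)
}

# run both directed searches (count-statistics weights match the synthetic
# noise model, so the pooled F test is calibrated) and return the ratio bound
study_ratio_bound <- function(study, lev_k1d_uL = 5.2) {
  bl <- k1d_bound_search(study$brvs, "putamen", "lower", weights = "counts",
                         refine = TRUE,
                         refine_tol = 0.01 * study$R * lev_k1d_uL,
                         multistart_K1D = 0.03)
  lu <- k1d_bound_search(study$levs, "putamen", "upper", weights = "counts",
                         refine = TRUE, refine_tol = 0.1,
                         multistart_K1D = 0.005)
  list(ratio = k1d_ratio_bound(bl, lu), brv_lower = bl, lev_upper = lu)
}

# synthetic one-tissue-compartment frame data for 1TC/F-test checks:
# returns the pieces needed by fit_1tc plus the noiseless frame values
make_1tc_data <- function(K1 = 0.45, VT = 18, vB = 0.05, tmax = 60,
                          dt = 0.05) {
  frames <- frame_schedule()
  keep <- frames$start + frames$duration <= tmax
  cp <- bolus_infusion_input()
  k2 <- K1 / VT
  tg <- seq(0, tmax, by = dt)
  cpv <- interpolate_curve(cp, tg)
  E <- exp(-k2 * dt)
  inp <- c(0, dt / 2 * (cpv[-1] + E * cpv[-length(cpv)]))
  ct <- K1 * as.numeric(stats::filter(inp, E, method = "recursive"))
  wb <- sampled_curve(tg, 0.91 * cpv, kind = "whole-blood",
                      zero_before = FALSE)
  sig <- (1 - vB) * ct + vB * interpolate_curve(wb, tg)
  fr <- frames[keep, ]
  pet <- vapply(seq_len(nrow(fr)), function(i) {
    ii <- which(tg >= fr$start[i] - 1e-9 &
                tg <= fr$start[i] + fr$duration[i] + 1e-9)
    sv2akin:::trapz_mean(tg[ii], sig[ii])
  }, numeric(1))
  list(frames = frames, pet = pet, plasma = cp, wb = wb, K1 = K1, VT = VT,
       vB = vB, n = nrow(fr))
}
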