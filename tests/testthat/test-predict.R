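make_traj <- function(t, cnd, cs = 0 * t, dnd = 0 * t, o = 0 * t) {
  structure(data.frame(t = t, C_ND = cnd, C_S = cs, D_ND = dnd, O = o),
            class = c("state_trajectory", "data.frame"))
}

test_that("frame averaging mixes tissue and whole blood through vB", {
  t <- seq(0, 120, by = 0.1)
  frames <- frame_schedule()
  # constant tissue and whole blood
  traj <- make_traj(t, cnd = rep(700, length(t)), cs = rep(300, length(t)))
  wb <- const_curve(2000, "whole-blood", 120)
  expect_equal(predict_pet(traj, wb, frames, vB = 0.05),
               rep(0.95 * 1000 + 0.05 * 2000, 33))
  # vB = 0: tissue only, no whole blood needed
  expect_equal(predict_pet(traj, NULL, frames, vB = 0), rep(1000, 33))
  # linear trajectory: frame average equals the midpoint value
  traj2 <- make_traj(t, cnd = 100 + 5 * t)
  expect_equal(predict_pet(traj2, NULL, frames, vB = 0), 100 + 5 * frames$mid)
  # frames outside the trajectory span
  expect_error(predict_pet(make_traj(seq(0, 60, 0.1), seq(0, 60, 0.1)),
                           NULL, frames, vB = 0), "covers")
})

test_that("occupancy metrics recover closed-form crossing times", {
  lam <- log(2) / 3
  t <- seq(0, 400, by = 0.05)
  dose <- 60
  o <- ifelse(t < dose, 0, 0.8 * (1 - exp(-lam * (t - dose))))
  traj <- make_traj(t, cnd = 0 * t, o = o)
  m <- occupancy_metrics(traj, dose_time = dose)
  expect_true(m$defined)
  expect_equal(m$O_max_pct, 100 * max(o))
  expect_equal(m$t_half, 3, tolerance = 1e-2)   # O_max/2 at t_half = ln2/lam
  expect_lt(m$t_half, m$t_max)                  # monotone trajectory

  # all-zero occupancy is flagged undefined, not reported as zeros
  m0 <- occupancy_metrics(make_traj(t, cnd = 0 * t), dose_time = dose)
  expect_false(m0$defined)
  expect_true(is.na(m0$t_max) && is.na(m0$t_half))
})

test_that("faster drug entry shortens the time to half occupancy", {
  # same equilibrium plateau, K1D differing 15-fold: the high-K1D (BRV-like)
  # run must reach half occupancy sooner in every replicate
  tl <- study_timeline(inj_post = NULL)
  cp <- bolus_infusion_input()
  for (seed in 1:3) {
    des <- study_design("LEV", seed = seed)
    dp <- generate_drug_pk(des, fixed_constants("LEV"))$dense
    base <- reference_truth("LEV", "putamen")
    grid <- seq(0, 120, by = 0.25)
    t_half <- sapply(c(base$K1D, 15 * base$K1D), function(k1d) {
      p <- kinetic_parameters(base$K1_disp, base$K1_post, base$VT, base$fND,
                              k1d, constants = base$constants)
      occupancy_metrics(simulate_system(p, cp, dp, tl, grid = grid),
                        dose_time = des$infusion_start)$t_half
    })
    expect_lt(t_half[2], t_half[1])
  }
})
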