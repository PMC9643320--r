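test_that("model configurations float the documented parameter sets", {
  expect_setequal(model_config("5p")$floating,
                  c("K1_disp", "K1_post", "VT", "fND", "K1D"))
  expect_setequal(model_config("7p")$floating,
                  c(model_config("5p")$floating, "koff", "koffD"))
  expect_setequal(model_config("6p:fNDD")$floating,
                  c(model_config("5p")$floating, "fNDD"))
  expect_length(model_config("13p")$floating, 13)
  expect_error(model_config("6p:VT"), "one of")
  expect_error(model_config("4p"), "unknown")
})

test_that("noiseless data generated by the model are recovered exactly", {
  ds <- noiseless_subject("LEV", seed = 21)
  f <- fit_joint(ds, "putamen")
  tr <- ds$truth$putamen
  truth <- c(K1_disp = tr$K1_disp, K1_post = tr$K1_post, VT = tr$VT,
             fND = tr$fND, K1D = tr$K1D)
  expect_true(f$converged)
  expect_equal(f$n, 66)
  expect_true(all(abs(f$estimates[names(truth)] - truth) / truth < 0.01))
  # zero-residual optimum: SS at the fit can be no worse than at the truth
  expect_lt(f$SS, 1)
  expect_lt(f$SS / sum(ds$disp$tacs$putamen^2), 1e-10)
})

test_that("1TC fit recovers parameters from 1TC-generated data", {
  d <- make_1tc_data(K1 = 0.45, VT = 18)
  f <- fit_1tc(d$pet, d$frames, d$plasma, d$wb, vB = d$vB)
  expect_true(f$converged)
  expect_equal(f$K1, 0.45, tolerance = 1e-3)
  expect_equal(f$VT, 18, tolerance = 1e-3)
  expect_equal(f$n, d$n)
  expect_error(fit_1tc(d$pet[1:5], d$frames[1:5, ], d$plasma, d$wb),
               "at least 10 frames")
})

test_that("1TC comparator agrees with the extended model on drug-free data", {
  # simulate the full competition model without drug, fit 1TC to the first
  # 60 min: VT within a few percent, K1 within 10%
  p <- reference_truth("LEV", "putamen")
  tl <- study_timeline(inj_post = NULL)
  cp <- bolus_infusion_input()
  wb <- sampled_curve(cp$times, 0.91 * cp$values, kind = "whole-blood",
                      zero_before = TRUE)
  frames <- frame_schedule()
  traj <- simulate_system(p, cp, NULL, tl, grid = frame_grid(frames))
  tac <- predict_pet(traj, wb, frames, vB = p$constants$vB)
  f <- fit_1tc(tac, frames, cp, wb, vB = p$constants$vB)
  expect_equal(f$VT, p$VT, tolerance = 0.05)
  expect_equal(f$K1, p$K1_disp, tolerance = 0.10)
})

test_that("standard errors match closed forms and information scaling", {
  set.seed(5)
  n <- 400
  x <- runif(n, 0, 2)
  sigma <- 0.3
  y <- 1.7 * x + rnorm(n, 0, sigma)
  a_hat <- sum(x * y) / sum(x^2)
  r <- y - a_hat * x
  se <- standard_errors(matrix(x, ncol = 1), r, estimates = a_hat)
  # closed form: sigma_hat / sqrt(sum x^2)
  sigma_hat <- sqrt(sum(r^2) / (n - 1))
  expect_equal(unname(se$se), sigma_hat / sqrt(sum(x^2)), tolerance = 1e-12)
  expect_equal(unname(se$rse), 100 * se$se / a_hat, ignore_attr = TRUE)

  # duplicating every observation shrinks the SE by 1/sqrt(2) (up to the
  # residual-dof factor, which is 1 here asymptotically)
  se2 <- standard_errors(matrix(c(x, x), ncol = 1), c(r, r))
  expect_equal(unname(se2$se / se$se),
               sqrt((n - 1) / (2 * n - 1)), tolerance = 1e-12)

  # singular normal matrix: flagged, not fatal
  s <- standard_errors(matrix(0, nrow = 10, ncol = 1), rnorm(10))
  expect_true(s$singular)
  expect_true(is.na(s$se))
})

test_that("reported SE tracks the Monte-Carlo spread of 1TC estimates", {
  set.seed(77)
  d <- make_1tc_data(K1 = 0.45, VT = 18)
  sd_noise <- 0.01 * max(d$pet)
  keep <- 200
  k1 <- se <- numeric(keep)
  for (i in seq_len(keep)) {
    y <- d$pet + rnorm(length(d$pet), 0, sd_noise)
    f <- fit_1tc(y, d$frames, d$plasma, d$wb, vB = d$vB, weights = "uniform")
    k1[i] <- f$K1
    se[i] <- f$se[["K1"]]
  }
  expect_equal(median(se), sd(k1), tolerance = 0.2)
})

test_that("allowing K1 to change at displacement does not alter K1 or K1D", {
  ds <- noiseless_subject("LEV", seed = 22)
  f <- fit_joint(ds, "putamen",
                 config = model_config("5p", split_K1_disp = TRUE))
  tr <- ds$truth$putamen
  expect_equal(f$estimates[["K1_disp"]], tr$K1_disp, tolerance = 0.01)
  expect_equal(f$estimates[["K1_disp2"]], tr$K1_disp, tolerance = 0.03)
  expect_equal(f$estimates[["K1D"]], tr$K1D, tolerance = 0.02)
})

test_that("richer nested configurations never fit worse", {
  ds <- generate_subject(study_design("LEV", seed = 31))
  f5 <- fit_joint(ds, "putamen")
  st <- as.list(f5$estimates)
  f6 <- fit_joint(ds, "putamen", config = model_config("6p:koff"),
                  start = c(st, list(koff = ds$constants$koff)))
  f7 <- fit_joint(ds, "putamen", config = model_config("7p"),
                  start = c(st, list(koff = ds$constants$koff,
                                     koffD = ds$constants$koffD)))
  expect_lte(f6$SS, f5$SS + 1e-6 * f5$SS)
  expect_lte(f7$SS, f6$SS + 1e-6 * f6$SS)
})
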