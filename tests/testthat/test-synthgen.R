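test_that("drug plasma synthesis is linear in dose and calibrated on target", {
  # zero dose: identically zero curve (no calibration possible)
  des0 <- study_design("LEV", dose_mg = 0, occupancy_target = NULL)
  pk0 <- generate_drug_pk(des0)
  expect_true(all(pk0$observed$values == 0))

  # linear PK: doubling the dose doubles the concentration everywhere
  d1 <- study_design("LEV", dose_mg = 750, occupancy_target = NULL)
  d2 <- study_design("LEV", dose_mg = 1500, occupancy_target = NULL)
  tt <- seq(0, 400, by = 1)
  expect_equal(2 * generate_drug_pk(d1)$fun(tt), generate_drug_pk(d2)$fun(tt))

  # calibration: closed-form equilibrium occupancy at the displacement-scan
  # end equals the target
  des <- study_design("BRV", occupancy_target = 0.92)
  k <- fixed_constants("BRV")
  dp <- generate_drug_pk(des, k)
  o_cal <- k$fPD * dp$fun(des$scan_duration) /
    (k$KDD + k$fPD * dp$fun(des$scan_duration))
  expect_equal(o_cal, 0.92, tolerance = 1e-6)

  # observation schedule: 11 displacement samples + 3 post-dose samples
  expect_equal(length(dp$observed$times), 1 + 11 + 3)
  expect_error(study_design("LEV", occupancy_target = 1.2),
               "occupancy_target")
})

test_that("noiseless generation reproduces the forward model exactly and is seeded", {
  ds <- noiseless_subject("BRV", seed = 9)
  clean <- attr(ds, "noiseless")
  expect_equal(as.numeric(ds$disp$tacs$putamen), clean$disp$putamen)
  expect_equal(as.numeric(ds$post$tacs$putamen), clean$post$putamen)

  # recompute through the public simulation + prediction path
  tl <- dataset_timeline(ds)
  traj <- simulate_system(ds$truth$putamen,
                          list(disp = ds$disp$plasma, post = ds$post$plasma),
                          ds$drug_input, tl,
                          grid = sort(unique(c(
                            frame_grid(ds$disp$frames, 0),
                            frame_grid(ds$post$frames,
                                       ds$post$injection_time),
                            seq(tl$scan1_end, tl$inj_post, by = 5)))))
  tac <- predict_pet(traj, ds$disp$whole_blood, ds$disp$frames,
                     vB = ds$constants$vB)
  expect_equal(as.numeric(ds$disp$tacs$putamen), tac, tolerance = 1e-10)

  # determinism: identical seeds give identical datasets
  a <- generate_subject(study_design("LEV", seed = 77))
  b <- generate_subject(study_design("LEV", seed = 77))
  expect_identical(a$disp$tacs, b$disp$tacs)
  expect_identical(a$post$tacs, b$post$tacs)
  expect_identical(a$drug_input$values, b$drug_input$values)
  c2 <- generate_subject(study_design("LEV", seed = 78))
  expect_false(identical(a$disp$tacs, c2$disp$tacs))
})

test_that("TAC noise follows the count-statistics variance model", {
  frames <- frame_schedule()
  tac <- rep(20000, 33)
  expect_identical(as.numeric(add_noise(tac, frames, 0)), tac)
  expect_error(add_noise(tac, frames, -1), ">= 0")

  # empirical SD per frame matches scale*sqrt(value*exp(lambda*t_mid)/dur);
  # equal-duration equal-value frames get noisier later in the scan (decay)
  lam <- log(2) / 20.4
  theo <- 3 * sqrt(tac * exp(lam * frames$mid) / frames$duration)
  reps <- t(vapply(seq_len(1500),
                   function(i) as.numeric(add_noise(tac, frames, 3,
                                                    seed = 10000 + i)),
                   numeric(33)))
  emp <- apply(reps, 2, sd)
  expect_true(all(abs(emp - theo) / theo < 0.10))
  late5 <- which(frames$duration == 5)
  expect_true(all(diff(theo[late5]) > 0))
  expect_gt(cor(frames$mid[late5], emp[late5]), 0.9)

  # variance scales as 1/duration: two frames with equal value whose decay
  # factors are divided out
  fr2 <- frame_schedule(c(0, 1), c(1, 4))
  th2 <- 3 * sqrt(1000 * exp(lam * fr2$mid) / fr2$duration)
  reps2 <- t(vapply(seq_len(3000),
                    function(i) as.numeric(add_noise(c(1000, 1000), fr2, 3,
                                                     seed = 20000 + i)),
                    numeric(2)))
  emp2 <- apply(reps2, 2, sd)
  expect_equal(emp2[1] / emp2[2], th2[1] / th2[2], tolerance = 0.1)
})

test_that("default-noise studies recover the generating parameters", {
  # 10 subjects at the default noise level: median absolute errors within
  # 5% (VT, K1), 25% (K1D, the least identifiable parameter)
  errs <- list(VT = c(), K1 = c(), K1D = c(), fND = c())
  for (i in 1:10) {
    drug <- if (i <= 5) "LEV" else "BRV"
    ds <- generate_subject(study_design(drug, seed = 800 + i))
    f <- fit_joint(ds, "putamen")
    tr <- ds$truth$putamen
    errs$VT <- c(errs$VT, (f$estimates[["VT"]] - tr$VT) / tr$VT)
    errs$K1 <- c(errs$K1,
                 (f$estimates[["K1_disp"]] - tr$K1_disp) / tr$K1_disp)
    errs$K1D <- c(errs$K1D, (f$estimates[["K1D"]] - tr$K1D) / tr$K1D)
    errs$fND <- c(errs$fND, (f$estimates[["fND"]] - tr$fND) / tr$fND)
  }
  expect_lt(median(abs(errs$VT)), 0.05)
  expect_lt(median(abs(errs$K1)), 0.05)
  expect_lt(median(abs(errs$fND)), 0.15)
  expect_lt(median(abs(errs$K1D)), 0.25)
})
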