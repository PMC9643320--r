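test_that("derived secondary parameters satisfy their defining identities", {
  p <- kinetic_parameters(K1_disp = 0.47, K1_post = 0.49, VT = 20, fND = 0.1,
                          K1D = 5e-3, fP_disp = 0.4, fP_post = 0.4,
                          constants = fixed_constants("LEV"))
  d <- derive_secondary(p)
  expect_equal(d$Bmax, 3.4 * (20 * 0.1 / 0.4 - 1) / 0.1)  # = 136 nmol/L
  expect_equal(d$k2, 0.47 * 0.1 / 0.4)
  expect_equal(d$kon, p$constants$koff / p$constants$KD)
  expect_equal(d$konD, p$constants$koffD / p$constants$KDD)
  expect_equal(d$k2D, p$K1D * p$constants$fNDD / p$constants$fPD)

  # fND = fP collapses k2 to K1
  p2 <- kinetic_parameters(0.47, 0.49, VT = 20, fND = 0.3, K1D = 5e-3,
                           fP_disp = 0.3, fP_post = 0.3,
                           constants = fixed_constants("LEV"))
  expect_equal(derive_secondary(p2)$k2, p2$K1_disp)

  # per-scan values use the scan's K1/fP
  p3 <- kinetic_parameters(0.4, 0.5, VT = 20, fND = 0.1, K1D = 5e-3,
                           fP_disp = 0.3, fP_post = 0.25,
                           constants = fixed_constants("BRV"))
  expect_equal(derive_secondary(p3, "post")$k2, 0.5 * 0.1 / 0.25)
})

test_that("negative specific-binding capacity is rejected with diagnostics", {
  expect_error(
    kinetic_parameters(0.47, 0.49, VT = 2, fND = 0.1, K1D = 5e-3,
                       fP_disp = 0.3, fP_post = 0.3,
                       constants = fixed_constants("LEV")),
    "VT \\* fND / fP")
  p <- kinetic_parameters(0.47, 0.49, VT = 20, fND = 0.1, K1D = 5e-3,
                          constants = fixed_constants("LEV"))
  p$VT <- 2  # corrupt after construction
  expect_error(derive_secondary(p), "specific binding")
})

test_that("constants constructor enforces invariants and drug defaults", {
  lev <- fixed_constants("LEV")
  brv <- fixed_constants("BRV")
  expect_equal(c(lev$KD, lev$vB), c(3.4, 0.05))
  expect_equal(c(lev$fPD, lev$KDD, lev$fNDD, lev$koffD),
               c(0.90, 21000, 1.0, 4.9))
  expect_equal(c(brv$fPD, brv$KDD, brv$fNDD, brv$koffD),
               c(0.83, 2000, 0.88, 5.9))
  expect_error(fixed_constants("LEV", fPD = 1.2), "fPD")
  expect_error(fixed_constants("LEV", vB = 0.5), "vB")
  expect_error(fixed_constants("LEV", KDD = -1), "positive")
})

test_that("K1D unit conversion round-trips", {
  expect_equal(k1d_to_uL(k1d_from_uL(88.3)), 88.3)
  expect_equal(k1d_to_uL(0.0052), 5.2)
})
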