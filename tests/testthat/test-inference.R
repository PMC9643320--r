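test_that("F statistic and tail probability follow the nested-model formula", {
  # no improvement: F = 0, p = 1
  ft0 <- f_test(100, 100, 5, 7, 66)
  expect_equal(ft0$F, 0)
  expect_equal(ft0$p_value, 1)

  # worked example: F = (20/2)/(100/59) = 5.9
  ft <- f_test(120, 100, 5, 7, 66)
  expect_equal(ft$F, 5.9)
  expect_equal(ft$df1, 2)
  expect_equal(ft$df2, 59)
  # independent tail-probability route via the beta-distribution identity
  p_beta <- stats::pbeta(ft$df2 / (ft$df2 + ft$df1 * ft$F),
                         ft$df2 / 2, ft$df1 / 2)
  expect_equal(ft$p_value, p_beta, tolerance = 1e-12)

  expect_error(f_test(120, 100, 7, 5, 66), "nesting")
  expect_error(f_test(120, 100, 5, 7, 6), "exceed")
  expect_error(f_test(90, 100, 5, 7, 66), "not nested")
})

test_that("test-retest measure is antisymmetric and exact on examples", {
  expect_equal(test_retest(1, 1), 0)
  expect_equal(test_retest(1.2, 0.8), 0.4)
  expect_equal(test_retest(0.8, 1.2), -0.4)
  expect_equal(test_retest(3, 7), -test_retest(7, 3))
  expect_error(test_retest(0, 0), "positive")
})

# one noisy subject shared by the fit-dependent inference checks
lev_ds <- generate_subject(study_design("LEV", seed = 41))
lev_ref <- fit_joint(lev_ds, "putamen")

test_that("sensitivity scan reports zero change at factor one", {
  tab <- sensitivity_fixed_params(lev_ds, "putamen", "KDD", factor = 1,
                                  reference = lev_ref)
  expect_true(all(tab$pct_change == 0))
  expect_setequal(tab$quantity,
                  c("VT", "fND", "K1_disp", "K1_post", "K1D", "SS"))
})

test_that("an extra floating parameter cannot be significantly better on 5p data", {
  res <- sensitivity_one_extra(lev_ds, "putamen", "koffD",
                               reference = lev_ref)
  expect_lte(res$fit6$SS, lev_ref$SS + 1e-9 * lev_ref$SS)  # nesting
  expect_gt(res$ftest$p_value, 0.05)   # true model is the nested one
})

test_that("constraining K1D at its own estimate is never rejected", {
  g <- k1d_to_uL(lev_ref$estimates[["K1D"]])
  res <- k1d_bound_search(list(lev_ds), "putamen", "lower", grid = g,
                          refine = FALSE)
  expect_lt(res$F[1], 0.2)
  expect_gt(res$p[1], 0.9)
  expect_true(res$accepted[1])
  expect_equal(res$bound, g)
})
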