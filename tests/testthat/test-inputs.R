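test_that("curve interpolation is linear with the stated boundary policy", {
  cv <- sampled_curve(c(10, 20), c(4, 8), kind = "tracer-plasma",
                      zero_before = FALSE)
  expect_equal(interpolate_curve(cv, c(10, 20)), c(4, 8))  # exact at nodes
  expect_equal(interpolate_curve(cv, 15), 6)
  expect_equal(interpolate_curve(cv, 30), 8)   # held after last sample
  expect_equal(interpolate_curve(cv, 5), 4)    # held before first sample

  dp <- sampled_curve(c(60, 65), c(0, 100), kind = "drug-plasma")
  expect_equal(interpolate_curve(dp, 30), 0)   # zero before infusion start

  # bounded by neighbouring nodes between nodes
  set.seed(1)
  cv2 <- sampled_curve(sort(runif(10, 0, 100)), runif(10, 0, 50),
                       kind = "tracer-plasma")
  tq <- runif(200, 0, 100)
  v <- interpolate_curve(cv2, tq)
  expect_true(all(v >= min(cv2$values) - 1e-12 &
                  v <= max(cv2$values) + 1e-12))
})

test_that("curve constructor validates its invariants", {
  expect_error(sampled_curve(c(2, 1), c(1, 1), "tracer-plasma"),
               "strictly increasing")
  expect_error(sampled_curve(c(1, 2), c(-1, 1), "tracer-plasma"),
               "non-negative")
  expect_error(sampled_curve(c(1, 2), c(0.5, 1.2), "parent-fraction"),
               "\\[0, 1\\]")
  expect_error(sampled_curve(numeric(0), numeric(0), "tracer-plasma"),
               "empty")
})

test_that("metabolite correction is the pointwise product on the union grid", {
  total <- sampled_curve(c(0, 10, 40, 120), c(0, 1000, 400, 200),
                         kind = "tracer-plasma", zero_before = FALSE)
  pf1 <- sampled_curve(c(0, 120), c(1, 1), kind = "parent-fraction")
  out1 <- metabolite_correct(total, pf1)
  expect_equal(interpolate_curve(out1, total$times), total$values)

  pf5 <- sampled_curve(c(0, 120), c(0.5, 0.5), kind = "parent-fraction")
  out5 <- metabolite_correct(total, pf5)
  expect_equal(out5$values, interpolate_curve(total, out5$times) / 2)

  # piecewise-linear inputs: at union-grid nodes the product is exact
  pf <- sampled_curve(c(0, 5, 60, 120), c(1, 0.9, 0.4, 0.25),
                      kind = "parent-fraction")
  out <- metabolite_correct(total, pf)
  tt <- sort(unique(c(total$times, pf$times)))
  dense <- interpolate_curve(total, tt) * interpolate_curve(pf, tt)
  expect_equal(interpolate_curve(out, tt), dense)
})

test_that("default frame schedule is the 33-frame 120-min protocol", {
  fr <- frame_schedule()
  expect_equal(nrow(fr), 33)
  expect_equal(sum(fr$duration), 120)
  expect_equal(fr$duration[1:6], rep(0.5, 6))
  # contiguous
  expect_equal(fr$start[-1], (fr$start + fr$duration)[-33])
  expect_error(frame_schedule(c(0, 1), c(2, 2)), "overlapping.*2")
})

test_that("bolus + infusion input has the stated dose split and plateau", {
  expect_equal(bolus_fraction(150, 120), 150 / 270)  # 5/9 of the dose

  sh <- tracer_input_shape()
  bi <- bolus_infusion_input(sh, Kbol = 150)
  pure <- bolus_infusion_input(sh, Kbol = Inf)
  f_bi <- attr(bi, "fun"); f_pure <- attr(pure, "fun")

  # Kbol -> Inf leaves only the bolus response
  tt <- seq(0, 120, by = 0.5)
  expect_equal(f_pure(tt), sv2akin:::bolus_response(sh, tt))

  # plateau equals integral of the impulse response / Kbol (quadrature oracle)
  tq <- seq(0, 20000, by = 0.05)
  num_int <- sum(sv2akin:::bolus_response(sh, tq)) * 0.05
  expect_equal(attr(bi, "plateau"), num_int / 150, tolerance = 1e-4)
  expect_equal(f_bi(20000) - f_pure(20000), attr(bi, "plateau"),
               tolerance = 1e-6)

  # continuity / non-negativity on a fine grid
  v <- f_bi(seq(0, 120, by = 0.01))
  expect_true(all(v >= 0))
  expect_lt(max(abs(diff(v))), sum(sh$A) * 0.02)

  expect_error(bolus_infusion_input(sh, Kbol = 0), "Kbol")
})
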