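test_that("the roof-effect amplitude ratio and its inverse are exact", {
  expect_equal(amplitude_ratio(0), 1)
  th <- atan(1 / 6.6)
  expect_equal(round(amplitude_ratio(th), 2), 0.74)
  expect_equal(round(theta_of_ratio(0.74) * 180 / pi, 1), 8.6)
  # round trip to machine precision
  for (t0 in c(0.01, 0.1, 0.5, 1.2)) {
    expect_equal(theta_of_ratio(amplitude_ratio(t0)), t0, tolerance = 1e-12)
  }
  expect_error(theta_of_ratio(0), "positive")
  expect_error(theta_of_ratio(-0.1), "positive")
  expect_error(theta_of_ratio(1.2), "weaker")
  expect_error(amplitude_ratio(2), "pi/2")
})

test_that("the tilt angle is recovered from a tilted doublet", {
  th <- atan(1 / 6.6)  # 8.616 deg
  s <- synth_multiplet(list(coupling_spec(15, theta_rad = th)),
                       ls = lineshape(fwhm_hz = 1.2), step_hz = 0.05,
                       width_hz = 60)
  ft <- fit_theta(s, j_hz = 15)
  expect_lt(abs(ft$theta_rad - th), 0.25 * pi / 180)
  expect_gt(ft$score, ft$score0)

  # untilted doublet: no spurious angle
  s0 <- synth_multiplet(list(coupling_spec(15)),
                        ls = lineshape(fwhm_hz = 1.2), step_hz = 0.05,
                        width_hz = 60)
  expect_equal(fit_theta(s0, j_hz = 15)$theta_rad, 0)

  # quality strictly higher at the construction angle than at zero
  out0 <- deconv_both(s$amplitudes, 0.05, 15, theta_rad = 0)
  outt <- deconv_both(s$amplitudes, 0.05, 15, theta_rad = th)
  expect_gt(as.numeric(quality_score(outt, "symmetry")),
            as.numeric(quality_score(out0, "symmetry")))
})

test_that("partner shifts follow delta_partner = delta_ref + J/tan(theta)", {
  # 45 degrees: offset exactly J
  p <- partner_shift(2, j_hz = 12, theta_rad = pi / 4, field_mhz = 400)
  expect_equal(p$partner_ppm, 2 + 12 / 400, tolerance = 1e-12)
  expect_false(p$reliable)  # dd/J = 1, outside 3..20

  # the Fig-7 geometry: offset 6.6 J
  th <- atan(1 / 6.6)
  p2 <- partner_shift(2, j_hz = 10, theta_rad = th, field_mhz = 400)
  expect_equal(p2$partner_ppm - 2, 6.6 * 10 / 400, tolerance = 1e-9)
  expect_true(p2$reliable)

  # sign convention: negative theta points down-frequency
  p3 <- partner_shift(2, j_hz = 10, theta_rad = -th, field_mhz = 400)
  expect_equal(p3$partner_ppm - 2, -6.6 * 10 / 400, tolerance = 1e-9)

  expect_error(partner_shift(2, 10, 0, 400), "indeterminate")

  # reliability window fires exactly at 3 < dd/J < 20
  expect_false(partner_shift(2, 10, atan(1 / 2.9), 400)$reliable)
  expect_true(partner_shift(2, 10, atan(1 / 3.1), 400)$reliable)
  expect_true(partner_shift(2, 10, atan(1 / 19.9), 400)$reliable)
  expect_false(partner_shift(2, 10, atan(1 / 20.1), 400)$reliable)
})

test_that("on an exact AB system the estimate's error is (D - dnu)/2", {
  # closed-form route on stick quantities, no line shape involved
  for (dnu in c(60, 99, 150)) {
    J <- 15
    D <- sqrt(dnu^2 + J^2)
    r <- (1 - J / D) / (1 + J / D)       # AB intensity ratio
    th <- theta_of_ratio(r)              # sin(theta) = J/D
    mhz <- 300
    delta_ref <- (D / 2) / mhz           # midpoint of the analysed doublet
    est <- partner_shift(delta_ref, J, -th, mhz)
    true_partner <- (-dnu / 2) / mhz
    err_hz <- (est$partner_ppm - true_partner) * mhz
    expect_equal(err_hz, (D - dnu) / 2, tolerance = 1e-9)
    # hence ~ J^2/(4 dnu), vanishing in the weak-coupling limit
    expect_equal(err_hz, J^2 / (4 * dnu), tolerance = 0.05)
  }
})

test_that("the propagated partner error blows up faster than 1/theta", {
  sig <- vapply(c(0.2, 0.1, 0.05), function(t)
    partner_shift(2, 10, t, 400, sigma_r = 0.01)$partner_sigma_ppm,
    numeric(1))
  expect_gt(sig[2] / sig[1], 2)   # halving theta more than doubles sigma
  expect_gt(sig[3] / sig[2], 2)
})
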