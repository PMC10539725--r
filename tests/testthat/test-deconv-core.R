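test_that("the inverse series M has the documented structure", {
  # spin 1/2, J* = 4: sticks at +/-2, +/-6, +/-10 with alternating signs
  m <- m_series(4, halfwidth_hz = 12)
  expect_equal(m$offsets_hz, c(-10, -6, -2, 2, 6, 10))
  expect_equal(m$weights, c(1, -1, 1, 1, -1, 1))

  # tilt: consecutive |weights| shrink by r towards the weaker line
  th <- atan(1 / 6.6)
  mt <- m_series(4, theta_rad = th, halfwidth_hz = 20)
  w <- abs(mt$weights)
  k <- which(mt$offsets_hz < 0)
  ratios <- w[k][-1] / w[k][-length(k)]  # moving towards the centre
  expect_true(all(abs(1 / ratios - 0.74) < 0.005))

  expect_error(m_series(4, spin = 1, theta_rad = 0.1, halfwidth_hz = 12),
               "spin-1/2")
  expect_error(m_series(4, halfwidth_hz = 2), "halfwidth")
})

test_that("sliding window sums of M vanish off-centre for all spins", {
  for (S in c(0.5, 1, 1.5, 3)) {
    n <- as.integer(2 * S + 1)
    # truncate at whole blocks so the window property is unbroken
    j <- 5
    core_edge <- (n - 1) / 2 * j
    hw <- core_edge + 4 * n * j + j / 2
    m <- m_series(j, spin = S, halfwidth_hz = hw)
    w <- m$weights
    sums <- vapply(seq_len(length(w) - n + 1),
                   function(i) sum(w[i:(i + n - 1)]), numeric(1))
    centre <- which.max(abs(sums))
    expect_equal(max(abs(sums[-centre])), 0)
    expect_equal(sums[centre], n)
  }
})

test_that("convolving a coupling pattern with its M leaves a single line", {
  for (S in c(0.5, 1.5)) {
    p <- coupling_pattern(list(coupling_spec(8, spin = S)))
    x <- numeric(401)
    for (k in seq_along(p$offsets_hz)) x[201 + p$offsets_hz[k]] <- p$weights[k]
    out <- convolve_sticks(x, 1, m_series(8, spin = S, halfwidth_hz = 200))
    expect_equal(out[201], 1, tolerance = 1e-12)
    # clean except the truncation margins (two arms at each end)
    arm <- 2 * S * 8
    inner <- (2 * arm):(401 - 2 * arm)
    expect_lt(max(abs(out[setdiff(inner, 201)])), 1e-6)
  }
})

test_that("stick convolution composes and preserves identity", {
  x <- rnorm(50)
  expect_equal(convolve_sticks(x, 1, stick_pattern(0, 1)), x)
  d <- stick_pattern(c(-3, 3), c(0.5, 0.5))
  y <- numeric(101); y[51] <- 1
  tri <- convolve_sticks(convolve_sticks(y, 1, d), 1, d)
  expect_equal(tri[c(45, 51, 57)], c(0.25, 0.5, 0.25))
  expect_equal(sum(abs(tri)), 1)
})

test_that("the side recursion eliminates the second sub-multiplet occurrence", {
  # stick doublet: L2R leaves a single stick at the left line
  x <- numeric(200); x[c(50, 90)] <- 1
  sl <- side_deconv(x, 1, 40, "L2R")
  expect_equal(which(abs(sl) > 1e-12), 50)
  expect_equal(sl[50], 1)
  # absolute sum halves on success
  expect_equal(sum(abs(sl)) / sum(abs(x)), 0.5)

  # 1:1:1 triplet of a spin-1 partner collapses in one pass
  x3 <- numeric(200); x3[c(50, 90, 130)] <- 1
  sl3 <- side_deconv(x3, 1, 40, "L2R", spin = 1)
  expect_equal(which(abs(sl3) > 1e-12), 50)

  expect_error(side_deconv(x, 1, 1.5, "L2R"), "sub-resolution")
})

test_that("S_L + S_R equals convolution with the truncated two-sided M", {
  # margin-aligned halves reproduce the two-sided series exactly for
  # even-integer arms (fractional arms differ by interpolation error)
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(300)
    arm <- sample(c(16, 24, 36, 44), 1)
    sl <- side_deconv(x, 1, arm, "L2R")
    sr <- side_deconv(x, 1, arm, "R2L")
    m <- m_series(arm, halfwidth_hz = 300)
    cv <- convolve_sticks(x, 1, m)
    al <- convolve_sticks(sl, 1, stick_pattern(arm / 2, 1)) +
      convolve_sticks(sr, 1, stick_pattern(-arm / 2, 1))
    expect_lt(max(abs(al - cv)) / max(abs(cv)), 1e-9)
  }
})

test_that("quality scores peak at true splittings", {
  s <- simple_multiplet(4.15, fwhm = 0.8, step = 0.05, width = 30)
  out <- deconv_both(s$amplitudes, 0.05, 4.15)
  expect_gte(quality_score(out, "symmetry"), 0.999)
  expect_gte(quality_score(out, "half_integral", original = s$amplitudes),
             0.99)

  # identical sides give exactly 1
  fake <- structure(list(s_left = out$s_left, s_right = out$s_left,
                         j_star_hz = 4.15, step_hz = 0.05, margin_pts = 0),
                    class = "deconv_output")
  expect_equal(as.numeric(quality_score(fake, "symmetry")), 1)

  # degenerate all-zero input flags itself
  z <- deconv_both(rep(0, 100), 0.05, 2)
  qz <- quality_score(z, "symmetry")
  expect_equal(as.numeric(qz), 0)
  expect_true(isTRUE(attr(qz, "degenerate")))
})

test_that("the quality scan finds the coupling first and its odd fractions after", {
  s <- simple_multiplet(4.15, fwhm = 0.8, step = 0.05, width = 30)
  q <- scan_quality(s)
  expect_gt(nrow(q$extrema), 0)
  expect_lt(abs(q$extrema$j_hz[1] - 4.15), 0.05)
  expect_true(any(abs(q$extrema$j_hz - 4.15 / 3) < 0.05))
  # extrema are reported in scan order, largest J* first
  expect_true(!is.unsorted(rev(q$extrema$j_grid_hz)))
  expect_error(scan_quality(s, j_grid_hz = numeric()), "empty")
  expect_error(scan_quality(s, j_grid_hz = c(1, 2, 3)), "decreasing")
})
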