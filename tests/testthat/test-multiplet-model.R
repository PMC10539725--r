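test_that("coupling patterns reproduce the canonical stick structures", {
  # spin-1/2 doublet: sticks at +/- J/2, equal halves
  p <- coupling_pattern(list(coupling_spec(4.15)))
  expect_equal(p$offsets_hz, c(-2.075, 2.075))
  expect_equal(p$weights, c(0.5, 0.5))

  # spin-3/2 partner: four equal lines spaced J
  p <- coupling_pattern(list(coupling_spec(81.6, spin = 1.5)))
  expect_equal(p$offsets_hz, c(-122.4, -40.8, 40.8, 122.4))
  expect_equal(p$weights, rep(0.25, 4))

  # two equivalent partners: binomial 1:2:1 triplet
  p <- coupling_pattern(list(coupling_spec(7, degeneracy = 2)))
  expect_equal(p$offsets_hz, c(-7, 0, 7))
  expect_equal(p$weights, c(0.25, 0.5, 0.25))

  # roof-tilted doublet: weight ratio r = (1 - sin t)/(1 + sin t)
  p <- coupling_pattern(list(coupling_spec(10, theta_rad = 8.616 * pi / 180)))
  expect_equal(round(min(p$weights) / max(p$weights), 2), 0.74)
  expect_equal(sum(p$weights), 1, tolerance = 1e-12)
})

test_that("pattern construction rejects unsupported tilt combinations", {
  expect_error(coupling_spec(5, spin = 1, theta_rad = 0.1), "spin-1/2")
  expect_error(coupling_spec(5, degeneracy = 2, theta_rad = 0.1), "spin-1/2")
  expect_error(coupling_spec(-1), "positive")
  expect_error(coupling_spec(5, spin = 0.75), "spin")
})

test_that("patterns are order-independent, symmetric, and count lines", {
  set.seed(42)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    specs <- lapply(seq_len(k), function(i)
      coupling_spec(runif(1, 1, 20), sample(c(0.5, 1, 1.5), 1)))
    p1 <- coupling_pattern(specs)
    p2 <- coupling_pattern(specs[sample(k)])
    expect_equal(p1$offsets_hz, p2$offsets_hz, tolerance = 1e-12)
    expect_equal(p1$weights, p2$weights, tolerance = 1e-12)
    # theta = 0: mirror symmetry
    expect_equal(p1$weights, rev(p1$weights), tolerance = 1e-12)
    # generic (incommensurate, distinct) J values: prod (2S+1) lines
    n_expect <- prod(vapply(specs, function(cs) 2 * cs$spin + 1, numeric(1)))
    expect_equal(length(p1$offsets_hz), n_expect)
  }
})

test_that("synthetic multiplets have the requested width, splitting and integral", {
  # singlet: measured FWHM within one grid step of nominal
  s <- synth_multiplet(list(), ls = lineshape(fwhm_hz = 1), step_hz = 0.02,
                       width_hz = 40)
  expect_lt(abs(measure_fwhm(s) - 1), 0.02)

  # resolved doublet: two maxima separated by J within the grid
  s <- simple_multiplet(10, fwhm = 1, step = 0.02)
  a <- s$amplitudes
  f <- freq_axis(s)
  left <- which(f < mean(f)); right <- which(f > mean(f))
  sep <- abs(f[right[which.max(a[right])]] - f[left[which.max(a[left])]])
  expect_lt(abs(sep - 10), 0.03)

  # normalization conservation: integral independent of the coupling list
  # (exact for a compact line shape; Lorentzian wings add truncation loss)
  for (kind in c("gaussian", "lorentzian")) {
    s0 <- synth_multiplet(list(), ls = lineshape(kind, fwhm_hz = 2),
                          step_hz = 0.1, width_hz = 600)
    s1 <- synth_multiplet(list(coupling_spec(81.6, spin = 1.5)),
                          ls = lineshape(kind, fwhm_hz = 2), step_hz = 0.1,
                          width_hz = 600)
    expect_equal(sum(s1$amplitudes), sum(s0$amplitudes),
                 tolerance = if (kind == "gaussian") 1e-6 else 1e-3)
  }

  # pattern wider than the grid is refused with the required width named
  expect_error(synth_multiplet(list(coupling_spec(50)),
                               ls = lineshape(fwhm_hz = 1), width_hz = 20),
               "at least")
})

test_that("preprocessing behaves as documented", {
  s <- simple_multiplet(c(8, 3), fwhm = 1, step = 0.05)
  # symmetrizing an already symmetric multiplet is a fixed point
  sym <- preprocess(s, symmetrize = TRUE, center_hz = centroid_hz(s))
  expect_equal(sym$amplitudes, s$amplitudes, tolerance = 1e-12)

  # offset removal zeroes the margin median
  off <- spectrum1d(s$amplitudes + 0.37, s$start_hz, s$step_hz)
  cor <- preprocess(off, remove_offset = TRUE)
  m <- ceiling(0.05 * length(cor$amplitudes))
  expect_equal(median(c(head(cor$amplitudes, m), tail(cor$amplitudes, m))),
               0, tolerance = 1e-9)

  # negated second derivative narrows a Lorentzian; oracle: the analytic
  # second derivative evaluated on a dense grid
  xd <- seq(-20, 20, by = 0.001)
  lor <- (2 / (pi * 2)) / (1 + (2 * xd / 2)^2)
  d2 <- -(diff(diff(lor)) / 0.001^2)
  oracle_fwhm <- {
    i <- which.max(d2); half <- d2[i] / 2
    lo <- max(which(d2[1:i] < half)); hi <- i + min(which(d2[-(1:i)] < half))
    (hi - lo) * 0.001
  }
  s2 <- synth_multiplet(list(), ls = lineshape(fwhm_hz = 2), step_hz = 0.02,
                        width_hz = 40)
  d2s <- preprocess(s2, second_derivative = TRUE)
  expect_lt(measure_fwhm(d2s), 2)
  expect_equal(measure_fwhm(d2s), oracle_fwhm, tolerance = 0.05)
})

test_that("reconstruction inverts the extraction", {
  ls <- lineshape(fwhm_hz = 1)
  base <- synth_multiplet(list(), ls = ls, step_hz = 0.05, width_hz = 30)
  res <- multiplet_result(0, list(), base)
  expect_equal(reconstruct(res, ls = ls, reference = base)$amplitudes,
               base$amplitudes, tolerance = 1e-9)

  # noiseless dd: reconstruction from the analysis matches the source
  s <- simple_multiplet(c(8.1, 3.3), fwhm = 1)
  r <- extract_couplings(s)
  rec <- reconstruct(r, reference = s)
  score <- sum(rec$amplitudes * s$amplitudes) /
    (sqrt(sum(rec$amplitudes^2)) * sqrt(sum(s$amplitudes^2)))
  expect_gte(score, 0.99)

  # round trip: extract then reconstruct a ddd reproduces all three J
  s3 <- simple_multiplet(c(11.5, 6.2, 2.8), fwhm = 0.9)
  r3 <- extract_couplings(s3)
  expect_equal(sort(extracted_js(r3)), c(2.8, 6.2, 11.5), tolerance = 0.05)
})
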