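test_that("overlapping lines are resolved into distinct couplings, not a triplet", {
  # two couplings closer than twice the linewidth: a visual near-triplet
  s <- simple_multiplet(c(6.32, 4.22), fwhm = 2.7, step = 0.1, width = 60)
  r <- extract_couplings(s)
  js <- sort(extracted_js(r), decreasing = TRUE)
  expect_length(js, 2)
  expect_lt(abs(js[1] - 6.32), 0.1)
  expect_lt(abs(js[2] - 4.22), 0.1)
  expect_identical(r$multiplicity_string, "dd")
})

test_that("a singlet yields an empty coupling list", {
  s <- synth_multiplet(list(), ls = lineshape(fwhm_hz = 1.2), step_hz = 0.1,
                       width_hz = 30)
  r <- extract_couplings(s)
  expect_length(r$couplings, 0)
  expect_identical(r$multiplicity_string, "s")
})

test_that("sub-linewidth couplings are found and flagged", {
  s <- simple_multiplet(1.2, fwhm = 2, step = 0.05, width = 40)
  r <- extract_couplings(s)
  expect_length(r$couplings, 1)
  expect_lt(abs(r$couplings[[1]]$j_hz - 1.2), 0.1)
  expect_true(r$couplings[[1]]$unresolved)
  expect_match(result_text(r), "use with care")
})

test_that("a region too narrow for the floor is rejected", {
  s <- synth_multiplet(list(), ls = lineshape(fwhm_hz = 0.15), step_hz = 0.01,
                       width_hz = 1.8)
  expect_error(extract_couplings(s), "too narrow")
})

test_that("degeneracy grouping follows the 0.5 Hz rule", {
  g <- group_degenerate(c(7.01, 6.98))
  expect_length(g, 1)
  expect_equal(g[[1]]$degeneracy, 2L)
  expect_equal(g[[1]]$j_hz, 6.995)
  expect_identical(multiplicity_string(g), "t")

  expect_length(group_degenerate(numeric()), 0)

  g2 <- group_degenerate(c(6.32, 4.22))
  expect_length(g2, 2)
  expect_equal(vapply(g2, `[[`, integer(1), "degeneracy"), c(1L, 1L))
})

test_that("multiplicity strings follow descending-J convention", {
  cps <- list(coupling_spec(9.9), coupling_spec(6, degeneracy = 3),
              coupling_spec(2))
  expect_identical(multiplicity_string(cps), "dqd")
  expect_identical(multiplicity_string(cps, validated = FALSE), "m")
  expect_identical(multiplicity_string(list(coupling_spec(81.6, spin = 1.5))),
                   "q")
})

test_that("validation degrades monotonically under model corruption", {
  s <- simple_multiplet(c(8.4, 3.1), fwhm = 1, step = 0.05)
  r <- extract_couplings(s)
  good <- as.numeric(validate_by_reconstruction(r, s)$score)
  expect_gte(good, 0.99)

  missing <- r; missing$couplings <- r$couplings[-2]
  extra <- r
  extra$couplings <- c(r$couplings, list(coupling_spec(5.5)))
  expect_lt(as.numeric(validate_by_reconstruction(missing, s)$score), good)
  expect_lt(as.numeric(validate_by_reconstruction(extra, s)$score), good)

  zero <- spectrum1d(rep(0, 100), 0, 0.05)
  v0 <- validate_by_reconstruction(r, zero)
  expect_equal(as.numeric(v0$score), 0)
  expect_false(v0$pass)
  expect_true(isTRUE(attr(v0$score, "degenerate")))
})

test_that("post-analysis degeneracy search repairs under-counted multiplicities", {
  # triple quintet posed against a t x hept source (weak outermost lines)
  src <- synth_multiplet(list(coupling_spec(7, degeneracy = 2),
                              coupling_spec(1.3, degeneracy = 6)),
                         ls = lineshape(fwhm_hz = 0.7), step_hz = 0.05,
                         width_hz = 45)
  base <- synth_multiplet(list(), ls = lineshape(fwhm_hz = 0.7),
                          step_hz = 0.05, width_hz = 45)
  under <- multiplet_result(0, list(coupling_spec(7, degeneracy = 2),
                                    coupling_spec(1.3, degeneracy = 4)),
                            base)
  expect_lt(as.numeric(validate_by_reconstruction(under, src)$score), 0.995)
  fixed <- post_degeneracy_search(under, src)
  degs <- vapply(fixed$couplings, `[[`, integer(1), "degeneracy")
  expect_equal(degs, c(2L, 6L))
  expect_gte(as.numeric(fixed$validation_score), 0.99)

  # a correctly identified dd is left unchanged
  s2 <- simple_multiplet(c(9.3, 4.4), fwhm = 1, step = 0.05)
  r2 <- extract_couplings(s2)
  same <- post_degeneracy_search(r2, s2)
  expect_equal(extracted_js(same), extracted_js(r2))

  # three near-equal splittings merge into one three-fold degenerate coupling
  qs <- synth_multiplet(list(coupling_spec(7, degeneracy = 3)),
                        ls = lineshape(fwhm_hz = 0.9), step_hz = 0.05,
                        width_hz = 45)
  base3 <- synth_multiplet(list(), ls = lineshape(fwhm_hz = 0.9),
                           step_hz = 0.05, width_hz = 45)
  three <- multiplet_result(0, list(coupling_spec(7.7), coupling_spec(7.0),
                                    coupling_spec(6.3)), base3)
  merged <- post_degeneracy_search(three, qs)
  expect_length(merged$couplings, 1)
  expect_equal(merged$couplings[[1]]$degeneracy, 3L)
  expect_lt(abs(merged$couplings[[1]]$j_hz - 7), 0.1)
  expect_gt(as.numeric(merged$validation_score),
            as.numeric(validate_by_reconstruction(three, qs, "lorentzian")$score))
})

test_that("overlap analysis with full integral share reduces to the plain path", {
  s <- simple_multiplet(c(9.1, 3.4), fwhm = 1, step = 0.05)
  r1 <- extract_couplings(s)
  r2 <- analyze_overlapped(s, analysis_options(overlap_fraction = 1))
  expect_equal(extracted_js(r2), extracted_js(r1))
  expect_equal(r2$validation_score, r1$validation_score)
})

test_that("overlap deeper than the largest coupling is refused", {
  s <- overlapped_pair(c(14.71, 4.77, 2.89), c(13.77, 6.15, 3.91, 2.93),
                       sep_hz = 8)
  expect_error(analyze_overlapped(s, analysis_options(overlap_fraction = 0.5)),
               "overlap too severe")
})

test_that("the strategy search converges and ranks phase-robust options first", {
  # clean symmetric dd: all strategies agree on the couplings
  s <- simple_multiplet(c(9.9, 4.2), fwhm = 1, step = 0.05)
  ranked <- strategy_search(s)
  expect_gt(length(ranked), 1)
  for (r in ranked) {
    js <- sort(extracted_js(r))
    expect_equal(js, c(4.2, 9.9), tolerance = 0.05)
  }
  expect_gte(as.numeric(ranked[[1]]$validation_score), 0.99)

  # misphased doublet: symmetrization breaks on dispersive shapes, so
  # symmetrize-off strategies must outrank symmetrize-on
  sm <- synth_multiplet(list(coupling_spec(7.4)),
                        ls = lineshape(fwhm_hz = 1.1, phase_deg = 35),
                        step_hz = 0.05, width_hz = 40)
  rk <- strategy_search(sm)
  top <- rk[[1]]$strategy_used
  expect_false(isTRUE(top$symmetrize_input) || isTRUE(top$symmetrize_each_step))
  expect_lt(abs(extracted_js(rk[[1]]) - 7.4), 0.05)
})

test_that("user spin assignments drive the general-spin deconvolution", {
  s <- synth_multiplet(list(coupling_spec(81.6, spin = 1.5)),
                       ls = lineshape(fwhm_hz = 2), step_hz = 0.4,
                       width_hz = 700)
  r <- extract_couplings(s, analysis_options(spin_map = list(list(spin = 1.5)),
                                             j_max_hz = 120, j_floor_hz = 20))
  expect_length(r$couplings, 1)
  expect_equal(r$couplings[[1]]$spin, 1.5)
  expect_lt(abs(r$couplings[[1]]$j_hz - 81.6), 0.4)
})
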