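#' Simulate a multiplet spectrum
#'
#' A multiplet is the convolution of a line shape with the stick pattern of
#' its couplings, placed at `center_hz`. Because the stick pattern carries
#' unit total weight, the integral of the (noise-free, offset-free) spectrum
#' equals the line shape integral whatever the coupling list.
#'
#' @param couplings List of [coupling_spec()] (empty for a singlet).
#' @param center_hz Multiplet position in Hz (default 0).
#' @param ls A [lineshape()] (default Lorentzian, 1 Hz fwhm).
#' @param width_hz Width of the simulated region. Default: pattern span plus
#'   `12 * fwhm` of margin (at least 5 fwhm per side as the deconvolution
#'   needs clean margins).
#' @param step_hz Grid spacing (default `fwhm / 10`).
#' @param noise_sd Standard deviation of added Gaussian noise (default 0).
#' @param baseline Constant baseline offset added to the spectrum.
#' @param seed Integer seed for the noise; recorded in the result's
#'   attributes for reproducibility. `NULL` leaves the RNG state alone.
#' @param spectrometer_mhz Optional observe frequency (MHz).
#' @return A [spectrum1d()].
#' @examples
#' s <- synth_multiplet(list(coupling_spec(7.4)), ls = lineshape(fwhm_hz = 0.8))
#' @export
synth_multiplet <- function(couplings = list(), center_hz = 0,
                            ls = lineshape("lorentzian", 1),
                            width_hz = NULL, step_hz = NULL,
                            noise_sd = 0, baseline = 0, seed = NULL,
                            spectrometer_mhz = NULL) {
  couplings <- as_coupling_list(couplings)
  pat <- coupling_pattern(couplings)
  fwhm <- if (ls$kind == "empirical") {
    if (is.null(step_hz)) stop("step_hz is required for empirical line shapes")
    step_hz * 5
  } else ls$fwhm_hz
  span <- if (length(pat$offsets_hz)) diff(range(pat$offsets_hz)) else 0
  if (is.null(step_hz)) step_hz <- fwhm / 10
  if (is.null(width_hz)) width_hz <- span + 12 * fwhm
  if (width_hz < span + 10 * fwhm)
    stop(sprintf("pattern (%.2f Hz) plus 5 fwhm margins needs a region of at least %.2f Hz",
                 span, span + 10 * fwhm))
  n <- max(2L, as.integer(round(width_hz / step_hz)) + 1L)
  x <- (seq_len(n) - 1) * step_hz - (n - 1) * step_hz / 2  # centred offsets
  amp <- numeric(n)
  for (k in seq_along(pat$offsets_hz))
    amp <- amp + pat$weights[k] *
      lineshape_profile(ls, x - pat$offsets_hz[k], step_hz)
  amp <- amp + baseline
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (noise_sd > 0) amp <- amp + rnorm(n, sd = noise_sd)
  out <- spectrum1d(amp, center_hz + x[1], step_hz, spectrometer_mhz)
  attr(out, "seed") <- seed
  out
}

#' Preprocess a multiplet region
#'
#' Optional steps applied before deconvolution, in this order: baseline
#' offset removal (subtract the median of the outer 5 % margin points),
#' resolution enhancement by the negated numerical second derivative
#' (central differences at grid resolution, so peaks stay positive), and
#' symmetrization (averaging the vector with its mirror about `center_hz`).
#'
#' @param spec A [spectrum1d()].
#' @param remove_offset Subtract the margin median baseline.
#' @param second_derivative Replace the region by minus its second derivative.
#' @param symmetrize Average with the mirror image about `center_hz`.
#' @param center_hz Mirror centre; defaults to the intensity centroid.
#' @return A [spectrum1d()] of the same length and axis.
#' @export
preprocess <- function(spec, remove_offset = FALSE, second_derivative = FALSE,
                       symmetrize = FALSE, center_hz = NULL) {
  stopifnot(inherits(spec, "spectrum1d"))
  a <- spec$amplitudes
  n <- length(a)
  if (remove_offset) {
    m <- max(2L, ceiling(0.05 * n))
    a <- a - median(c(a[seq_len(m)], a[seq(n - m + 1L, n)]))
  }
  if (second_derivative) {
    d2 <- numeric(n)
    d2[2:(n - 1)] <- (a[1:(n - 2)] - 2 * a[2:(n - 1)] + a[3:n]) / spec$step_hz^2
    a <- -d2
  }
  if (symmetrize) {
    tmp <- spectrum1d(a, spec$start_hz, spec$step_hz, spec$spectrometer_mhz)
    if (is.null(center_hz)) center_hz <- centroid_hz(tmp)
    f <- freq_axis(spec)
    if (center_hz < f[1] || center_hz > f[n])
      stop("symmetrization centre outside the region")
    mir <- approx(f, a, xout = 2 * center_hz - f, yleft = 0, yright = 0)$y
    a <- (a + mir) / 2
  }
  spectrum1d(a, spec$start_hz, spec$step_hz, spec$spectrometer_mhz)
}

#' Rebuild a multiplet from an extracted result
#'
#' Convolves a line shape with the coupling pattern of the result, at the
#' result's centre. The line shape is either the residual singlet kept at
#' the end of the recursive simplification (default) or a synthetic
#' [lineshape()]. When a reference spectrum is supplied, the reconstruction
#' is least-squares amplitude-scaled to it.
#'
#' @param result A [multiplet_result()] (or any list with `center_hz`,
#'   `couplings` and `residual_singlet`).
#' @param ls Optional [lineshape()]; `NULL` uses the residual singlet.
#' @param reference Optional [spectrum1d()] to scale against (also fixes the
#'   output grid).
#' @return A [spectrum1d()].
#' @export
reconstruct <- function(result, ls = NULL, reference = NULL) {
  pat <- coupling_pattern(result$couplings)
  base <- if (is.null(ls)) result$residual_singlet else NULL
  if (is.null(base) && is.null(ls))
    stop("result has no residual singlet and no line shape was given")
  target <- if (!is.null(reference)) reference else base
  if (is.null(target))
    stop("need a reference spectrum or a residual singlet to define the grid")
  step <- target$step_hz
  n <- length(target$amplitudes)
  if (!is.null(ls)) {
    x <- freq_axis(target) - result$center_hz
    amp <- numeric(n)
    for (k in seq_along(pat$offsets_hz))
      amp <- amp + pat$weights[k] *
        lineshape_profile(ls, x - pat$offsets_hz[k], step)
  } else {
    b <- base$amplitudes
    if (!is.null(reference) && length(b) != n) {
      b <- approx(freq_axis(base), b, xout = freq_axis(reference),
                  yleft = 0, yright = 0)$y
    }
    amp <- convolve_sticks(b, step, pat)
  }
  if (!is.null(reference)) {
    denom <- sum(amp^2)
    if (denom > 0) amp <- amp * sum(amp * reference$amplitudes) / denom
  }
  spectrum1d(amp, target$start_hz, step, target$spectrometer_mhz)
}

# Numeric full width at half maximum of the tallest feature, by linear
# interpolation of the half-height crossings.
measure_fwhm <- function(spec) {
  a <- as_amplitudes(spec)
  f <- if (inherits(spec, "spectrum1d")) freq_axis(spec) else seq_along(a)
  i <- which.max(a)
  half <- a[i] / 2
  lo <- i; while (lo > 1 && a[lo] > half) lo <- lo - 1
  hi <- i; while (hi < length(a) && a[hi] > half) hi <- hi + 1
  xl <- approx(a[c(lo, lo + 1)], f[c(lo, lo + 1)], xout = half)$y
  xr <- approx(a[c(hi - 1, hi)], f[c(hi - 1, hi)], xout = half)$y
  xr - xl
}
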