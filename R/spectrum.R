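#' One-dimensional frequency-domain spectrum
#'
#' A real amplitude vector on a uniform frequency grid. All internal
#' computation is done in Hz; the optional spectrometer frequency enables
#' conversion to the ppm scale at the I/O boundary (ppm increasing towards
#' low field, i.e. right-to-left, per NMR convention).
#'
#' @param amplitudes Numeric vector of real amplitudes (length >= 2).
#' @param start_hz Frequency of the first point, in Hz.
#' @param step_hz Grid spacing in Hz per point; must be > 0.
#' @param spectrometer_mhz Observe frequency in MHz, or `NULL` if unknown
#'   (ppm features are then disabled).
#' @return An object of class `spectrum1d`.
#' @examples
#' s <- spectrum1d(rep(0, 100), start_hz = -5, step_hz = 0.1)
#' range(freq_axis(s))
#' @export
spectrum1d <- function(amplitudes, start_hz, step_hz, spectrometer_mhz = NULL) {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) < 2L)
    stop("a spectrum needs at least two points")
  if (!all(is.finite(amplitudes)))
    stop("amplitudes must be finite")
  if (!is.numeric(step_hz) || length(step_hz) != 1L || step_hz <= 0)
    stop("step_hz must be a single positive number")
  structure(
    list(amplitudes = amplitudes,
         start_hz = as.numeric(start_hz),
         step_hz = as.numeric(step_hz),
         spectrometer_mhz = if (is.null(spectrometer_mhz)) NULL else as.numeric(spectrometer_mhz)),
    class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  n <- length(x$amplitudes)
  cat(sprintf("<spectrum1d> %d points, %.4f ... %.4f Hz (step %.5f Hz)\n",
              n, x$start_hz, x$start_hz + (n - 1) * x$step_hz, x$step_hz))
  if (!is.null(x$spectrometer_mhz))
    cat(sprintf("  observe frequency %.2f MHz\n", x$spectrometer_mhz))
  invisible(x)
}

#' Frequency axis of a spectrum
#'
#' @param spec A [spectrum1d()].
#' @return Numeric vector of frequencies in Hz, one per point.
#' @export
freq_axis <- function(spec) {
  stopifnot(inherits(spec, "spectrum1d"))
  spec$start_hz + (seq_along(spec$amplitudes) - 1) * spec$step_hz
}

#' ppm axis of a spectrum
#'
#' Requires the spectrometer frequency to be set.
#' @param spec A [spectrum1d()].
#' @return Numeric vector of chemical shifts in ppm.
#' @export
ppm_axis <- function(spec) {
  if (is.null(spec$spectrometer_mhz))
    stop("no spectrometer frequency recorded: ppm axis unavailable")
  freq_axis(spec) / spec$spectrometer_mhz
}

#' Extract a frequency region from a spectrum
#'
#' @param spec A [spectrum1d()].
#' @param lo_hz,hi_hz Region bounds in Hz (`lo_hz < hi_hz`).
#' @param lo_ppm,hi_ppm Alternatively, bounds in ppm (needs the spectrometer
#'   frequency).
#' @return A [spectrum1d()] restricted to the requested region.
#' @export
crop_spectrum <- function(spec, lo_hz = NULL, hi_hz = NULL,
                          lo_ppm = NULL, hi_ppm = NULL) {
  stopifnot(inherits(spec, "spectrum1d"))
  if (!is.null(lo_ppm) || !is.null(hi_ppm)) {
    if (is.null(spec$spectrometer_mhz))
      stop("ppm bounds given but no spectrometer frequency recorded")
    lo_hz <- lo_ppm * spec$spectrometer_mhz
    hi_hz <- hi_ppm * spec$spectrometer_mhz
  }
  if (is.null(lo_hz) || is.null(hi_hz) || lo_hz >= hi_hz)
    stop("need region bounds with lo < hi")
  f <- freq_axis(spec)
  if (lo_hz < f[1] - spec$step_hz / 2 || hi_hz > f[length(f)] + spec$step_hz / 2)
    stop("region bounds outside the spectrum")
  keep <- which(f >= lo_hz & f <= hi_hz)
  if (length(keep) < 2L) stop("region contains fewer than two points")
  spectrum1d(spec$amplitudes[keep], f[keep[1]], spec$step_hz, spec$spectrometer_mhz)
}

# Amplitude vector of a spectrum1d or plain numeric vector.
as_amplitudes <- function(x) {
  if (inherits(x, "spectrum1d")) x$amplitudes else as.numeric(x)
}

# Intensity-weighted centre (Hz) of a region; negative noise clipped so the
# centroid is not pulled around by baseline excursions.
centroid_hz <- function(spec) {
  a <- pmax(as_amplitudes(spec), 0)
  f <- freq_axis(spec)
  if (sum(a) <= 0) return(mean(f))
  sum(a * f) / sum(a)
}
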