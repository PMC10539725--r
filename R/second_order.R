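#' Roof-effect amplitude ratio
#'
#' For a mildly second-order doublet the two line amplitudes are tilted by
#' the "roof effect"; with theta = atan(J / delta-delta) the ratio of the
#' weaker to the stronger line is `r = (1 - sin(theta)) / (1 + sin(theta))`.
#' `theta_of_ratio()` is the exact inverse, `sin(theta) = (1 - r)/(1 + r)`.
#'
#' @param theta_rad Tilt angle in radians, `0 <= theta < pi/2`.
#' @return `amplitude_ratio`: the ratio r in (0, 1].
#' @examples
#' amplitude_ratio(atan(1 / 6.6))   # ~0.74
#' @export
amplitude_ratio <- function(theta_rad) {
  if (any(theta_rad < 0) || any(theta_rad >= pi / 2))
    stop("theta must lie in [0, pi/2)")
  (1 - sin(theta_rad)) / (1 + sin(theta_rad))
}

#' @rdname amplitude_ratio
#' @param r Amplitude ratio in (0, 1].
#' @return `theta_of_ratio`: the tilt angle in radians.
#' @export
theta_of_ratio <- function(r) {
  if (any(r <= 0)) stop("amplitude ratio must be positive")
  if (any(r > 1)) stop("amplitude ratio must be <= 1 (weaker over stronger line)")
  asin((1 - r) / (1 + r))
}

#' Fit the roof angle at a quality extremum
#'
#' Scans theta over a grid, re-running the tilted two-sided deconvolution at
#' the fixed trial splitting `j_hz` (which must be an extremum of the
#' theta = 0 quality curve: optimizing theta only there avoids a
#' two-variable search), and returns the angle maximizing the symmetry
#' score. Positive angles put the stronger line on the high-frequency side,
#' so the scan runs over signed angles and the sign of the result points
#' towards the coupling partner.
#'
#' @param x Amplitude vector or [spectrum1d()] holding the doublet.
#' @param step_hz Grid spacing (taken from `x` if a spectrum).
#' @param j_hz The splitting (a theta = 0 quality extremum).
#' @param theta_max_rad,theta_step_rad Scan range and step; defaults 20 deg
#'   in 0.25 deg steps, both signs.
#' @return List with `theta_rad` (0 when no angle improves the score),
#'   `score` (at the fitted angle), `score0` (at theta = 0) and `r`.
#' @export
fit_theta <- function(x, step_hz = NULL, j_hz,
                      theta_max_rad = 20 * pi / 180,
                      theta_step_rad = 0.25 * pi / 180) {
  if (inherits(x, "spectrum1d")) { step_hz <- x$step_hz; x <- x$amplitudes }
  grid <- seq(-theta_max_rad, theta_max_rad, by = theta_step_rad)
  grid <- sort(unique(c(grid, 0)))
  sc <- vapply(grid, function(th) {
    out <- deconv_both(x, step_hz, j_hz, spin = 0.5, theta_rad = th)
    as.numeric(quality_score(out, "symmetry"))
  }, numeric(1))
  s0 <- sc[grid == 0]
  i <- which.max(sc)
  # 3-point parabolic refinement of the angle
  th <- grid[i]
  if (i > 1 && i < length(grid)) {
    den <- sc[i - 1] - 2 * sc[i] + sc[i + 1]
    if (den < 0)
      th <- th + 0.5 * theta_step_rad * (sc[i - 1] - sc[i + 1]) / den
  }
  if (sc[i] <= s0 + 1e-12) th <- 0
  list(theta_rad = th,
       score = max(sc[i], s0),
       score0 = s0,
       r = amplitude_ratio(abs(th)))
}

#' Coupling-partner chemical shift from the roof effect
#'
#' Mild second-order tilt lets the partner's chemical shift be estimated
#' from the analysed doublet alone: the partner lies `J / tan(theta)` Hz
#' away on the side of the stronger line,
#' `delta_partner = delta_ref + J / tan(theta)` (in Hz, converted to ppm by
#' the observe frequency). The uncertainty is propagated to first order
#' from the amplitude-ratio uncertainty through
#' `sin(theta) = (1 - r)/(1 + r)`; since `d(J/tan)/d theta ~ 1/sin^2`, the
#' error blows up for weak tilt. Estimates are flagged unreliable outside
#' `3 < delta-delta / J < 20`.
#'
#' @param delta_ref_ppm Chemical shift of the analysed doublet (midpoint of
#'   its two lines), in ppm.
#' @param j_hz Coupling constant in Hz.
#' @param theta_rad Signed tilt angle (positive: partner at higher
#'   frequency); must be non-zero.
#' @param field_mhz Spectrometer observe frequency in MHz.
#' @param sigma_r Standard error of the measured amplitude ratio (e.g. from
#'   the noise level of the margin region); 0 gives a zero propagated error.
#' @return An object of class `second_order_fit`: list with `j_hz`,
#'   `theta_rad`, `r`, `delta_ref_ppm`, `partner_ppm`, `partner_sigma_ppm`,
#'   `delta_delta_hz`, `field_mhz`, `reliable`.
#' @export
partner_shift <- function(delta_ref_ppm, j_hz, theta_rad, field_mhz,
                          sigma_r = 0) {
  if (theta_rad == 0) stop("no roof effect (theta = 0): partner indeterminate")
  if (field_mhz <= 0) stop("field_mhz must be positive")
  th <- abs(theta_rad)
  r <- amplitude_ratio(th)
  dd_hz <- j_hz / tan(th)
  partner_ppm <- delta_ref_ppm + sign(theta_rad) * dd_hz / field_mhz
  # sigma_theta = sigma_sin / cos = (2 sigma_r / (1+r)^2) / cos(theta)
  sigma_theta <- 2 * sigma_r / ((1 + r)^2 * cos(th))
  sigma_dd <- j_hz * sigma_theta / sin(th)^2
  ratio <- dd_hz / j_hz
  structure(list(j_hz = j_hz, theta_rad = theta_rad, r = r,
                 delta_ref_ppm = delta_ref_ppm,
                 partner_ppm = partner_ppm,
                 partner_sigma_ppm = sigma_dd / field_mhz,
                 delta_delta_hz = dd_hz, field_mhz = field_mhz,
                 reliable = (ratio > 3 && ratio < 20)),
            class = "second_order_fit")
}

#' @export
print.second_order_fit <- function(x, ...) {
  cat(sprintf("partner ~ %.3f +/- %.3f ppm (J = %.2f Hz, theta = %.2f deg, r = %.3f)%s\n",
              x$partner_ppm, x$partner_sigma_ppm, x$j_hz,
              x$theta_rad * 180 / pi, x$r,
              if (!x$reliable) "  [outside the reliable 3 < dd/J < 20 window]" else ""))
  invisible(x)
}
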