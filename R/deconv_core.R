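#' Inverse simplification series M(J*)
#'
#' The doubly infinite series of alternating-sign delta functions whose
#' convolution with the splitting pattern of a coupling J collapses the
#' splitting when the trial value `j_star_hz` equals J. For a partner of
#' spin S (n = 2S+1 lines) the series is a centred core of n unit sticks
#' spaced J*, flanked on both sides by repeating outward blocks of one stick
#' of weight -(n-1) followed by n-1 unit sticks, truncated at
#' `halfwidth_hz`. By construction the sliding sum of any n consecutive
#' weights is zero except over the central window, so that
#' `coupling_pattern(J, S)` (unit total weight) convolved with
#' `m_series(J, S)` leaves a single unit stick (up to truncation tails).
#'
#' For spin 1/2 this reduces to sticks at ±(2k+1) J*/2 with signs (-1)^k.
#' With a roof angle theta (spin 1/2 only) consecutive absolute weights
#' shrink by r = (1 - sin t)/(1 + sin t) towards the weaker doublet line and
#' grow by 1/r towards the stronger line, signs still alternating, the
#' amplitude ratio of consecutive sticks in M being the inverse of the ratio
#' in the tilted doublet.
#'
#' @param j_star_hz Trial splitting in Hz (> 0).
#' @param spin Partner spin (default 1/2).
#' @param theta_rad Roof angle (spin 1/2 only); sign as in [coupling_spec()].
#' @param halfwidth_hz Truncation: sticks with |offset| beyond this are
#'   dropped. Must be >= `j_star_hz`.
#' @return A [stick_pattern()].
#' @export
m_series <- function(j_star_hz, spin = 0.5, theta_rad = 0, halfwidth_hz) {
  if (j_star_hz <= 0) stop("j_star_hz must be positive")
  if (halfwidth_hz < j_star_hz) stop("halfwidth must be at least one arm (j_star)")
  if (theta_rad != 0 && spin != 0.5)
    stop("a roof angle is defined only for spin-1/2 partners")
  n <- as.integer(round(2 * spin + 1))
  if (theta_rad == 0) {
    core_off <- (seq_len(n) - (n + 1) / 2) * j_star_hz
    off <- core_off
    wt <- rep(1, n)
    b <- 1L
    repeat {
      edge <- core_off[n] + ((b - 1) * n) * j_star_hz
      blk_off <- edge + seq_len(n) * j_star_hz
      if (blk_off[1] > halfwidth_hz) break
      blk_wt <- c(-(n - 1), rep(1, n - 1))
      keep <- blk_off <= halfwidth_hz
      off <- c(off, blk_off[keep], -blk_off[keep])
      wt <- c(wt, blk_wt[keep], blk_wt[keep])
      b <- b + 1L
    }
    stick_pattern(off, wt)
  } else {
    # tilted doublet: F = a d(-J/2) + b d(+J/2); core weights c/b at +J*/2
    # and c/a at -J*/2 with c = ab/(a^2+b^2) make F (x) M the unit stick,
    # each side then recurring with ratio -(b/a) upward, -(a/b) downward.
    r <- amplitude_ratio(abs(theta_rad))
    a <- r / (1 + r); b <- 1 / (1 + r)          # theta > 0: stronger at +J/2
    if (theta_rad < 0) { tmp <- a; a <- b; b <- tmp }
    cc <- a * b / (a^2 + b^2)
    kmax <- max(0L, floor((halfwidth_hz / j_star_hz - 0.5)))
    k <- 0:kmax
    off_p <- (2 * k + 1) * j_star_hz / 2
    wt_p <- (cc / b) * (-b / a)^k
    wt_m <- (cc / a) * (-a / b)^k
    stick_pattern(c(-rev(off_p), off_p), c(rev(wt_m), wt_p))
  }
}

#' Convolve an amplitude vector with a stick pattern
#'
#' `out[i] = sum_k weights[k] * x[i - offsets[k]/step]`, with linear
#' interpolation for fractional-bin offsets and zero padding outside the
#' region; the length is preserved.
#'
#' @param x Numeric amplitude vector (or [spectrum1d()]).
#' @param step_hz Grid spacing in Hz (taken from `x` if it is a spectrum).
#' @param sticks A [stick_pattern()].
#' @return Numeric vector of the same length as `x`.
#' @export
convolve_sticks <- function(x, step_hz = NULL, sticks) {
  if (inherits(x, "spectrum1d")) { step_hz <- x$step_hz; x <- x$amplitudes }
  if (is.null(step_hz) || step_hz <= 0) stop("step_hz must be positive")
  out <- numeric(length(x))
  for (k in seq_along(sticks$offsets_hz))
    out <- out + sticks$weights[k] *
      cpp_shift_interp(x, -sticks$offsets_hz[k] / step_hz)
  out
}

#' One-sided deconvolution walk
#'
#' Runs the side-to-side recursion in one direction: a cursor walks the
#' vector and subtracts, one arm length `j_star_hz` behind (2S arms for a
#' partner of spin S), the accumulated output. Left-to-right and
#' right-to-left runs produce the two sub-multiplets S_L and S_R whose
#' similarity measures the success of the simplification. The right-to-left
#' run reverses the vector, applies the same recursion and reverses back.
#'
#' @param x Amplitude vector or [spectrum1d()].
#' @param step_hz Grid spacing (taken from `x` if a spectrum).
#' @param j_star_hz Trial splitting in Hz; must be at least `2 * step_hz`.
#' @param direction `"L2R"` or `"R2L"`.
#' @param spin Partner spin (1/2, 1, 3/2, 2, 5/2, 3).
#' @param theta_rad Roof angle (spin 1/2 only).
#' @return Numeric vector, same length as the input.
#' @export
side_deconv <- function(x, step_hz = NULL, j_star_hz,
                        direction = c("L2R", "R2L"),
                        spin = 0.5, theta_rad = 0) {
  direction <- match.arg(direction)
  if (inherits(x, "spectrum1d")) { step_hz <- x$step_hz; x <- x$amplitudes }
  if (is.null(step_hz) || step_hz <= 0) stop("step_hz must be positive")
  if (j_star_hz < 2 * step_hz)
    stop("j_star below twice the grid step: sub-resolution trial")
  n <- as.integer(round(2 * spin + 1))
  if (theta_rad != 0 && (spin != 0.5))
    stop("a roof angle is defined only for spin-1/2 partners")
  d <- j_star_hz / step_hz
  if (length(x) <= (n - 1) * d)
    stop("region shorter than the deconvolution arm")
  rho <- if (theta_rad == 0) rep(1, n - 1) else {
    r <- amplitude_ratio(abs(theta_rad))
    # ratio (far line)/(near line) along the walk
    if ((theta_rad > 0) == (direction == "L2R")) 1 / r else r
  }
  if (direction == "L2R") {
    cpp_side_deconv(x, d, rho)
  } else {
    rev(cpp_side_deconv(rev(x), d, rho))
  }
}

#' Two-sided deconvolution at one trial splitting
#'
#' Convenience wrapper running [side_deconv()] in both directions.
#'
#' @inheritParams side_deconv
#' @return An object of class `deconv_output` with fields `s_left`,
#'   `s_right`, `j_star_hz`, `step_hz`, `spin`, `theta_rad` and
#'   `margin_pts` (one arm, `(2S) * j_star / step`, the width of the
#'   marginal artifact zones).
#' @export
deconv_both <- function(x, step_hz = NULL, j_star_hz, spin = 0.5,
                        theta_rad = 0) {
  if (inherits(x, "spectrum1d")) { step_hz <- x$step_hz; x <- x$amplitudes }
  structure(list(
    s_left = side_deconv(x, step_hz, j_star_hz, "L2R", spin, theta_rad),
    s_right = side_deconv(x, step_hz, j_star_hz, "R2L", spin, theta_rad),
    j_star_hz = j_star_hz, step_hz = step_hz, spin = spin,
    theta_rad = theta_rad,
    margin_pts = (2 * spin) * j_star_hz / step_hz),
    class = "deconv_output")
}

#' Quality of a deconvolution
#'
#' Two criteria for the success of a simplification at trial splitting J*:
#'
#' * `"symmetry"`: normalized scalar product of the two sub-multiplets S_L
#'   and S_R after aligning them (S_R is shifted by the arm length
#'   (2S) J* so the two copies of the simplified sub-multiplet superpose)
#'   and chopping off the marginal artifact zones of one arm per side.
#'   Values in \[-1, 1\], 1 for perfect simplification.
#' * `"half_integral"`: `1 - 2 |sum(|S_side|) / sum(|original|) - 1/2|`,
#'   maximal (1) when the absolute sum of one sub-multiplet is exactly half
#'   that of the starting multiplet, as it is after a successful
#'   simplification. Needs only one side; used for partially overlapping
#'   multiplets, where `overlap_fraction` f restricts the target to the
#'   analysed multiplet's share (absolute sum f/2 of the region total over
#'   the walk up to the f-quantile of the original's absolute integral).
#'
#' @param output A [deconv_both()] result.
#' @param mode `"symmetry"` or `"half_integral"`.
#' @param original The amplitude vector the deconvolution started from
#'   (required for `"half_integral"`).
#' @param side Which sub-multiplet the half-integral criterion uses
#'   (`"left"` walks L2R, `"right"` walks R2L).
#' @param overlap_fraction Integral fraction f of the analysed multiplet
#'   (default 1: isolated multiplet).
#' @return A single score. A degenerate input (zero-norm side) returns 0
#'   with attribute `degenerate = TRUE`.
#' @export
quality_score <- function(output, mode = c("symmetry", "half_integral"),
                          original = NULL, side = c("left", "right"),
                          overlap_fraction = 1) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  if (mode == "symmetry") {
    L <- output$s_left
    s <- output$margin_pts
    n <- length(L)
    Rs <- cpp_shift_interp(output$s_right, s)
    hi <- floor(n - s)
    if (hi < 8) return(structure(0, degenerate = TRUE))
    Lw <- L[1:hi]; Rw <- Rs[1:hi]
    nl <- sqrt(sum(Lw^2)); nr <- sqrt(sum(Rw^2))
    if (nl == 0 || nr == 0) return(structure(0, degenerate = TRUE))
    sum(Lw * Rw) / (nl * nr)
  } else {
    if (is.null(original)) stop("half_integral mode needs the original region")
    orig <- as_amplitudes(original)
    tot <- sum(abs(orig))
    if (tot == 0) return(structure(0, degenerate = TRUE))
    f <- overlap_fraction
    v <- if (side == "left") output$s_left else rev(output$s_right)
    o <- if (side == "left") abs(orig) else rev(abs(orig))
    # for a partial multiplet, stop the bookkeeping at 80 % of its integral
    # share: the collapsed sub-multiplet (shifted towards the starting edge)
    # lies before that point, while the zone where the neighbour is being
    # subtracted — occupied territory — stays out of the measure
    q <- if (f < 1) 0.8 else 1
    pf <- which(cumsum(o) >= q * f * tot)[1]
    if (is.na(pf)) pf <- length(o)
    ratio <- sum(abs(v[1:pf])) / (f * tot)
    1 - 2 * abs(ratio - 0.5)
  }
}

#' Scan the quality function over trial splittings
#'
#' Evaluates [quality_score()] at every J* of a decreasing grid and detects
#' the local maxima: their positions are the coupling-constant candidates,
#' the first extremum encountered when scanning downward pointing to the
#' largest coupling of the multiplet. Maxima are refined by three-point
#' parabolic interpolation.
#'
#' @param x Amplitude vector or [spectrum1d()].
#' @param step_hz Grid spacing (taken from `x` if a spectrum).
#' @param j_max_hz,j_floor_hz Scan range; defaults: half the region width
#'   down to 1 Hz. The grid runs in steps of `step_hz / 2` (finer than the
#'   data grid so extrema are not aliased).
#' @param j_grid_hz Optional explicit decreasing grid (overrides the range).
#' @param spin,theta_rad Passed to [side_deconv()].
#' @param mode,side,overlap_fraction Passed to [quality_score()].
#' @param prominence Minimal relative prominence (fraction of the curve's
#'   range) for a local maximum to be reported. Default 0.02.
#' @return An object of class `quality_curve`: list with `j_hz` (decreasing),
#'   `score`, and `extrema`, a data frame with columns `j_hz` (refined),
#'   `j_grid_hz`, `score`, `prominence`, ordered as encountered in the scan
#'   (largest J* first).
#' @export
scan_quality <- function(x, step_hz = NULL, j_max_hz = NULL, j_floor_hz = 1,
                         j_grid_hz = NULL, spin = 0.5, theta_rad = 0,
                         mode = c("symmetry", "half_integral"),
                         side = "left", overlap_fraction = 1,
                         prominence = 0.02) {
  mode <- match.arg(mode)
  if (inherits(x, "spectrum1d")) { step_hz <- x$step_hz; x <- x$amplitudes }
  if (is.null(step_hz) || step_hz <= 0) stop("step_hz must be positive")
  W <- (length(x) - 1) * step_hz
  if (is.null(j_grid_hz)) {
    if (is.null(j_max_hz)) j_max_hz <- W / 2
    lo <- max(j_floor_hz, 2 * step_hz)
    if (j_max_hz <= lo) stop("region too narrow for the requested J* floor")
    j_grid_hz <- seq(j_max_hz, lo, by = -step_hz / 2)
  }
  if (!length(j_grid_hz)) stop("empty J* grid")
  if (is.unsorted(rev(j_grid_hz))) stop("J* grid must be decreasing")
  nsub <- 2 * spin
  score <- vapply(j_grid_hz, function(j) {
    if (length(x) <= nsub * j / step_hz + 2) return(0)
    if (mode == "symmetry") {
      out <- deconv_both(x, step_hz, j, spin, theta_rad)
      as.numeric(quality_score(out, "symmetry"))
    } else {
      sl <- if (side == "left")
        side_deconv(x, step_hz, j, "L2R", spin, theta_rad)
      else side_deconv(x, step_hz, j, "R2L", spin, theta_rad)
      out <- structure(list(s_left = sl, s_right = sl, j_star_hz = j,
                            step_hz = step_hz,
                            margin_pts = nsub * j / step_hz),
                       class = "deconv_output")
      as.numeric(quality_score(out, "half_integral", original = x,
                               side = side, overlap_fraction = overlap_fraction))
    }
  }, numeric(1))
  ex <- find_maxima(j_grid_hz, score, prominence)
  structure(list(j_hz = j_grid_hz, score = score, extrema = ex,
                 mode = mode, spin = spin),
            class = "quality_curve")
}

#' @export
print.quality_curve <- function(x, ...) {
  cat(sprintf("<quality_curve> %d trial splittings, %s criterion, %d extrema\n",
              length(x$j_hz), x$mode, nrow(x$extrema)))
  if (nrow(x$extrema)) print(x$extrema, digits = 4)
  invisible(x)
}

# Local maxima of score over a decreasing j grid, with a simple prominence
# measure (drop to the deepest valley separating the peak from any higher
# point), refined by 3-point parabolic interpolation.
find_maxima <- function(j, s, prominence_rel = 0.02) {
  n <- length(s)
  res <- data.frame(j_hz = numeric(), j_grid_hz = numeric(),
                    score = numeric(), prominence = numeric())
  if (n < 3) return(res)
  rng <- diff(range(s))
  if (rng <= 0) return(res)
  cand <- which(diff(sign(diff(s))) < 0) + 1L
  for (i in cand) {
    # walk left/right until a strictly higher point or the boundary
    lmin <- s[i]; k <- i
    while (k > 1 && s[k] <= s[i]) { lmin <- min(lmin, s[k]); k <- k - 1 }
    if (s[k] <= s[i]) lmin <- min(lmin, s[k])
    rmin <- s[i]; k <- i
    while (k < n && s[k] <= s[i]) { rmin <- min(rmin, s[k]); k <- k + 1 }
    if (s[k] <= s[i]) rmin <- min(rmin, s[k])
    prom <- s[i] - max(lmin, rmin)
    if (prom < prominence_rel * rng) next
    denom <- s[i - 1] - 2 * s[i] + s[i + 1]
    jr <- if (denom < 0) {
      dj <- j[i + 1] - j[i]   # negative (grid decreasing)
      j[i] + 0.5 * dj * (s[i - 1] - s[i + 1]) / denom
    } else j[i]
    # clamp refinement to the neighbouring grid cells
    jr <- min(max(jr, min(j[i + 1], j[i - 1])), max(j[i + 1], j[i - 1]))
    res <- rbind(res, data.frame(j_hz = jr, j_grid_hz = j[i],
                                 score = s[i], prominence = prom))
  }
  res[order(-res$j_grid_hz), , drop = FALSE]
}
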