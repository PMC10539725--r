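#' Spectral line shape specification
#'
#' Describes the singlet shape a multiplet's stick pattern is convolved with:
#' the Lorentzian of transverse relaxation, the (often Gaussian) B0
#' inhomogeneity broadening, their convolution (Voigt), or an arbitrary
#' empirical profile. A zero-order phase error mixes the absorptive shape
#' with its dispersive (Hilbert) partner.
#'
#' For `kind = "voigt"` the Lorentzian and Gaussian components each carry
#' `fwhm_hz / 2`, a simple equal-mix parameterization (the overall width is
#' then slightly below `fwhm_hz`).
#'
#' @param kind One of `"lorentzian"`, `"gaussian"`, `"voigt"`, `"empirical"`.
#' @param fwhm_hz Full width at half maximum in Hz (> 0). Ignored for
#'   `"empirical"`.
#' @param phase_deg Zero-order phase error in degrees (default 0 = pure
#'   absorption).
#' @param shape For `kind = "empirical"`: a numeric amplitude vector sampled
#'   on the target grid, centred on its middle point; must have a positive
#'   finite sum.
#' @return An object of class `lineshape`.
#' @export
lineshape <- function(kind = c("lorentzian", "gaussian", "voigt", "empirical"),
                      fwhm_hz = 1, phase_deg = 0, shape = NULL) {
  kind <- match.arg(kind)
  if (kind == "empirical") {
    if (is.null(shape) || !all(is.finite(shape)) || sum(shape) <= 0)
      stop("empirical line shape needs a finite vector with positive sum")
  } else {
    if (!is.numeric(fwhm_hz) || length(fwhm_hz) != 1L || fwhm_hz <= 0)
      stop("fwhm_hz must be a single positive number")
  }
  structure(list(kind = kind, fwhm_hz = fwhm_hz,
                 phase_deg = phase_deg, shape = shape),
            class = "lineshape")
}

# Hilbert (dispersive) partner of an absorption profile, via FFT with 4x
# zero padding to tame wrap-around.
dispersion_partner <- function(y) {
  n <- length(y)
  n2 <- 2^ceiling(log2(4 * n))
  yp <- c(y, rep(0, n2 - n))
  Y <- fft(yp)
  k <- seq_len(n2) - 1
  sgn <- ifelse(k == 0 | k == n2 / 2, 0, ifelse(k < n2 / 2, 1, -1))
  d <- Re(fft(Y * complex(imaginary = -sgn), inverse = TRUE)) / n2
  d[seq_len(n)]
}

# Evaluate a lineshape, centred at 0, on offsets x (Hz, uniform grid assumed
# for phase != 0 or voigt/empirical kinds). Unit integral: sum(y) * step = 1.
lineshape_profile <- function(ls, x, step_hz) {
  stopifnot(inherits(ls, "lineshape"))
  w <- ls$fwhm_hz
  absorb <- switch(ls$kind,
    lorentzian = (2 / (pi * w)) / (1 + (2 * x / w)^2),
    gaussian = {
      s <- w / (2 * sqrt(2 * log(2)))
      exp(-x^2 / (2 * s^2)) / (s * sqrt(2 * pi))
    },
    voigt = {
      l <- (2 / (pi * (w / 2))) / (1 + (2 * x / (w / 2))^2)
      s <- (w / 2) / (2 * sqrt(2 * log(2)))
      g <- exp(-x^2 / (2 * s^2)) / (s * sqrt(2 * pi))
      # discrete convolution on the grid, recentred
      n <- length(x)
      cv <- stats::convolve(l, rev(g), type = "open") * step_hz
      mid <- (length(cv) + 1) / 2
      idx <- round(mid + (seq_len(n) - (which.min(abs(x)))))
      cv[pmin(pmax(idx, 1), length(cv))]
    },
    empirical = {
      v <- as.numeric(ls$shape)
      ctr <- (length(v) + 1) / 2
      out <- approx((seq_along(v) - ctr) * step_hz, v, xout = x,
                    yleft = 0, yright = 0)$y
      out / (sum(out) * step_hz)
    })
  phi <- ls$phase_deg * pi / 180
  if (phi != 0) {
    disp <- if (ls$kind == "lorentzian") {
      u <- 2 * x / w
      (2 / (pi * w)) * u / (1 + u^2)
    } else {
      dispersion_partner(absorb)
    }
    absorb <- cos(phi) * absorb + sin(phi) * disp
  }
  absorb
}
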