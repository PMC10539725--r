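#' Stick pattern of signed delta functions
#'
#' A set of zero-width lines (delta functions) given by frequency offsets
#' from the pattern centre and signed weights. Offsets are kept strictly
#' increasing; sticks closer than `merge_tol_hz` are merged by weight
#' addition (and dropped when the merged weight cancels to ~0), which
#' prevents spurious near-duplicate lines for commensurate coupling sets.
#'
#' @param offsets_hz Numeric offsets from the pattern centre, in Hz.
#' @param weights Signed numeric weights, same length as `offsets_hz`.
#' @param merge_tol_hz Sticks within this distance are merged (default 1e-6 Hz).
#' @return An object of class `stick_pattern` with fields `offsets_hz`,
#'   `weights`.
#' @export
stick_pattern <- function(offsets_hz = numeric(), weights = numeric(),
                          merge_tol_hz = 1e-6) {
  if (length(offsets_hz) != length(weights))
    stop("offsets and weights must have the same length")
  o <- as.numeric(offsets_hz); w <- as.numeric(weights)
  if (length(o)) {
    ord <- order(o)
    o <- o[ord]; w <- w[ord]
    # merge runs of near-coincident offsets
    grp <- cumsum(c(TRUE, diff(o) > merge_tol_hz))
    o <- as.numeric(tapply(o * abs(w), grp, sum) / pmax(tapply(abs(w), grp, sum), .Machine$double.xmin))
    o2 <- as.numeric(tapply(offsets_hz[ord], grp, mean))
    o[!is.finite(o)] <- o2[!is.finite(o)]
    w <- as.numeric(tapply(w, grp, sum))
    keep <- abs(w) > 1e-14
    o <- o[keep]; w <- w[keep]
  }
  structure(list(offsets_hz = o, weights = w), class = "stick_pattern")
}

#' @export
print.stick_pattern <- function(x, ...) {
  cat(sprintf("<stick_pattern> %d sticks\n", length(x$offsets_hz)))
  if (length(x$offsets_hz) <= 12) {
    print(data.frame(offset_hz = round(x$offsets_hz, 6),
                     weight = round(x$weights, 6)))
  } else {
    cat(sprintf("  offsets %.3f ... %.3f Hz, total |weight| %.4f\n",
                min(x$offsets_hz), max(x$offsets_hz), sum(abs(x$weights))))
  }
  invisible(x)
}

# Convolution of two stick patterns: pairwise offset sums, weight products.
convolve_patterns <- function(a, b, merge_tol_hz = 1e-6) {
  if (!length(a$offsets_hz)) return(b)
  if (!length(b$offsets_hz)) return(a)
  o <- outer(a$offsets_hz, b$offsets_hz, `+`)
  w <- outer(a$weights, b$weights)
  stick_pattern(as.vector(o), as.vector(w), merge_tol_hz)
}

#' One scalar coupling
#'
#' The unit of extracted results: a coupling constant `j_hz` to `degeneracy`
#' equivalent partners of spin `spin`. A non-zero roof angle `theta_rad`
#' (mild second-order tilt, theta = atan(J / delta-delta)) is defined for a
#' single spin-1/2 partner only; positive theta puts the stronger doublet
#' line on the high-frequency side (the side of the coupling partner).
#'
#' @param j_hz Coupling constant in Hz (> 0).
#' @param spin Partner spin, one of 1/2, 1, 3/2, 2, 5/2, 3.
#' @param degeneracy Number of equivalent partners (>= 1).
#' @param theta_rad Roof angle in radians, `|theta| < pi/2`; sign selects the
#'   stronger-line side. Default 0 (first order).
#' @param unresolved Logical flag set by the analyzer for couplings below the
#'   observed linewidth ("use with care").
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(j_hz, spin = 0.5, degeneracy = 1L, theta_rad = 0,
                          unresolved = FALSE) {
  if (!is.numeric(j_hz) || length(j_hz) != 1L || j_hz <= 0)
    stop("j_hz must be a single positive number")
  if (!spin %in% c(0.5, 1, 1.5, 2, 2.5, 3))
    stop("spin must be one of 1/2, 1, 3/2, 2, 5/2, 3")
  degeneracy <- as.integer(degeneracy)
  if (degeneracy < 1L) stop("degeneracy must be >= 1")
  if (abs(theta_rad) >= pi / 2) stop("theta must satisfy |theta| < pi/2")
  if (theta_rad != 0 && (spin != 0.5 || degeneracy != 1L))
    stop("a roof angle is defined only for a single spin-1/2 partner")
  structure(list(j_hz = as.numeric(j_hz), spin = spin,
                 degeneracy = degeneracy, theta_rad = as.numeric(theta_rad),
                 unresolved = isTRUE(unresolved)),
            class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("J = %.3f Hz, spin %g, degeneracy %d%s%s\n",
              x$j_hz, x$spin, x$degeneracy,
              if (x$theta_rad != 0) sprintf(", theta = %.2f deg", x$theta_rad * 180 / pi) else "",
              if (x$unresolved) " [unresolved]" else ""))
  invisible(x)
}

# Coerce list / single spec into a list of coupling_spec.
as_coupling_list <- function(couplings) {
  if (inherits(couplings, "coupling_spec")) return(list(couplings))
  if (is.null(couplings)) return(list())
  stopifnot(is.list(couplings))
  lapply(couplings, function(cs) {
    if (inherits(cs, "coupling_spec")) cs
    else do.call(coupling_spec, cs)
  })
}

#' Stick pattern of a set of couplings
#'
#' Builds F, the forward splitting pattern: the convolution of the elementary
#' patterns of each coupling. One spin-1/2 coupling gives sticks at ±J/2;
#' a partner of spin S gives 2S+1 equal sticks spaced J and centred at 0;
#' degeneracy n applies the elementary pattern n times (binomial weights for
#' spin 1/2). A roof angle scales the two doublet sticks so that
#' (high-field weight)/(low-field weight) = r = (1 - sin t)/(1 + sin t) for
#' t = |theta| when theta > 0 (stronger line high-frequency), mirrored for
#' theta < 0. The total weight is normalized to 1.
#'
#' @param couplings List of [coupling_spec()] (possibly empty: returns the
#'   single unit stick at 0).
#' @param merge_tol_hz Merge tolerance passed to [stick_pattern()].
#' @return A [stick_pattern()] of unit total weight.
#' @examples
#' coupling_pattern(list(coupling_spec(7, degeneracy = 2)))  # 1:2:1 triplet
#' @export
coupling_pattern <- function(couplings = list(), merge_tol_hz = 1e-6) {
  couplings <- as_coupling_list(couplings)
  pat <- stick_pattern(0, 1)
  for (cs in couplings) {
    elem <- elementary_pattern(cs)
    for (k in seq_len(cs$degeneracy))
      pat <- convolve_patterns(pat, elem, merge_tol_hz)
  }
  pat
}

# Elementary (single application) stick pattern of one coupling.
elementary_pattern <- function(cs) {
  n <- as.integer(round(2 * cs$spin + 1))
  if (cs$theta_rad != 0) {
    r <- amplitude_ratio(abs(cs$theta_rad))
    wk <- r / (1 + r)   # weaker line
    st <- 1 / (1 + r)   # stronger line
    if (cs$theta_rad > 0)
      stick_pattern(c(-cs$j_hz / 2, cs$j_hz / 2), c(wk, st))
    else
      stick_pattern(c(-cs$j_hz / 2, cs$j_hz / 2), c(st, wk))
  } else {
    off <- (seq_len(n) - (n + 1) / 2) * cs$j_hz
    stick_pattern(off, rep(1 / n, n))
  }
}
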