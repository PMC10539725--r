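`%||%` <- function(a, b) if (is.null(a)) b else a

#' Options driving the recursive multiplet analysis
#'
#' @param j_floor_hz Smallest trial splitting tested (default 1 Hz, a good
#'   compromise for standard 1D 1H spectra; overridable, no automatic
#'   linewidth-based floor).
#' @param j_max_hz Largest trial splitting; default half the region width.
#' @param degeneracy_tol_hz Couplings differing by less than this are taken
#'   as degenerate (default 0.5 Hz).
#' @param validation_threshold Minimal reconstruction scalar product for a
#'   result to be considered validated (default 0.99).
#' @param success_threshold Minimal quality score for an extremum to be
#'   accepted as a coupling during the recursion (default 0.8); guards
#'   against combination artifacts posing as large couplings.
#' @param extremum_slack Score margin used by the `"best_within_slack"`
#'   choice policy and by the sharpened-scan refinement (default 0.05).
#' @param choice_policy How the accepted extremum of a scan is chosen:
#'   `"first_above_threshold"` (default) takes the first extremum scanning
#'   downward that clears `success_threshold` — the
#'   largest-coupling-first rule; `"best_within_slack"` additionally skips
#'   extrema scoring more than `extremum_slack` below the scan's best,
#'   which sidesteps combination artifacts (J1 + J2) in richly degenerate
#'   multiplets at the price of occasionally skipping a noise-degraded
#'   true coupling. The strategy search tries both.
#' @param symmetrize_input Symmetrize the region before the analysis.
#' @param symmetrize_each_step Symmetrize after each simplification step
#'   (generally beneficial; breaks down for non-absorptive line shapes).
#' @param direction_policy How the two sub-multiplets are combined into the
#'   next working region: `"both_sum"` (default; their aligned average),
#'   `"best_half"` (splice the cleaner half of each; can leave a small
#'   discontinuity in the middle), `"left_only"`, `"right_only"`.
#' @param remove_offset Subtract the margin-median baseline first.
#' @param second_derivative Analyse the negated second derivative
#'   (resolution enhancement).
#' @param refine Apply the reconstruction-based finalization steps —
#'   degeneracy confirmation, pruning of sub-linewidth ghosts, and the
#'   final J polish (default `TRUE`). Switched off for the truncated
#'   sub-multiplets of overlapped analyses, whose hard cut edge violates
#'   the clean-margin assumption behind those fits.
#' @param sharpen_scan After the plain scan picks a splitting, re-scan a
#'   narrow J* window around it on a resolution-enhanced copy of the
#'   working region (negated second derivative of a lightly
#'   Gaussian-smoothed copy): its quality extrema are markedly narrower,
#'   which splits the merged extremum of two couplings closer than the
#'   linewidth (default `TRUE`). The deconvolution itself always runs on
#'   the unenhanced region.
#' @param theta_scan Fit a roof angle at each extracted doublet splitting.
#' @param theta_max_deg,theta_step_deg Roof-angle scan range and step.
#' @param spin_map Optional user assignment of partner spins: a list of
#'   `list(spin =, degeneracy =)` consumed largest-coupling-first;
#'   unassigned steps default to spin 1/2, degeneracy 1.
#' @param overlap_fraction Integral fraction of the analysed multiplet
#'   relative to the whole region (only for partially overlapping
#'   multiplets; see [analyze_overlapped()]).
#' @param overlap_direction Walk direction for overlapped analyses:
#'   `"L2R"` analyses the left multiplet, `"R2L"` the right one.
#' @param prominence Relative prominence threshold for extremum detection.
#' @param max_steps Maximum number of simplification steps.
#' @return An object of class `analysis_options`.
#' @export
analysis_options <- function(j_floor_hz = 1, j_max_hz = NULL,
                             degeneracy_tol_hz = 0.5,
                             validation_threshold = 0.99,
                             success_threshold = 0.8,
                             extremum_slack = 0.05,
                             choice_policy = c("first_above_threshold",
                                               "best_within_slack"),
                             symmetrize_input = FALSE,
                             symmetrize_each_step = TRUE,
                             direction_policy = c("both_sum", "best_half",
                                                  "left_only", "right_only"),
                             remove_offset = TRUE,
                             second_derivative = FALSE,
                             refine = TRUE,
                             sharpen_scan = TRUE,
                             theta_scan = FALSE,
                             theta_max_deg = 20, theta_step_deg = 0.25,
                             spin_map = NULL,
                             overlap_fraction = NULL,
                             overlap_direction = c("L2R", "R2L"),
                             prominence = 0.02,
                             max_steps = 12L) {
  direction_policy <- match.arg(direction_policy)
  overlap_direction <- match.arg(overlap_direction)
  choice_policy <- match.arg(choice_policy)
  if (j_floor_hz <= 0) stop("j_floor_hz must be positive")
  if (degeneracy_tol_hz < 0) stop("degeneracy_tol_hz must be >= 0")
  if (validation_threshold <= 0 || validation_threshold > 1)
    stop("validation_threshold must lie in (0, 1]")
  if (!is.null(overlap_fraction) &&
      (overlap_fraction <= 0 || overlap_fraction > 1))
    stop("overlap_fraction must lie in (0, 1]")
  structure(as.list(environment()), class = "analysis_options")
}

#' Result of a multiplet analysis
#'
#' @param center_hz Multiplet position (Hz).
#' @param couplings List of [coupling_spec()], sorted descending in J.
#' @param residual_singlet [spectrum1d()] with the final simplified shape.
#' @param validation_score Normalized scalar product of the reconstruction
#'   with the source region.
#' @param validated Logical: did the score reach the validation threshold?
#' @param partner_estimates List of second-order fits (possibly empty).
#' @param strategy_used Named list recording the option set used.
#' @param steps Per-step records (splitting, score, working region).
#' @return An object of class `multiplet_result`.
#' @export
multiplet_result <- function(center_hz, couplings, residual_singlet,
                             validation_score = NA_real_, validated = FALSE,
                             partner_estimates = list(),
                             strategy_used = list(), steps = list()) {
  couplings <- as_coupling_list(couplings)
  ord <- order(-vapply(couplings, `[[`, numeric(1), "j_hz"))
  couplings <- couplings[ord]
  structure(list(center_hz = center_hz, couplings = couplings,
                 residual_singlet = residual_singlet,
                 validation_score = validation_score, validated = validated,
                 multiplicity_string = multiplicity_string(couplings, validated),
                 partner_estimates = partner_estimates,
                 strategy_used = strategy_used, steps = steps),
            class = "multiplet_result")
}

#' @export
print.multiplet_result <- function(x, ...) {
  cat(result_text(x), "\n")
  invisible(x)
}

#' Conventional one-line description of a result
#'
#' E.g. `"ddd, J = 9.90, 6.32, 4.22 Hz (score 0.997)"`, prefixed by the
#' chemical shift when the observe frequency is known.
#'
#' @param result A [multiplet_result()].
#' @param digits Decimals for J values (default 2).
#' @return A character scalar.
#' @export
result_text <- function(result, digits = 2) {
  mhz <- result$residual_singlet$spectrometer_mhz
  pos <- if (!is.null(mhz))
    sprintf("δ %.3f, ", result$center_hz / mhz)
  else sprintf("%.2f Hz, ", result$center_hz)
  js <- vapply(result$couplings, `[[`, numeric(1), "j_hz")
  jtxt <- if (length(js))
    sprintf(", J = %s Hz", paste(formatC(js, digits = digits, format = "f"),
                                 collapse = ", "))
  else ""
  flag <- if (any(vapply(result$couplings, `[[`, logical(1), "unresolved")))
    " [sub-linewidth coupling(s): use with care]" else ""
  sprintf("%s%s%s (score %.3f)%s", pos, result$multiplicity_string, jtxt,
          result$validation_score, flag)
}

#' Conventional multiplicity label
#'
#' Descending-J concatenation of the standard letters (d, t, q, quint,
#' sext, hept, ...), degeneracy grouping applied; partners with spin > 1/2
#' are labelled by their 2S+1 equal lines (a 1:1:1:1 quartet is a "q").
#' `"m"` when the result failed validation, `"s"` for no couplings.
#'
#' @param couplings List of [coupling_spec()].
#' @param validated Logical; `FALSE` gives `"m"`.
#' @return A character scalar.
#' @export
multiplicity_string <- function(couplings, validated = TRUE) {
  if (!validated) return("m")
  couplings <- as_coupling_list(couplings)
  if (!length(couplings)) return("s")
  letters_ <- c("s", "d", "t", "q", "quint", "sext", "hept", "oct", "non", "dec")
  lab <- function(cs) {
    if (cs$spin == 0.5) {
      if (cs$degeneracy + 1 <= length(letters_)) letters_[cs$degeneracy + 1]
      else sprintf("%d-let", cs$degeneracy + 1)
    } else {
      n <- as.integer(round(2 * cs$spin + 1))
      base <- if (n <= length(letters_)) letters_[n] else sprintf("%d-let", n)
      paste(rep(base, cs$degeneracy), collapse = "")
    }
  }
  ord <- order(-vapply(couplings, `[[`, numeric(1), "j_hz"))
  paste(vapply(couplings[ord], lab, character(1)), collapse = "")
}

#' Group near-equal couplings as degenerate
#'
#' Single-linkage grouping of extracted J values: values differing by less
#' than `tol_hz` (chained) form one group, reported as a single coupling
#' with degeneracy equal to the group size and J equal to the group mean.
#'
#' @param j_hz Numeric vector of extracted splittings.
#' @param tol_hz Grouping threshold (default 0.5 Hz).
#' @param spin Partner spin for the returned specs (default 1/2).
#' @return List of [coupling_spec()], descending in J.
#' @export
group_degenerate <- function(j_hz, tol_hz = 0.5, spin = 0.5) {
  if (!length(j_hz)) return(list())
  j <- sort(as.numeric(j_hz), decreasing = TRUE)
  grp <- cumsum(c(TRUE, -diff(j) > tol_hz))
  unname(lapply(split(j, grp),
                function(g) coupling_spec(mean(g), spin, length(g))))
}

# resolution-enhanced copy for extremum localization: negated second
# derivative of a Gaussian-smoothed (sigma ~ fwhm/5) copy — narrow quality
# extrema at tolerable noise amplification
sharpen_region <- function(x, step, fwhm) {
  sg <- max(fwhm / 5, step)
  half <- ceiling(3 * sg / step)
  k <- stats::dnorm(seq(-half, half) * step, sd = sg)
  k <- k / sum(k)
  n <- length(x)
  xs <- stats::convolve(c(rep(x[1], half), x, rep(x[n], half)), rev(k),
                        type = "filter")
  d2 <- numeric(n)
  d2[2:(n - 1)] <- xs[1:(n - 2)] - 2 * xs[2:(n - 1)] + xs[3:n]
  -d2
}

# mirror a vector about a (fractional, 1-based) centre index
symmetrize_vec <- function(x, cidx) {
  n <- length(x)
  mir <- cpp_shift_interp(rev(x), (n + 1) - 2 * cidx)
  (x + mir) / 2
}

# align the two sub-multiplets onto the original multiplet centre and
# combine them into the next working region
combine_sides <- function(out, policy, cidx) {
  half <- out$margin_pts / 2
  La <- cpp_shift_interp(out$s_left, -half)
  Ra <- cpp_shift_interp(out$s_right, half)
  switch(policy,
         both_sum = (La + Ra) / 2,
         left_only = La,
         right_only = Ra,
         best_half = {
           n <- length(La)
           m <- min(n - 1L, max(1L, as.integer(round(cidx))))
           c(La[seq_len(m)], Ra[seq(m + 1L, n)])
         })
}

#' Extract the coupling constants of one multiplet
#'
#' The recursive simplification: scan the quality function from large trial
#' splittings downward, accept the first extremum whose score passes the
#' success threshold (aiming at the largest coupling first both limits
#' artifact accumulation and sidesteps the spurious J/(2n+1) extrema),
#' deconvolve at that splitting, and repeat on the simplified multiplet
#' until no acceptable extremum remains above the floor. Near-equal
#' splittings are then grouped as degenerate and the result validated by
#' reconstruction.
#'
#' @param region A [spectrum1d()] containing one multiplet (for partially
#'   overlapping multiplets set `overlap_fraction` in the options; the call
#'   is then dispatched to [analyze_overlapped()]).
#' @param options An [analysis_options()].
#' @return A [multiplet_result()].
#' @examples
#' s <- synth_multiplet(list(coupling_spec(9.9), coupling_spec(6.32),
#'                           coupling_spec(4.22)),
#'                      ls = lineshape(fwhm_hz = 1.35), step_hz = 0.1)
#' extract_couplings(s)
#' @export
extract_couplings <- function(region, options = analysis_options()) {
  stopifnot(inherits(region, "spectrum1d"))
  opt <- options
  if (!is.null(opt$overlap_fraction) && opt$overlap_fraction < 1)
    return(analyze_overlapped(region, opt))
  step <- region$step_hz
  n <- length(region$amplitudes)
  W <- (n - 1) * step
  if (W / 2 <= max(opt$j_floor_hz, 2 * step))
    stop("region too narrow for the J* floor")
  prep <- preprocess(region, remove_offset = opt$remove_offset,
                     second_derivative = opt$second_derivative,
                     symmetrize = opt$symmetrize_input)
  center <- centroid_hz(prep)
  cidx <- (center - region$start_hz) / step + 1
  work <- prep$amplitudes
  spin_queue <- opt$spin_map
  raw_j <- numeric(); raw_spin <- numeric()
  steps <- list()
  trailing_reject <- FALSE
  jmax_cur <- opt$j_max_hz %||% (W / 2)
  for (s in seq_len(opt$max_steps)) {
    sp <- 0.5; dg <- 1L
    if (length(spin_queue)) {
      sp <- spin_queue[[1]]$spin %||% 0.5
      dg <- as.integer(spin_queue[[1]]$degeneracy %||% 1L)
    }
    if (jmax_cur <= max(opt$j_floor_hz, 2 * step)) break
    curve <- scan_quality(work, step, j_max_hz = jmax_cur,
                          j_floor_hz = opt$j_floor_hz, spin = sp,
                          mode = "symmetry", prominence = opt$prominence)
    ex <- curve$extrema
    ex <- ex[ex$score >= opt$success_threshold, , drop = FALSE]
    if (identical(opt$choice_policy, "best_within_slack") && nrow(ex))
      ex <- ex[ex$score >= max(ex$score) - opt$extremum_slack, , drop = FALSE]
    if (!nrow(ex)) break
    # scan order: largest J* first; combination artifacts above a true
    # coupling are caught by the halving gate below, and the spurious
    # J/(2n+1) extrema lie below it by construction
    j <- ex$j_hz[1]
    if (isTRUE(opt$sharpen_scan)) {
      # two couplings closer than the linewidth share one broad extremum in
      # the plain curve; the sharpened copy resolves them — take the largest
      # splitting the narrow extrema offer around the plain choice
      fw <- tryCatch(measure_fwhm(spectrum1d(pmax(work, 0), region$start_hz,
                                             step)),
                     error = function(e) NA_real_)
      if (is.finite(fw) && fw > 4 * step) {
        sharp <- sharpen_region(work, step, fw)
        lo <- max(opt$j_floor_hz, 2.5 * step, j - fw)
        hi <- min(jmax_cur, j + fw)
        if (hi > lo + step) {
          qs <- tryCatch(scan_quality(sharp, step,
                                      j_grid_hz = seq(hi, lo, by = -step / 2),
                                      spin = sp, mode = "symmetry",
                                      prominence = opt$prominence),
                         error = function(e) NULL)
          if (!is.null(qs) && nrow(qs$extrema)) {
            exs <- qs$extrema
            exs <- exs[exs$score >= max(exs$score) - opt$extremum_slack, ,
                       drop = FALSE]
            if (nrow(exs)) j <- exs$j_hz[1]
          }
        }
      }
    }
    snapshot <- spectrum1d(work, region$start_hz, step,
                           region$spectrometer_mhz)
    # a successful simplification collapses the 2S+1 equal lines into one,
    # so the absolute sum must drop to ~1/(2S+1) of its value; anything
    # else is an artifact posing as a splitting and ends the recursion
    ok <- TRUE
    work_try <- work
    for (k in seq_len(dg)) {
      before <- soft_abs_sum(work_try)
      out <- deconv_both(work_try, step, j, spin = sp)
      cand <- combine_sides(out, opt$direction_policy, cidx)
      if (opt$symmetrize_each_step) cand <- symmetrize_vec(cand, cidx)
      ratio <- soft_abs_sum(cand) / before * (2 * sp + 1)
      if (!is.finite(ratio) || ratio < 0.5 || ratio > 1.3) { ok <- FALSE; break }
      work_try <- cand
    }
    if (!ok) {  # artifact: resume the scan below the rejected extremum
      trailing_reject <- TRUE
      jmax_cur <- j - step / 2
      next
    }
    trailing_reject <- FALSE
    work <- work_try
    steps[[length(steps) + 1L]] <-
      list(j_hz = j, spin = sp, score = ex$score[1], region = snapshot)
    raw_j <- c(raw_j, rep(j, dg)); raw_spin <- c(raw_spin, rep(sp, dg))
    if (length(spin_queue)) spin_queue <- spin_queue[-1]
    jmax_cur <- min(jmax_cur, j + max(opt$degeneracy_tol_hz, step))
  }
  residual <- spectrum1d(work, region$start_hz, step, region$spectrometer_mhz)
  couplings <- list()
  for (sp in unique(raw_spin)) {
    jj <- raw_j[raw_spin == sp]
    couplings <- c(couplings,
                   group_degenerate(jj, opt$degeneracy_tol_hz, spin = sp))
  }
  if (isTRUE(opt$refine))
    couplings <- confirm_degeneracy(couplings, raw_j, raw_spin,
                                    validation_source(region, opt), residual,
                                    centroid_hz(prep), step,
                                    opt$degeneracy_tol_hz)
  # flag sub-linewidth couplings
  fw <- tryCatch(measure_fwhm(residual), error = function(e) NA_real_)
  if (is.finite(fw))
    couplings <- lapply(couplings, function(cs) {
      if (cs$j_hz < fw) cs$unresolved <- TRUE
      cs
    })
  if (isTRUE(opt$refine)) {
    couplings <- prune_unresolved(couplings, validation_source(region, opt),
                                  residual, centroid_hz(prep))
    couplings <- polish_couplings(couplings, validation_source(region, opt),
                                  residual, centroid_hz(prep), step)
  }
  res <- multiplet_result(center_hz = center, couplings = couplings,
                          residual_singlet = residual,
                          strategy_used = strategy_record(opt),
                          steps = steps)
  # a trailing rejected extremum means structure remained that no clean
  # simplification explains: the residual is then not a single line
  res$incomplete <- trailing_reject
  res <- run_theta_scan(res, opt)
  val <- validate_by_reconstruction(res, validation_source(region, opt),
                                    threshold = opt$validation_threshold)
  res$validation_score <- val$score
  res$validated <- val$pass
  res$multiplicity_string <- multiplicity_string(res$couplings, val$pass)
  res
}

# the spectrum validation compares against: offset/derivative preprocessing
# applied (the extraction operated on that version), but never symmetrized.
validation_source <- function(region, opt) {
  preprocess(region, remove_offset = opt$remove_offset,
             second_derivative = opt$second_derivative)
}

strategy_record <- function(opt) {
  list(symmetrize_input = opt$symmetrize_input,
       symmetrize_each_step = opt$symmetrize_each_step,
       direction_policy = opt$direction_policy,
       choice_policy = opt$choice_policy,
       remove_offset = opt$remove_offset,
       second_derivative = opt$second_derivative,
       theta_scan = opt$theta_scan,
       j_floor_hz = opt$j_floor_hz,
       success_threshold = opt$success_threshold)
}

# roof-angle refinement of extracted doublet splittings
run_theta_scan <- function(res, opt) {
  if (!isTRUE(opt$theta_scan)) return(res)
  fits <- list()
  for (st in res$steps) {
    if (st$spin != 0.5) next
    ft <- fit_theta(st$region, j_hz = st$j_hz,
                    theta_max_rad = opt$theta_max_deg * pi / 180,
                    theta_step_rad = opt$theta_step_deg * pi / 180)
    if (ft$theta_rad == 0) next
    # attach the angle to the matching (non-degenerate) coupling
    for (i in seq_along(res$couplings)) {
      cs <- res$couplings[[i]]
      if (cs$spin == 0.5 && cs$degeneracy == 1L &&
          abs(cs$j_hz - st$j_hz) <= opt$degeneracy_tol_hz) {
        res$couplings[[i]]$theta_rad <- ft$theta_rad
        break
      }
    }
    # for a plain tilted doublet, rebuild the residual with the tilted
    # recursion (the theta = 0 walk and any symmetrization distort it)
    if (length(res$couplings) == 1L && length(res$steps) == 1L) {
      reg <- st$region
      out <- deconv_both(reg$amplitudes, reg$step_hz, st$j_hz,
                         spin = 0.5, theta_rad = ft$theta_rad)
      cidx <- (centroid_hz(reg) - reg$start_hz) / reg$step_hz + 1
      resid <- combine_sides(out, "both_sum", cidx)
      res$residual_singlet <- spectrum1d(resid, reg$start_hz, reg$step_hz,
                                         reg$spectrometer_mhz)
    }
    mhz <- st$region$spectrometer_mhz
    if (!is.null(mhz)) {
      # doublet line midpoint: centroid corrected for the intensity tilt
      mid_hz <- centroid_hz(st$region) -
        sign(ft$theta_rad) * (st$j_hz / 2) * sin(abs(ft$theta_rad))
      noise <- margin_noise_sd(st$region)
      amp <- max(abs(st$region$amplitudes))
      sigma_r <- if (amp > 0) sqrt(2) * noise / amp else 0
      fits[[length(fits) + 1L]] <-
        partner_shift(mid_hz / mhz, st$j_hz, ft$theta_rad, mhz, sigma_r)
    }
  }
  res$partner_estimates <- fits
  res
}

# A splitting below the linewidth leaves almost no trace in the data, so a
# noise-born extremum can masquerade as one. Keep an unresolved coupling
# only when the synthetic-lineshape reconstruction is genuinely better with
# it than without it; a ghost's removal leaves the match unchanged or
# improves it.
prune_unresolved <- function(couplings, source, residual, center_hz) {
  lscore <- function(cpl) {
    r <- multiplet_result(center_hz, cpl, residual)
    as.numeric(validate_by_reconstruction(r, source, "lorentzian")$score)
  }
  repeat {
    idx <- which(vapply(couplings, function(cs)
      isTRUE(cs$unresolved) && cs$spin == 0.5, logical(1)))
    if (!length(idx)) return(couplings)
    changed <- FALSE
    for (i in idx[order(vapply(couplings[idx], `[[`, numeric(1), "j_hz"))]) {
      with_sc <- lscore(couplings)
      reduced <- couplings
      if (reduced[[i]]$degeneracy > 1L)
        reduced[[i]]$degeneracy <- reduced[[i]]$degeneracy - 1L
      else reduced <- reduced[-i]
      without_sc <- lscore(reduced)
      if (max(with_sc, without_sc) < 0.95) next  # fit not credible here
      if (without_sc >= with_sc - 1e-3) {
        couplings <- reduced
        changed <- TRUE
        break
      }
    }
    if (!changed) return(couplings)
  }
}

# Two extracted splittings within the grouping tolerance are merged as
# degenerate, but near the tolerance boundary they may be two genuinely
# distinct couplings whose estimates drifted together. When the raw values
# behind a group are spread wider than the grid, keep the group only if the
# synthetic reconstruction does not clearly prefer the ungrouped variant
# (parsimony wins ties).
confirm_degeneracy <- function(couplings, raw_j, raw_spin, source, residual,
                               center_hz, step, tol_hz) {
  lscore <- function(cpl) {
    r <- multiplet_result(center_hz, cpl, residual)
    as.numeric(validate_by_reconstruction(r, source, "lorentzian")$score)
  }
  out <- list()
  for (cs in couplings) {
    if (cs$spin != 0.5 || cs$degeneracy < 2L) { out <- c(out, list(cs)); next }
    members <- raw_j[raw_spin == 0.5 & abs(raw_j - cs$j_hz) <=
                       cs$degeneracy * tol_hz]
    if (length(members) != cs$degeneracy ||
        diff(range(members)) <= 2 * step) { out <- c(out, list(cs)); next }
    others <- couplings[!vapply(couplings, identical, logical(1), cs)]
    grouped_sc <- lscore(couplings)
    ungrouped <- c(others, lapply(members, coupling_spec))
    ungrouped_sc <- lscore(ungrouped)
    if (is.finite(ungrouped_sc) && ungrouped_sc > grouped_sc + 5e-5)
      out <- c(out, lapply(members, coupling_spec))
    else out <- c(out, list(cs))
  }
  out
}

# Final polish: the recursion accumulates a small bias in each J (every
# step inherits the previous steps' artifacts), so each splitting is
# re-fitted on the source region by maximizing the synthetic-Lorentzian
# reconstruction match, one coordinate at a time. Only engaged when the
# Lorentzian model credibly fits (score >= 0.97), and a refit is kept only
# when it improves the match.
polish_couplings <- function(couplings, source, residual, center_hz, step) {
  if (!length(couplings)) return(couplings)
  src <- as_amplitudes(source)
  ns <- sqrt(sum(src^2))
  if (ns == 0) return(couplings)
  x_rel <- (if (inherits(source, "spectrum1d")) freq_axis(source)
            else (seq_along(src) - 1) * step) - center_hz
  sc_with_width <- function(cpl, wd) {
    pat <- coupling_pattern(cpl)
    recon <- numeric(length(src))
    prof <- lineshape("lorentzian", wd)
    for (k in seq_along(pat$offsets_hz))
      recon <- recon + pat$weights[k] *
        lineshape_profile(prof, x_rel - pat$offsets_hz[k], step)
    nr <- sqrt(sum(recon^2))
    if (nr == 0) 0 else sum(recon * src) / (nr * ns)
  }
  w0 <- tryCatch(measure_fwhm(residual), error = function(e) 5 * step)
  if (!is.finite(w0) || w0 <= 0) w0 <- 5 * step
  wfit <- exp(optimize(function(lw) -sc_with_width(couplings, exp(lw)),
                       lower = log(max(2 * step, w0 / 8)),
                       upper = log(max(w0 * 2, 10 * step)))$minimum)
  best <- sc_with_width(couplings, wfit)
  if (best < 0.97) return(couplings)
  for (i in seq_along(couplings)) {
    j0 <- couplings[[i]]$j_hz
    half <- max(0.3, 2 * step)
    opt_j <- optimize(function(j) {
      cpl <- couplings; cpl[[i]]$j_hz <- j
      -sc_with_width(cpl, wfit)
    }, lower = max(j0 - half, 2 * step), upper = j0 + half)
    if (-opt_j$objective > best) {
      couplings[[i]]$j_hz <- opt_j$minimum
      best <- -opt_j$objective
    }
  }
  couplings
}

# absolute sum with the noise floor excised (soft threshold at twice the
# margin noise), so the halving criterion is not drowned by accumulated
# noise once most of the signal has been simplified away
soft_abs_sum <- function(x) {
  # point-to-point noise from the median absolute successive difference
  # (a smooth baseline or dispersive tail contributes almost nothing)
  nsd <- median(abs(diff(x))) / (sqrt(2) * 0.6745)
  if (!is.finite(nsd)) nsd <- 0
  sum(pmax(abs(x) - 2 * nsd, 0))
}

margin_noise_sd <- function(spec) {
  a <- as_amplitudes(spec)
  m <- max(2L, ceiling(0.05 * length(a)))
  sd(c(a[seq_len(m)], a[seq(length(a) - m + 1L, length(a))]))
}

#' Validate a result by reconstruction
#'
#' Rebuilds the multiplet from the extracted data (final singlet shape with
#' the measured couplings reintroduced, least-squares scaled) and measures
#' its similarity to the starting multiplet as a normalized scalar product;
#' a result passes when the score reaches the validation threshold
#' (default 0.99).
#'
#' @param result A [multiplet_result()].
#' @param source_region The region the extraction started from.
#' @param lineshape_policy `"residual"` (default: convolve the residual
#'   singlet — a self-consistency check) or `"lorentzian"` (multiplet
#'   simulation with a synthetic Lorentzian line whose width is fitted to
#'   best match the source under the candidate couplings; unlike the
#'   residual policy this catches under-counted multiplicities, whose
#'   leftover structure otherwise hides inside the residual shape).
#' @param threshold Pass mark (default 0.99).
#' @return List with `score` (0 with attribute `degenerate` for an all-zero
#'   region) and `pass`.
#' @export
validate_by_reconstruction <- function(result, source_region,
                                       lineshape_policy = c("residual",
                                                            "lorentzian"),
                                       threshold = 0.99) {
  lineshape_policy <- match.arg(lineshape_policy)
  src <- as_amplitudes(source_region)
  ns <- sqrt(sum(src^2))
  if (ns == 0)
    return(list(score = structure(0, degenerate = TRUE), pass = FALSE))
  score_with <- function(ls) {
    recon <- reconstruct(result, ls = ls, reference = source_region)
    nr <- sqrt(sum(recon$amplitudes^2))
    if (nr == 0) return(structure(0, degenerate = TRUE))
    sum(recon$amplitudes * src) / (nr * ns)
  }
  if (lineshape_policy == "residual") {
    score <- score_with(NULL)
  } else {
    w0 <- tryCatch(measure_fwhm(result$residual_singlet),
                   error = function(e) NA_real_)
    step <- if (inherits(source_region, "spectrum1d"))
      source_region$step_hz else result$residual_singlet$step_hz
    if (!is.finite(w0) || w0 <= 0) w0 <- 5 * step
    W <- (length(src) - 1) * step
    opt <- optimize(function(lw) -score_with(lineshape("lorentzian", exp(lw))),
                    lower = log(max(2 * step, w0 / 8)),
                    upper = log(min(W / 3, max(w0 * 2, 10 * step))))
    score <- -opt$objective
  }
  list(score = score, pass = as.numeric(score) >= threshold)
}

#' Test higher degeneracy against the source multiplet
#'
#' When the automatic analysis misses weak outermost lines it under-counts
#' the multiplicity and validation fails. This post-processing hill-climbs
#' over degeneracy variants — raising each coupling's multiplicity
#' (d, t, q, ..., up to the heptet of two methyl groups) and merging
#' near-equal couplings into one degenerate group — re-scoring each variant
#' by reconstruction, and returns the best-scoring result (the input
#' unchanged when nothing improves).
#'
#' @param result A [multiplet_result()] (typically one that failed or
#'   marginally passed validation).
#' @param source_region The region the extraction started from.
#' @param options An [analysis_options()] (tolerances, thresholds).
#' @param lineshape_policy Passed to [validate_by_reconstruction()].
#' @return A [multiplet_result()] with updated couplings and score.
#' @export
post_degeneracy_search <- function(result, source_region,
                                   options = analysis_options(),
                                   lineshape_policy = "lorentzian") {
  score_of <- function(cpl) {
    r2 <- result; r2$couplings <- cpl
    as.numeric(validate_by_reconstruction(r2, source_region,
                                          lineshape_policy,
                                          options$validation_threshold)$score)
  }
  best <- result$couplings
  best_score <- score_of(best)
  for (round in 1:8) {
    improved <- FALSE
    variants <- list()
    for (i in seq_along(best)) {
      if (best[[i]]$spin != 0.5) next
      # raise by one and by two: the +2 jump is needed because an even and
      # an odd multiplicity place their lines on combs shifted by half a
      # splitting, so the score is not monotone in single steps
      for (up in 1:2) {
        if (best[[i]]$degeneracy + up > 8L) next
        v <- best; v[[i]]$degeneracy <- v[[i]]$degeneracy + up
        variants[[length(variants) + 1L]] <- v
      }
    }
    if (length(best) >= 2) {
      js <- vapply(best, `[[`, numeric(1), "j_hz")
      ord <- order(-js)
      for (k in seq_len(length(ord) - 1)) {
        i <- ord[k]; j <- ord[k + 1]
        if (best[[i]]$spin != 0.5 || best[[j]]$spin != 0.5) next
        if (abs(best[[i]]$j_hz - best[[j]]$j_hz) >
            3 * options$degeneracy_tol_hz) next
        d1 <- best[[i]]$degeneracy; d2 <- best[[j]]$degeneracy
        v <- best
        v[[i]] <- coupling_spec((best[[i]]$j_hz * d1 + best[[j]]$j_hz * d2) /
                                  (d1 + d2), 0.5, d1 + d2)
        v[[j]] <- NULL
        variants[[length(variants) + 1L]] <- v
      }
    }
    for (v in variants) {
      sc <- score_of(v)
      if (sc > best_score + 1e-9) { best <- v; best_score <- sc; improved <- TRUE }
    }
    if (!improved) break
  }
  res <- result
  res$couplings <- as_coupling_list(best)
  ord <- order(-vapply(res$couplings, `[[`, numeric(1), "j_hz"))
  res$couplings <- res$couplings[ord]
  res$validation_score <- best_score
  res$validated <- best_score >= options$validation_threshold
  res$multiplicity_string <- multiplicity_string(res$couplings, res$validated)
  res
}

#' Analyse one of two partially overlapping multiplets
#'
#' Signal overlap over a distance smaller than the largest coupling of the
#' analysed multiplet can be handled by running the deconvolution one-sided
#' from the non-overlapped edge: a successful first step eliminates the
#' second occurrence of the sub-multiplet, and with it the overlap. Success
#' is measured by the half-integral criterion restricted to the analysed
#' multiplet's integral share f (the sub-multiplet's absolute sum must reach
#' f/2 of the region total); the walk is then truncated where the running
#' absolute integral reaches that target and the remaining (now isolated)
#' sub-multiplet is analysed recursively.
#'
#' @param region A [spectrum1d()] holding both multiplets.
#' @param options An [analysis_options()] with `overlap_fraction` set to the
#'   analysed multiplet's integral fraction and `overlap_direction` to
#'   `"L2R"` (left multiplet) or `"R2L"` (right one). `overlap_fraction = 1`
#'   reduces exactly to [extract_couplings()].
#' @return A [multiplet_result()] for the analysed multiplet. Errors with
#'   "overlap too severe" when no first-step splitting passes the success
#'   threshold.
#' @export
analyze_overlapped <- function(region, options = analysis_options()) {
  stopifnot(inherits(region, "spectrum1d"))
  opt <- options
  f <- opt$overlap_fraction %||% 1
  if (f >= 1) {
    opt$overlap_fraction <- NULL
    return(extract_couplings(region, opt))
  }
  dirn <- opt$overlap_direction
  side <- if (dirn == "L2R") "left" else "right"
  step <- region$step_hz
  prep <- preprocess(region, remove_offset = opt$remove_offset)
  work <- prep$amplitudes
  tot <- sum(abs(work))
  W <- (length(work) - 1) * step
  curve <- scan_quality(work, step, j_max_hz = opt$j_max_hz %||% (W / 2),
                        j_floor_hz = opt$j_floor_hz,
                        mode = "half_integral", side = side,
                        overlap_fraction = f, prominence = opt$prominence)
  ex <- curve$extrema
  # absolute threshold only: the half-integral scores of an overlapped
  # region are not comparable across J* the way symmetry scores are
  ex <- ex[ex$score >= opt$success_threshold, , drop = FALSE]
  if (!nrow(ex))
    stop("overlap too severe: no splitting passes the success threshold ",
         "(overlap wider than the largest coupling?)")
  j1 <- ex$j_hz[1]
  out <- side_deconv(work, step, j1, direction = dirn)
  walk <- if (dirn == "L2R") out else rev(out)
  cut <- which(cumsum(abs(walk)) >= f * tot / 2)[1]
  if (is.na(cut)) cut <- length(walk)
  walk[seq(min(cut + 1L, length(walk)), length(walk))] <- 0
  trunc <- if (dirn == "L2R") walk else rev(walk)
  sub <- spectrum1d(trunc, region$start_hz, step, region$spectrometer_mhz)
  inner_opt <- opt
  inner_opt$overlap_fraction <- NULL
  inner_opt$remove_offset <- FALSE
  inner_opt$refine <- FALSE
  inner_opt$sharpen_scan <- FALSE  # the cut edge derails the derivative
  inner_opt$j_max_hz <- j1 + max(opt$degeneracy_tol_hz, step)
  inner <- extract_couplings(sub, inner_opt)
  inner_js <- unlist(lapply(inner$couplings,
                            function(cs) rep(cs$j_hz, cs$degeneracy)))
  couplings <- group_degenerate(c(j1, inner_js), opt$degeneracy_tol_hz)
  # the sub-multiplet sits half an arm towards the starting edge
  center <- inner$center_hz + (if (dirn == "L2R") j1 / 2 else -j1 / 2)
  # validate against the leading edge of the region: when the overlap is
  # shallower than the largest coupling, the outer quarter (by integral) of
  # the analysed multiplet's share is free of the neighbour, so the full
  # reconstruction must match the data there
  cw <- if (dirn == "L2R") cumsum(abs(work)) else rev(cumsum(rev(abs(work))))
  lead <- which(cw <= 0.25 * f * tot)
  pat <- coupling_pattern(couplings)
  x_rel <- freq_axis(prep) - center
  w0 <- tryCatch(measure_fwhm(inner$residual_singlet),
                 error = function(e) 5 * step)
  if (!is.finite(w0) || w0 <= 0) w0 <- 5 * step
  edge_with <- function(wd) {
    recon <- numeric(length(x_rel))
    for (k in seq_along(pat$offsets_hz))
      recon <- recon + pat$weights[k] *
        lineshape_profile(lineshape("lorentzian", wd),
                          x_rel - pat$offsets_hz[k], step)
    den <- sqrt(sum(recon[lead]^2)) * sqrt(sum(work[lead]^2))
    if (den > 0) sum(recon[lead] * work[lead]) / den else 0
  }
  edge_score <- if (length(lead) > 8)
    -optimize(function(lw) -edge_with(exp(lw)),
              lower = log(max(2 * step, w0 / 8)),
              upper = log(max(w0 * 2, 10 * step)))$objective
  else 0
  if (edge_score < opt$validation_threshold)
    stop(sprintf(paste("overlap too severe: reconstruction does not match",
                       "the non-overlapped edge (score %.3f); separation",
                       "requires the overlap to be narrower than the",
                       "largest coupling"), edge_score))
  res <- multiplet_result(center_hz = center, couplings = couplings,
                          residual_singlet = inner$residual_singlet,
                          validation_score = edge_score,
                          validated = TRUE,
                          strategy_used = c(strategy_record(opt),
                                            list(overlap_fraction = f,
                                                 overlap_direction = dirn)),
                          steps = c(list(list(j_hz = j1, spin = 0.5,
                                              score = ex$score[1],
                                              region = prep)),
                                    inner$steps))
  res$multiplicity_string <- multiplicity_string(res$couplings, res$validated)
  res
}

#' Search over deconvolution strategies
#'
#' Different parameter sets driving the deconvolution suit different data
#' (symmetrization helps noisy absorptive multiplets but breaks misphased
#' ones, etc.). This runs [extract_couplings()] for every option set of a
#' grid, validates each result (applying [post_degeneracy_search()] to
#' failures), and ranks by validation score; ties are broken by fewer
#' couplings (parsimony), then by the larger smallest J.
#'
#' @param region A [spectrum1d()].
#' @param base_options An [analysis_options()] supplying everything the grid
#'   does not vary.
#' @param option_grid A data frame whose columns are option names and rows
#'   option sets; default: all combinations of `symmetrize_input` and
#'   `symmetrize_each_step`.
#' @return A list of [multiplet_result()]s, best first. Option sets whose
#'   run errors are dropped.
#' @export
strategy_search <- function(region, base_options = analysis_options(),
                            option_grid = NULL) {
  if (is.null(option_grid))
    option_grid <- expand.grid(symmetrize_input = c(FALSE, TRUE),
                               symmetrize_each_step = c(FALSE, TRUE),
                               choice_policy = c("first_above_threshold",
                                                 "best_within_slack"),
                               stringsAsFactors = FALSE)
  if (!nrow(option_grid)) stop("empty option grid")
  results <- list()
  for (i in seq_len(nrow(option_grid))) {
    opt <- base_options
    for (nm in names(option_grid)) opt[[nm]] <- option_grid[i, nm]
    res <- tryCatch({
      r <- extract_couplings(region, opt)
      if (!r$validated || isTRUE(r$incomplete))
        r <- post_degeneracy_search(r, validation_source(region, opt), opt)
      r
    }, error = function(e) NULL)
    if (!is.null(res)) results[[length(results) + 1L]] <- res
  }
  if (!length(results)) return(results)
  nj <- vapply(results, function(r)
    sum(vapply(r$couplings, `[[`, integer(1), "degeneracy")), integer(1))
  minj <- vapply(results, function(r) {
    js <- vapply(r$couplings, `[[`, numeric(1), "j_hz")
    if (length(js)) min(js) else Inf
  }, numeric(1))
  sc <- vapply(results, function(r) as.numeric(r$validation_score), numeric(1))
  results[order(-sc, nj, -minj)]
}
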