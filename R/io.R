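#' Read a 1D spectrum from JCAMP-DX or two-column text
#'
#' JCAMP-DX: `##XYDATA= (X++(Y..Y))` tables in AFFN or with SQZ / DIF / DUP
#' compression; the frequency axis is rebuilt from `##FIRSTX`, `##LASTX`,
#' `##NPOINTS` (and `##XFACTOR` / `##YFACTOR` scaling), the observe
#' frequency from `##.OBSERVE FREQUENCY`. Descending axes are reversed so
#' the internal representation always has a positive Hz step. Two-column
#' text: frequency (Hz) and amplitude, whitespace- or tab-separated; the
#' grid must be uniform (rejected otherwise, reporting the measured
#' spacing spread). A missing observe frequency leaves the spectrum in
#' Hz-only mode (ppm features disabled).
#'
#' @param path File path.
#' @param format `"jcampdx"`, `"xy_tsv"`, or `"auto"` (by extension:
#'   `.jdx`/`.dx`/`.jcamp` vs anything else).
#' @return A [spectrum1d()].
#' @export
read_spectrum <- function(path, format = c("auto", "jcampdx", "xy_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcampdx"
    else "xy_tsv"
  }
  if (format == "jcampdx") read_jcampdx(path) else read_xy_tsv(path)
}

read_xy_tsv <- function(path) {
  d <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(d) < 2) stop("expected two numeric columns (frequency_hz, amplitude)")
  x <- as.numeric(d[[1]]); y <- as.numeric(d[[2]])
  if (anyNA(x) || anyNA(y)) stop("non-numeric values in the two-column table")
  if (x[1] > x[length(x)]) { x <- rev(x); y <- rev(y) }
  dx <- diff(x)
  spread <- max(abs(dx - median(dx)))
  if (spread > 1e-4 * abs(median(dx)))
    stop(sprintf("non-uniform frequency grid: spacing %.6g +/- %.3g Hz",
                 median(dx), spread))
  spectrum1d(y, x[1], median(dx))
}

# --- JCAMP-DX ---------------------------------------------------------------

jcamp_labels <- function(lines) {
  idx <- grep("^\\s*##", lines)
  lab <- sub("^\\s*##([^=]*)=.*$", "\\1", lines[idx])
  val <- sub("^\\s*##[^=]*=\\s*", "", lines[idx])
  names(val) <- toupper(gsub("[ _-]", "", lab))
  list(idx = idx, values = val)
}

# split one ASDF data line into tokens (AFFN numbers or pseudo-digit
# groups). Exponent notation is not recognized inside tables: "E"/"e" after
# a number is indistinguishable from the SQZ digits +5/-5, which is why
# JCAMP-DX writers avoid it there (as does ours).
asdf_tokens <- function(line) {
  line <- sub("\\$\\$.*$", "", line)  # strip comments
  m <- gregexpr("[@A-Ia-i%J-Rj-rS-Zs][0-9]*|[+-]?[0-9]*\\.?[0-9]+|\\?",
                line)[[1]]
  if (m[1] == -1) return(character())
  regmatches(line, list(m))[[1]]
}

sqz_value <- function(ch) {
  up <- match(ch, c("@", LETTERS[1:9])); if (!is.na(up)) return(up - 1)
  lo <- match(ch, letters[1:9]); if (!is.na(lo)) return(-lo)
  NA_real_
}
dif_value <- function(ch) {
  up <- match(ch, c("%", LETTERS[10:18])); if (!is.na(up)) return(up - 1)
  lo <- match(ch, letters[10:18]); if (!is.na(lo)) return(-lo)
  NA_real_
}
dup_value <- function(ch) {
  v <- match(ch, c(LETTERS[19:26], "s"))
  if (!is.na(v)) v else NA_real_
}

# decode the Y tokens of one line; returns the y values and whether the
# line ended in DIF mode (its last y is then repeated as a check value at
# the start of the next line)
asdf_decode_line <- function(tokens) {
  ys <- numeric(0)
  mode <- "affn"
  last_diff <- 0
  for (tk in tokens) {
    c1 <- substr(tk, 1, 1)
    rest <- substr(tk, 2, nchar(tk))
    if (!is.na(suppressWarnings(as.numeric(tk)))) {
      ys <- c(ys, as.numeric(tk)); mode <- "affn"
    } else if (!is.na(sqz_value(c1))) {
      v <- sqz_value(c1)
      num <- as.numeric(paste0(abs(v), rest))
      ys <- c(ys, if (v < 0) -num else num)
      mode <- "sqz"
    } else if (!is.na(dif_value(c1))) {
      v <- dif_value(c1)
      num <- (if (v < 0) -1 else 1) * as.numeric(paste0(abs(v), rest))
      if (!length(ys)) stop("DIF token with no preceding ordinate")
      last_diff <- num
      ys <- c(ys, ys[length(ys)] + num)
      mode <- "dif"
    } else if (!is.na(dup_value(c1))) {
      count <- as.numeric(paste0(dup_value(c1), rest))
      if (count < 2) stop("DUP count below 2")
      if (!length(ys)) stop("DUP token with no preceding item")
      if (mode == "dif") {
        for (k in seq_len(count - 1))
          ys <- c(ys, ys[length(ys)] + last_diff)
      } else {
        ys <- c(ys, rep(ys[length(ys)], count - 1))
      }
    } else if (tk == "?") {
      ys <- c(ys, NA_real_); mode <- "affn"
    } else stop("unrecognized token in data table: ", tk)
  }
  list(y = ys, dif_end = (mode == "dif"))
}

read_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lab <- jcamp_labels(lines)
  getl <- function(nm) {
    v <- lab$values[nm]
    if (is.na(v)) NULL else unname(v)
  }
  xy_at <- grep("^\\s*##\\s*XYDATA", lines)
  if (!length(xy_at)) stop("no ##XYDATA table found")
  xy_at <- xy_at[1]
  after <- lab$idx[lab$idx > xy_at]
  end_at <- if (length(after)) min(after) else length(lines) + 1L
  data_lines <- lines[seq(xy_at + 1L, end_at - 1L)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  yfac <- as.numeric(getl("YFACTOR") %||% "1")
  y <- numeric(0)
  pending_check <- FALSE
  for (ln in data_lines) {
    tk <- asdf_tokens(ln)
    if (length(tk) < 2) next
    dec <- asdf_decode_line(tk[-1])  # first token is the X value
    yy <- dec$y
    if (pending_check && length(yy)) yy <- yy[-1]
    y <- c(y, yy)
    pending_check <- dec$dif_end
  }
  y <- y * yfac
  np <- as.numeric(getl("NPOINTS") %||% length(y))
  if (length(y) != np)
    warning(sprintf("NPOINTS (%d) and decoded table length (%d) differ",
                    np, length(y)))
  xfac <- as.numeric(getl("XFACTOR") %||% "1")
  fx <- as.numeric(getl("FIRSTX")); lx <- as.numeric(getl("LASTX"))
  if (!length(fx) || !length(lx) || is.na(fx) || is.na(lx))
    stop("FIRSTX/LASTX missing: cannot rebuild the frequency axis")
  fx <- fx * xfac; lx <- lx * xfac
  step <- (lx - fx) / (length(y) - 1)
  if (step < 0) { y <- rev(y); fx <- lx; step <- -step }
  mhz <- getl("$OBSERVEFREQUENCY") %||% getl(".OBSERVEFREQUENCY")
  mhz <- if (is.null(mhz)) NULL else as.numeric(sub("^([0-9.eE+-]+).*$", "\\1", mhz))
  spectrum1d(y, fx, step, mhz)
}

#' Write a spectrum as two-column text
#'
#' Tab-separated `frequency_hz  amplitude`, one point per line.
#'
#' @param spec A [spectrum1d()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum1d"))
  d <- data.frame(frequency_hz = sprintf("%.8f", freq_axis(spec)),
                  amplitude = sprintf("%.10g", spec$amplitudes))
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a spectrum as JCAMP-DX
#'
#' Uncompressed AFFN `(X++(Y..Y))` table (maximal interoperability; the
#' reader additionally accepts SQZ/DIF/DUP input).
#'
#' @param spec A [spectrum1d()].
#' @param path Output path.
#' @param title `##TITLE` record.
#' @return `path`, invisibly.
#' @export
write_spectrum_jcamp <- function(spec, path, title = "jdeconv spectrum") {
  stopifnot(inherits(spec, "spectrum1d"))
  f <- freq_axis(spec)
  n <- length(spec$amplitudes)
  hdr <- c(sprintf("##TITLE= %s", title),
           "##JCAMP-DX= 4.24",
           "##DATA TYPE= NMR SPECTRUM",
           "##ORIGIN= jdeconv",
           "##OWNER= jdeconv",
           "##XUNITS= HZ",
           "##YUNITS= ARBITRARY UNITS")
  if (!is.null(spec$spectrometer_mhz))
    hdr <- c(hdr, sprintf("##.OBSERVE FREQUENCY= %.6f", spec$spectrometer_mhz))
  hdr <- c(hdr,
           sprintf("##FIRSTX= %.8f", f[1]),
           sprintf("##LASTX= %.8f", f[n]),
           sprintf("##NPOINTS= %d", n),
           "##XFACTOR= 1",
           "##YFACTOR= 1",
           sprintf("##FIRSTY= %.10f", spec$amplitudes[1]),
           "##XYDATA= (X++(Y..Y))")
  per <- 6L
  rows <- split(seq_len(n), ceiling(seq_len(n) / per))
  body <- vapply(rows, function(ii)
    paste(c(sprintf("%.6f", f[ii[1]]),
            sprintf("%.10f", spec$amplitudes[ii])), collapse = " "),
    character(1))
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}

#' Region selection for batch analysis
#'
#' @param lo_hz,hi_hz Bounds in Hz (`lo < hi`), or
#' @param lo_ppm,hi_ppm bounds in ppm.
#' @param label Optional region name.
#' @param overlap_fraction Integral fraction of the analysed multiplet when
#'   it partially overlaps a neighbour (see [analyze_overlapped()]).
#' @param overlap_direction `"L2R"` or `"R2L"` for overlapped analyses.
#' @return An object of class `region_selection`.
#' @export
region_selection <- function(lo_hz = NULL, hi_hz = NULL,
                             lo_ppm = NULL, hi_ppm = NULL, label = NULL,
                             overlap_fraction = NULL,
                             overlap_direction = "L2R") {
  if (is.null(lo_hz) && is.null(lo_ppm)) stop("region bounds required")
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz, lo_ppm = lo_ppm,
                 hi_ppm = hi_ppm, label = label,
                 overlap_fraction = overlap_fraction,
                 overlap_direction = overlap_direction),
            class = "region_selection")
}

#' Analyse a batch of multiplet regions
#'
#' For each selected region: run the strategy search, keep the best
#' validated result, optionally fit roof angles, and collect a report.
#' Per-region failures are reported as `"m"` entries and never abort the
#' batch.
#'
#' @param spec A [spectrum1d()].
#' @param selections List of [region_selection()] (a single selection is
#'   accepted).
#' @param options Base [analysis_options()].
#' @return An object of class `jdeconv_report`: list with `schema`
#'   (`"jdeconv-report/1"`) and `regions`.
#' @export
run_analysis <- function(spec, selections, options = analysis_options()) {
  if (inherits(selections, "region_selection")) selections <- list(selections)
  entries <- list()
  for (sel in selections) {
    entry <- tryCatch({
      reg <- crop_spectrum(spec, sel$lo_hz, sel$hi_hz, sel$lo_ppm, sel$hi_ppm)
      res <- if (!is.null(sel$overlap_fraction) && sel$overlap_fraction < 1) {
        opt <- options
        opt$overlap_fraction <- sel$overlap_fraction
        opt$overlap_direction <- sel$overlap_direction
        analyze_overlapped(reg, opt)
      } else {
        ranked <- strategy_search(reg, options)
        if (!length(ranked)) stop("all strategies failed")
        ranked[[1]]
      }
      result_entry(res, sel)
    }, error = function(e) {
      list(label = sel$label, multiplicity = "m", couplings = list(),
           error = conditionMessage(e))
    })
    entries[[length(entries) + 1L]] <- entry
  }
  structure(list(schema = "jdeconv-report/1", regions = entries),
            class = "jdeconv_report")
}

result_entry <- function(res, sel = NULL) {
  mhz <- res$residual_singlet$spectrometer_mhz
  list(label = if (is.null(sel)) NULL else sel$label,
       center_hz = round(res$center_hz, 4),
       center_ppm = if (!is.null(mhz)) round(res$center_hz / mhz, 4) else NULL,
       multiplicity = res$multiplicity_string,
       couplings = lapply(res$couplings, function(cs)
         list(j_hz = round(cs$j_hz, 2), spin = cs$spin,
              degeneracy = cs$degeneracy,
              theta_deg = round(cs$theta_rad * 180 / pi, 2),
              unresolved = cs$unresolved)),
       validation_score = round(as.numeric(res$validation_score), 4),
       validated = res$validated,
       partner_estimates = lapply(res$partner_estimates, function(p)
         list(partner_ppm = round(p$partner_ppm, 4),
              sigma_ppm = round(p$partner_sigma_ppm, 4),
              j_hz = round(p$j_hz, 2),
              theta_deg = round(p$theta_rad * 180 / pi, 2),
              reliable = p$reliable)),
       strategy = res$strategy_used,
       text = result_text(res))
}

#' @export
print.jdeconv_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Report as text lines / JSON
#'
#' @param report A [run_analysis()] report.
#' @return `report_text`: character vector, one line per region.
#' @export
report_text <- function(report) {
  vapply(report$regions, function(e) {
    lb <- if (!is.null(e$label)) paste0(e$label, ": ") else ""
    if (!is.null(e$error)) paste0(lb, "m (", e$error, ")")
    else paste0(lb, e$text)
  }, character(1))
}

#' @rdname report_text
#' @param path Optional path to write the JSON to.
#' @return `report_json`: the JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = 8,
                         null = "null", pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
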