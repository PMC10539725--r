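# shared synthetic fixtures; everything is generated in code

extracted_js <- function(res)
  unlist(lapply(res$couplings, function(cs) rep(cs$j_hz, cs$degeneracy)))

simple_multiplet <- function(js, fwhm = 1, step = 0.05, width = NULL,
                             noise_sd = 0, seed = NULL, ...) {
  if (is.null(width))
    width <- max(2.3 * max(js) + 10 * fwhm, sum(js) + 12 * fwhm + 10)
  synth_multiplet(lapply(js, coupling_spec), ls = lineshape(fwhm_hz = fwhm),
                  step_hz = step, width_hz = width, noise_sd = noise_sd,
                  seed = seed, ...)
}

# exact AB two-spin system: four Lorentzian lines at +/-(D +/- J)/2 around
# center_hz with outer intensities (1 - J/D)/2 and inner (1 + J/D)/2
ab_spectrum <- function(j_hz, dnu_hz, fwhm = 1.2, step = 0.05,
                        center_hz = 0, mhz = NULL, halfwidth_hz = NULL) {
  D <- sqrt(dnu_hz^2 + j_hz^2)
  if (is.null(halfwidth_hz)) halfwidth_hz <- (D + j_hz) / 2 + 30 * fwhm
  f <- seq(center_hz - halfwidth_hz, center_hz + halfwidth_hz, by = step)
  lor <- function(x) (2 / (pi * fwhm)) / (1 + (2 * x / fwhm)^2)
  pos <- center_hz + c(-(D + j_hz) / 2, -(D - j_hz) / 2,
                       (D - j_hz) / 2, (D + j_hz) / 2)
  wt <- c(1 - j_hz / D, 1 + j_hz / D, 1 + j_hz / D, 1 - j_hz / D) / 4
  amp <- numeric(length(f))
  for (k in 1:4) amp <- amp + wt[k] * lor(f - pos[k])
  spectrum1d(amp, f[1], step, mhz)
}

# two multiplets with partially overlapping tails on a common grid
overlapped_pair <- function(js_a, js_b, sep_hz, fwhm = 1.2, step = 0.05) {
  sA <- simple_multiplet(js_a, fwhm, step, width = sum(js_a) + 24 * fwhm)
  sB <- simple_multiplet(js_b, fwhm, step, width = sum(js_b) + 24 * fwhm)
  lo <- min(freq_axis(sA)) - 5
  hi <- max(freq_axis(sB)) + sep_hz + 5
  f <- seq(lo, hi, by = step)
  amp <- stats::approx(freq_axis(sA), sA$amplitudes, f,
                       yleft = 0, yright = 0)$y +
    stats::approx(freq_axis(sB) + sep_hz, sB$amplitudes, f,
                  yleft = 0, yright = 0)$y
  spectrum1d(amp, f[1], step)
}

# SQZ/DIF/DUP encoder used to build compressed JCAMP-DX twins of AFFN
# fixtures (the reader is also checked against a hand-decoded file)
jcamp_dif_write <- function(spec, path, title = "dif fixture") {
  y <- spec$amplitudes
  yfac <- max(abs(y)) / 32767
  yi <- round(y / yfac)
  enc <- function(v, zero, pos, neg) {
    s <- as.character(abs(v))
    first <- as.integer(substr(s, 1, 1))
    head <- if (v == 0) zero else if (v > 0) pos[first] else neg[first]
    paste0(head, substr(s, 2, nchar(s)))
  }
  sqz <- function(v) enc(v, "@", LETTERS[1:9], letters[1:9])
  dif <- function(v) enc(v, "%", LETTERS[10:18], letters[10:18])
  f <- freq_axis(spec)
  n <- length(yi)
  per <- 10L
  lines_out <- character()
  i <- 1L
  first_line <- TRUE
  while (i <= n) {
    jj <- i:min(i + per - 1L, n)
    toks <- if (first_line) sqz(yi[jj[1]])
    else c(sqz(yi[jj[1] - 1L]), dif(yi[jj[1]] - yi[jj[1] - 1L]))
    if (length(jj) > 1)
      toks <- c(toks, vapply(jj[-1], function(k) dif(yi[k] - yi[k - 1L]),
                             character(1)))
    lines_out <- c(lines_out,
                   paste(c(sprintf("%.6f", f[jj[1]]), toks), collapse = ""))
    first_line <- FALSE
    i <- i + per
  }
  hdr <- c(sprintf("##TITLE= %s", title), "##JCAMP-DX= 4.24",
           "##DATA TYPE= NMR SPECTRUM", "##XUNITS= HZ",
           "##YUNITS= ARBITRARY UNITS",
           sprintf("##FIRSTX= %.8f", f[1]), sprintf("##LASTX= %.8f", f[n]),
           sprintf("##NPOINTS= %d", n), "##XFACTOR= 1",
           sprintf("##YFACTOR= %.12g", yfac), "##XYDATA= (X++(Y..Y))")
  writeLines(c(hdr, lines_out, "##END="), path)
  invisible(path)
}
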