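# Raman spectrum container, first-derivative peak detection,
# characteristic-peak libraries and the qualitative (presence/absence) call.

#' Construct a Raman spectrum
#'
#' A light container for one acquired or simulated Raman trace: a strictly
#' increasing shift axis (cm-1) with matching intensities (detector counts),
#' plus optional sample metadata.
#'
#' @param shift numeric Raman shift axis, cm-1, strictly increasing,
#'   length >= 16.
#' @param intensity numeric intensities, same length, all finite.
#' @param sample_id optional sample identifier.
#' @param concentration optional spiked analyte concentration (mg/kg).
#' @return object of class `"raman_spectrum"`.
#' @export
raman_spectrum <- function(shift, intensity, sample_id = NULL,
                           concentration = NA_real_) {
  shift <- as.numeric(shift)
  intensity <- as.numeric(intensity)
  if (length(shift) != length(intensity))
    .stop_input("shift and intensity must have the same length")
  if (length(shift) < 16L)
    .stop_input("spectrum too short: at least 16 points required")
  if (any(diff(shift) <= 0)) .stop_input("shift axis must be strictly increasing")
  if (any(!is.finite(shift)) || any(!is.finite(intensity)))
    .stop_input("shift and intensity must be finite")
  structure(list(shift = shift, intensity = intensity,
                 sample_id = sample_id,
                 concentration = as.numeric(concentration)),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum%s: %d points, %g-%g cm-1%s\n",
              if (is.null(x$sample_id)) "" else paste0(" '", x$sample_id, "'"),
              length(x$shift), min(x$shift), max(x$shift),
              if (is.na(x$concentration)) ""
              else sprintf(", spiked %g mg/kg", x$concentration)))
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  graphics::plot(x$shift, x$intensity, type = "l",
                 xlab = "Raman shift (cm-1)", ylab = "Intensity (counts)", ...)
  invisible(x)
}

#' Read and write spectrum CSV files
#'
#' The on-disk format is a two-column numeric table `shift_cm1,intensity`.
#' Leading lines of the form `# key: value` carry metadata (`sample_id`,
#' `concentration`); the reader accepts comma, semicolon or tab delimiters.
#'
#' @param path file path.
#' @return `read_spectrum` returns a [raman_spectrum()];
#'   `write_spectrum` returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) .stop_input(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) .stop_input(paste0("empty spectrum file: ", path))
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) .stop_input(paste0("no spectral data in: ", path))
  sep <- c("," = ",", ";" = ";", "\t" = "\t")[
    which.max(vapply(c(",", ";", "\t"),
                     function(s) lengths(regmatches(body[1], gregexpr(s, body[1], fixed = TRUE))),
                     integer(1)))]
  tab <- utils::read.table(text = body, header = TRUE, sep = sep)
  if (ncol(tab) < 2) .stop_input(paste0("malformed spectrum file: ", path))
  conc <- if (!is.null(meta$concentration)) suppressWarnings(as.numeric(meta$concentration)) else NA_real_
  raman_spectrum(tab[[1]], tab[[2]],
                 sample_id = meta$sample_id, concentration = conc)
}

#' @rdname read_spectrum
#' @param s a [raman_spectrum()].
#' @export
write_spectrum <- function(s, path) {
  if (!inherits(s, "raman_spectrum")) .stop_input("s must be a raman_spectrum")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(s$sample_id)) writeLines(paste0("# sample_id: ", s$sample_id), con)
  if (!is.na(s$concentration))
    writeLines(paste0("# concentration: ", format(s$concentration)), con)
  writeLines("shift_cm1,intensity", con)
  writeLines(paste(format(s$shift, trim = TRUE, scientific = FALSE),
                   format(s$intensity, trim = TRUE, scientific = FALSE), sep = ","), con)
  invisible(path)
}

# rolling-minimum baseline, then lightly smoothed; optional, off by default
.rolling_min_baseline <- function(y, window) {
  n <- length(y)
  half <- window %/% 2
  mins <- vapply(seq_len(n), function(i)
    min(y[max(1, i - half):min(n, i + half)]), numeric(1))
  as.numeric(stats::filter(c(rep(mins[1], half), mins, rep(mins[n], half)),
                           rep(1 / window, window), sides = 2))[(half + 1):(half + n)]
}

# topographic prominence of smoothed local maxima
.prominence <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    j <- i
    while (j > 1L && y[j - 1L] <= h) j <- j - 1L
    left_min <- min(y[j:i])
    k <- i
    n <- length(y)
    while (k < n && y[k + 1L] <= h) k <- k + 1L
    right_min <- min(y[i:k])
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect peaks in a Raman spectrum
#'
#' Smooths the trace with a Savitzky-Golay filter, takes the first
#' derivative, and reports its downward zero crossings (local maxima of the
#' smoothed trace) whose topographic prominence reaches
#' `min_prominence_frac` of the spectrum's dynamic range (or the absolute
#' `min_prominence`, if given). Apex intensities are read from the raw,
#' unsmoothed trace so that downstream threshold comparisons do not depend
#' on the smoothing strength.
#'
#' @param s a [raman_spectrum()].
#' @param smooth_window odd Savitzky-Golay window length, `>= 5` and smaller
#'   than the spectrum; default 9.
#' @param poly_order polynomial order of the filter, default 2.
#' @param min_prominence_frac prominence floor as a fraction of
#'   `max(intensity) - min(intensity)`; default 0.02.
#' @param min_prominence absolute prominence floor in counts; overrides the
#'   relative floor when non-`NULL`.
#' @param snr_min signal-to-noise floor: prominence must also reach
#'   `snr_min` times the noise level, estimated robustly as
#'   `mad(diff(intensity)) / sqrt(2)`. Without it, a blank trace — whose
#'   dynamic range is itself noise — would yield spurious peaks everywhere
#'   under a purely relative floor. Both floors scale with the spectrum, so
#'   calls remain invariant under uniform intensity scaling. Set 0 to
#'   disable. Default 5.
#' @param baseline_correct subtract a rolling-minimum baseline before peak
#'   search (default `FALSE`; the qualitative workflow operates on raw
#'   traces).
#' @param baseline_window window (points) of the rolling minimum.
#' @return data frame with one row per detected peak, columns `position`
#'   (cm-1), `apex_intensity` (raw counts) and `prominence` (counts),
#'   sorted by position.
#' @export
detect_peaks <- function(s, smooth_window = 9, poly_order = 2,
                         min_prominence_frac = 0.02, min_prominence = NULL,
                         snr_min = 5, baseline_correct = FALSE,
                         baseline_window = 101) {
  if (!inherits(s, "raman_spectrum")) .stop_input("s must be a raman_spectrum")
  n <- length(s$shift)
  if (smooth_window %% 2 != 1 || smooth_window < 5 || smooth_window >= n)
    .stop_input("smooth_window must be odd, >= 5 and smaller than the spectrum")
  if (min_prominence_frac < 0 || min_prominence_frac >= 1)
    .stop_input("min_prominence_frac must be in [0, 1)")
  raw <- s$intensity
  y <- raw
  if (baseline_correct) y <- y - .rolling_min_baseline(y, baseline_window)
  sm <- signal::sgolayfilt(y, p = poly_order, n = smooth_window)
  d <- diff(sm)
  d[abs(d) < 1e-10 * max(abs(sm), 1)] <- 0  # filter round-off is not slope
  # downward zero crossing of the first derivative at interior point i
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[cand > 1L & cand < n]
  if (length(cand) == 0L)
    return(data.frame(position = numeric(0), apex_intensity = numeric(0),
                      prominence = numeric(0)))
  prom <- .prominence(sm, cand)
  floor_ <- if (!is.null(min_prominence)) min_prominence
            else min_prominence_frac * (max(raw) - min(raw))
  if (snr_min > 0) {
    sigma <- stats::mad(diff(raw)) / sqrt(2)
    floor_ <- max(floor_, snr_min * sigma)
  }
  keep <- prom >= floor_ & prom > 0
  data.frame(position = s$shift[cand[keep]],
             apex_intensity = raw[cand[keep]],
             prominence = prom[keep])
}

#' Characteristic-peak library
#'
#' The qualitative decision rule for one analyte: between 2 and 6
#' characteristic Raman shifts, and the shift tolerance (3-10 cm-1) within
#' which a detected peak counts as the same peak. Library peaks must be
#' separated by more than twice the tolerance so matches are unambiguous.
#'
#' @param analyte analyte name.
#' @param peaks numeric characteristic shifts, cm-1.
#' @param tolerance matching tolerance, cm-1, in `[3, 10]`; default 5.
#' @return object of class `"peak_library"`.
#' @examples
#' cbz_library()
#' @export
peak_library <- function(analyte, peaks, tolerance = 5) {
  peaks <- sort(as.numeric(peaks))
  if (length(peaks) < 2L || length(peaks) > 6L)
    .stop_input("a peak library holds between 2 and 6 characteristic peaks")
  if (tolerance < 3 || tolerance > 10)
    .stop_input("tolerance must be within [3, 10] cm-1")
  if (any(diff(peaks) <= 2 * tolerance))
    .stop_input("library peaks must be separated by more than 2 x tolerance")
  structure(list(analyte = analyte, peaks = peaks, tolerance = tolerance),
            class = "peak_library")
}

#' @export
print.peak_library <- function(x, ...) {
  cat(sprintf("Peak library '%s': %s cm-1 (tolerance %g cm-1)\n",
              x$analyte, paste(x$peaks, collapse = ", "), x$tolerance))
  invisible(x)
}

#' The carbendazim characteristic-peak library
#'
#' The six characteristic SERS shifts of carbendazim in apple matrix
#' (630, 728, 1000, 1218, 1260 and 1315 cm-1), shipped as the package's
#' reference library.
#'
#' @param tolerance matching tolerance in cm-1, default 5.
#' @export
cbz_library <- function(tolerance = 5) {
  peak_library("carbendazim", c(630, 728, 1000, 1218, 1260, 1315), tolerance)
}

#' Build a characteristic-peak library from standard and blank peaks
#'
#' Characteristic peaks are those present in the analyte standard (or spiked
#' sample) but absent from the blank matrix: every standard peak with a
#' blank peak within `tolerance` is discarded. Survivors are ranked by
#' prominence, thinned so retained peaks are separated by more than twice
#' the tolerance, and truncated to `max_peaks`.
#'
#' @param standard_peaks data frame from [detect_peaks()] on the standard.
#' @param blank_peaks data frame from [detect_peaks()] on the blank matrix
#'   (may have zero rows).
#' @param analyte analyte name recorded in the library.
#' @param tolerance matching tolerance, cm-1, in `[3, 10]`.
#' @param max_peaks maximum number of library peaks, default 6.
#' @return a [peak_library()]. Errors if fewer than two analyte-specific
#'   peaks survive.
#' @export
build_library <- function(standard_peaks, blank_peaks, analyte = "analyte",
                          tolerance = 5, max_peaks = 6) {
  if (tolerance < 3 || tolerance > 10)
    .stop_input("tolerance must be within [3, 10] cm-1")
  if (nrow(standard_peaks) == 0L)
    .stop_method("no peaks detected in the standard spectrum")
  specific <- standard_peaks
  if (!is.null(blank_peaks) && nrow(blank_peaks) > 0L) {
    clash <- vapply(specific$position, function(p)
      any(abs(blank_peaks$position - p) <= tolerance), logical(1))
    specific <- specific[!clash, , drop = FALSE]
  }
  specific <- specific[order(-specific$prominence), , drop = FALSE]
  kept <- numeric(0)
  for (i in seq_len(nrow(specific))) {
    p <- specific$position[i]
    if (all(abs(kept - p) > 2 * tolerance)) kept <- c(kept, p)
    if (length(kept) == max_peaks) break
  }
  if (length(kept) < 2L)
    .stop_method("fewer than 2 analyte-specific peaks survive; cannot build library")
  peak_library(analyte, kept, tolerance)
}

#' Read and write peak libraries as JSON
#'
#' Format: `{"analyte": ..., "peaks": [...], "tolerance_cm1": ...}`.
#'
#' @param path file path.
#' @export
read_peak_library <- function(path) {
  if (!file.exists(path)) .stop_input(paste0("no such file: ", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$analyte) || is.null(doc$peaks) || is.null(doc$tolerance_cm1))
    .stop_input("peak library JSON must have fields analyte, peaks, tolerance_cm1")
  peak_library(doc$analyte, doc$peaks, doc$tolerance_cm1)
}

#' @rdname read_peak_library
#' @param lib a [peak_library()].
#' @export
write_peak_library <- function(lib, path) {
  if (!inherits(lib, "peak_library")) .stop_input("lib must be a peak_library")
  jsonlite::write_json(list(analyte = lib$analyte, peaks = lib$peaks,
                            tolerance_cm1 = lib$tolerance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# greedy nearest-first assignment of detected peaks to library peaks
.match_peaks <- function(lib_peaks, detected, tolerance) {
  matched_pos <- rep(NA_real_, length(lib_peaks))
  matched_int <- rep(NA_real_, length(lib_peaks))
  if (nrow(detected) > 0L) {
    pairs <- expand.grid(li = seq_along(lib_peaks), di = seq_len(nrow(detected)))
    pairs$dist <- abs(lib_peaks[pairs$li] - detected$position[pairs$di])
    pairs <- pairs[pairs$dist <= tolerance, , drop = FALSE]
    pairs <- pairs[order(pairs$dist), , drop = FALSE]
    used_d <- logical(nrow(detected))
    for (r in seq_len(nrow(pairs))) {
      li <- pairs$li[r]; di <- pairs$di[r]
      if (is.na(matched_pos[li]) && !used_d[di]) {
        matched_pos[li] <- detected$position[di]
        matched_int[li] <- detected$apex_intensity[di]
        used_d[di] <- TRUE
      }
    }
  }
  data.frame(library_peak = lib_peaks, matched_position = matched_pos,
             apex_intensity = matched_int)
}

#' Qualitative analyte call by characteristic-peak matching
#'
#' Detects peaks in the sample spectrum and matches them to the library by
#' greedy nearest-neighbour assignment within the library tolerance (each
#' detected peak is used at most once). The sample is called positive if and
#' only if every library peak is matched. Matched apex intensities are
#' recorded for the downstream semi-quantitative decision.
#'
#' @param s a [raman_spectrum()].
#' @param lib a [peak_library()].
#' @param ... peak-detection parameters passed to [detect_peaks()].
#' @return object of class `"qualitative_result"`: list with `positive`
#'   (logical) and `matches` (data frame `library_peak, matched_position,
#'   apex_intensity`, `NA` where unmatched).
#' @export
qualitative_call <- function(s, lib, ...) {
  if (!inherits(lib, "peak_library")) .stop_input("lib must be a peak_library")
  detected <- detect_peaks(s, ...)
  matches <- .match_peaks(lib$peaks, detected, lib$tolerance)
  structure(list(positive = !anyNA(matches$matched_position),
                 matches = matches, analyte = lib$analyte,
                 sample_id = s$sample_id),
            class = "qualitative_result")
}

#' @export
print.qualitative_result <- function(x, ...) {
  cat(sprintf("Qualitative call for %s%s: %s (%d/%d characteristic peaks matched)\n",
              x$analyte,
              if (is.null(x$sample_id)) "" else paste0(" in '", x$sample_id, "'"),
              if (x$positive) "POSITIVE" else "negative",
              sum(!is.na(x$matches$matched_position)), nrow(x$matches)))
  invisible(x)
}

#' Apex intensity at a given characteristic peak
#'
#' Convenience extractor: detects peaks and returns the raw apex intensity
#' of the nearest detected peak within `tolerance` of `position`, or `NA`
#' if none is found.
#'
#' @param s a [raman_spectrum()].
#' @param position target shift, cm-1.
#' @param tolerance matching tolerance, cm-1.
#' @param ... passed to [detect_peaks()].
#' @export
peak_intensity <- function(s, position, tolerance = 5, ...) {
  detected <- detect_peaks(s, ...)
  if (nrow(detected) == 0L) return(NA_real_)
  d <- abs(detected$position - position)
  i <- which.min(d)
  if (d[i] > tolerance) return(NA_real_)
  detected$apex_intensity[i]
}
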