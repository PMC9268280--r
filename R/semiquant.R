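# Threshold-based semi-quantitative screening: Gaussian fit of
# characteristic-peak intensities at the decision concentration (typically
# the MRL), a one-sided lower confidence bound as the intensity threshold,
# candidate scoring and selection, and the exceeds/below call.

#' Fit a Gaussian intensity model for one characteristic peak
#'
#' SERS peak intensities at a fixed spiked concentration scatter between
#' replicates; when that scatter is Gaussian, an intensity threshold can be
#' placed at the one-sided lower confidence bound of the fitted
#' distribution, `threshold = mean - z * sd` (default `z = qnorm(0.95)`),
#' so that a sample truly at the training concentration exceeds the
#' threshold with probability about `confidence`. Normality is checked with
#' the Shapiro-Wilk test at alpha = 0.05; a failing model is flagged
#' unusable and must not be selected.
#'
#' The training set should exceed 50 replicates; smaller sets are accepted
#' with a warning so that reduced-scale studies can run.
#'
#' @param intensities numeric apex intensities (counts) of the peak across
#'   training replicates, `n >= 3`.
#' @param peak_position the peak's Raman shift, cm-1.
#' @param confidence one-sided confidence of the threshold, default 0.95.
#' @param z explicit one-sided z multiplier; default `qnorm(confidence)`
#'   (1.645 at 95%).
#' @param mean_ci fit the threshold to the lower confidence bound of the
#'   *mean* (`mean - z * sd / sqrt(n)`) instead of the population bound.
#'   Default `FALSE`: the decision is about individual samples, not the
#'   mean.
#' @return object of class `"intensity_model"`: list with `peak_position`,
#'   `mean`, `sd`, `n`, `z`, `confidence`, `threshold`, `normality` (list
#'   `stat`, `p`, `pass`) and `usable`.
#' @examples
#' set.seed(1)
#' fit_intensity_model(rnorm(60, 14000, 1200), 630)
#' @export
fit_intensity_model <- function(intensities, peak_position, confidence = 0.95,
                                z = NULL, mean_ci = FALSE) {
  intensities <- as.numeric(intensities)
  intensities <- intensities[!is.na(intensities)]
  n <- length(intensities)
  if (n < 3L) .stop_input("at least 3 training intensities are required")
  if (n <= 50L)
    warning("training set has ", n, " samples; > 50 recommended for a ",
            "stable threshold", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) .stop_input("confidence must be in (0, 1)")
  if (is.null(z)) z <- stats::qnorm(confidence)
  m <- mean(intensities)
  s <- stats::sd(intensities)
  if (s == 0) {
    normality <- list(stat = NA_real_, p = NA_real_, pass = NA)
    warning("zero variance in training intensities; normality not assessable",
            call. = FALSE)
  } else {
    sw <- stats::shapiro.test(intensities)
    normality <- list(stat = unname(sw$statistic), p = sw$p.value,
                      pass = sw$p.value >= 0.05)
  }
  threshold <- if (mean_ci) m - z * s / sqrt(n) else m - z * s
  structure(list(peak_position = peak_position, mean = m, sd = s, n = n,
                 z = z, confidence = confidence, threshold = threshold,
                 mean_ci = mean_ci, normality = normality,
                 usable = !isFALSE(normality$pass), data = intensities),
            class = "intensity_model")
}

#' @export
print.intensity_model <- function(x, digits = 4, ...) {
  cat(sprintf("Intensity model at %g cm-1 (n = %d)\n", x$peak_position, x$n))
  cat(sprintf("  mean %s, sd %s, threshold %s (z = %.3f, %s bound)\n",
              signif(x$mean, digits), signif(x$sd, digits),
              signif(x$threshold, digits), x$z,
              if (x$mean_ci) "mean-CI" else "population"))
  if (is.na(x$normality$pass)) {
    cat("  normality: not assessable (zero variance)\n")
  } else {
    cat(sprintf("  Shapiro-Wilk W = %.4f, p = %.3g: %s\n",
                x$normality$stat, x$normality$p,
                if (x$normality$pass) "Gaussian fit accepted"
                else "Gaussian fit REJECTED - model unusable"))
  }
  invisible(x)
}

#' @export
#' @rdname fit_intensity_model
#' @param object an `intensity_model`.
#' @param newdata numeric intensities to classify.
#' @param ... unused.
predict.intensity_model <- function(object, newdata, ...) {
  newdata > object$threshold
}

#' Histogram of training intensities with the fitted Gaussian overlay
#'
#' The visual audit of the normality verdict: raw histogram, fitted density
#' and the semi-quantitative threshold.
#'
#' @param x an [fit_intensity_model()] fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.intensity_model <- function(x, ...) {
  if (is.null(x$data))
    .stop_input("this model carries no training data (loaded from JSON?)")
  graphics::hist(x$data, freq = FALSE, xlab = "Apex intensity (counts)",
                 main = sprintf("Intensity distribution at %g cm-1", x$peak_position),
                 ...)
  if (x$sd > 0) graphics::curve(stats::dnorm(t, x$mean, x$sd), xname = "t",
                                add = TRUE, col = "steelblue4", lwd = 2)
  graphics::abline(v = x$threshold, lty = 2, col = "firebrick")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a semi-quantitative candidate model
#'
#' A candidate threshold is scored from the detection probabilities of the
#' exceeds-threshold call on three test sets: `pod1` at low concentration,
#' `pod2` at half the decision concentration, `pod3` at the decision
#' concentration itself:
#' \deqn{S = 2 (POD_3 - POD_2 - POD_1) \times 50.}
#' A perfect threshold (0, 0, 1) scores 100; higher scores mean fewer false
#' exceedances below the decision concentration and higher sensitivity at
#' it.
#'
#' @param pod1,pod2,pod3 proportions in `[0, 1]`.
#' @return object of class `"model_score"`: list `pod1, pod2, pod3, score`.
#' @examples
#' score_model(0, 0, 1)      # 100
#' score_model(0, 0.05, 1)   # 95
#' @export
score_model <- function(pod1, pod2, pod3) {
  p <- c(pod1, pod2, pod3)
  if (length(p) != 3L || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    .stop_input("pod1, pod2, pod3 must be proportions in [0, 1]")
  structure(list(pod1 = pod1, pod2 = pod2, pod3 = pod3,
                 score = 2 * (pod3 - pod2 - pod1) * 50),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("POD (low / half / decision) = %.3f / %.3f / %.3f -> score %g\n",
              x$pod1, x$pod2, x$pod3, x$score))
  invisible(x)
}

.as_intensities <- function(set, model, tolerance, ...) {
  if (is.numeric(set)) return(as.numeric(set))
  if (is.list(set) && all(vapply(set, inherits, logical(1), "raman_spectrum")))
    return(vapply(set, peak_intensity, numeric(1),
                  position = model$peak_position, tolerance = tolerance, ...))
  .stop_input("test sets must be numeric intensities or lists of raman_spectrum")
}

#' Evaluate a candidate intensity model on three test sets
#'
#' Computes the fraction of each test set whose peak intensity exceeds the
#' model threshold (an undetected peak counts as not exceeding) and scores
#' the candidate with [score_model()]. Test sets should exceed 20 members
#' each; smaller sets warn.
#'
#' @param model an [fit_intensity_model()] fit.
#' @param low,half,full test sets at low concentration, half the decision
#'   concentration and the decision concentration: numeric intensity
#'   vectors, or lists of [raman_spectrum()] from which the model peak's
#'   apex intensity is extracted.
#' @param tolerance shift tolerance (cm-1) for intensity extraction from
#'   spectra.
#' @param ... peak-detection parameters for the extraction.
#' @return a [score_model()] object.
#' @export
evaluate_candidate <- function(model, low, half, full, tolerance = 5, ...) {
  if (!inherits(model, "intensity_model")) .stop_input("model must be an intensity_model")
  sets <- list(low = low, half = half, full = full)
  pods <- vapply(sets, function(set) {
    ints <- .as_intensities(set, model, tolerance, ...)
    if (length(ints) == 0L) .stop_input("empty test set")
    if (length(ints) <= 20L)
      warning("test set has ", length(ints), " samples; > 20 recommended",
              call. = FALSE)
    # undetected peaks (NA intensity) are below any threshold
    mean(!is.na(ints) & ints > model$threshold)
  }, numeric(1))
  score_model(pods[["low"]], pods[["half"]], pods[["full"]])
}

#' Select the optimal semi-quantitative model
#'
#' Filters candidates to those whose training intensities passed the
#' normality check, then picks the highest score; ties are broken by lower
#' `pod2`, then lower `pod1`, then lower peak position.
#'
#' @param candidates a list whose elements are lists with components
#'   `model` (an `intensity_model`) and `score` (a `model_score`).
#' @return the winning `intensity_model`, with the winning `model_score`
#'   attached as attribute `"score"`.
#' @export
select_model <- function(candidates) {
  if (length(candidates) < 1L) .stop_input("at least one candidate is required")
  ok <- vapply(candidates, function(cd) isTRUE(cd$model$normality$pass), logical(1))
  if (!any(ok))
    .stop_method("no candidate model passes the Gaussian normality check")
  pool <- candidates[ok]
  key <- vapply(pool, function(cd)
    c(-cd$score$score, cd$score$pod2, cd$score$pod1, cd$model$peak_position),
    numeric(4))
  best <- do.call(order, as.data.frame(t(key)))[1L]
  model <- pool[[best]]$model
  attr(model, "score") <- pool[[best]]$score
  model
}

#' Semi-quantitative screening call for one spectrum
#'
#' Runs the qualitative characteristic-peak call first; if negative, the
#' exceeds-MRL question is indeterminate (`NA`). If positive, the sample is
#' declared at-or-above the decision concentration exactly when the matched
#' apex intensity at the model's peak strictly exceeds the model threshold.
#'
#' @param s a [raman_spectrum()].
#' @param lib a [peak_library()]; must contain the model's peak.
#' @param model an [fit_intensity_model()] fit.
#' @param ... peak-detection parameters passed to [qualitative_call()].
#' @return object of class `"semiquant_result"`: list with
#'   `qualitative` (the [qualitative_call()] result), `exceeds` (logical or
#'   `NA`), `peak_intensity` and `threshold`.
#' @export
semiquant_call <- function(s, lib, model, ...) {
  if (!inherits(model, "intensity_model")) .stop_input("model must be an intensity_model")
  if (!inherits(lib, "peak_library")) .stop_input("lib must be a peak_library")
  d <- abs(lib$peaks - model$peak_position)
  if (min(d) > lib$tolerance)
    .stop_input("the model's peak is not a library characteristic peak")
  lib_peak <- lib$peaks[which.min(d)]
  qual <- qualitative_call(s, lib, ...)
  if (!qual$positive) {
    res <- list(qualitative = qual, exceeds = NA,
                peak_intensity = NA_real_, threshold = model$threshold,
                peak_position = model$peak_position)
  } else {
    pi <- qual$matches$apex_intensity[qual$matches$library_peak == lib_peak]
    res <- list(qualitative = qual, exceeds = pi > model$threshold,
                peak_intensity = pi, threshold = model$threshold,
                peak_position = model$peak_position)
  }
  structure(res, class = "semiquant_result")
}

#' @export
print.semiquant_result <- function(x, ...) {
  if (!x$qualitative$positive) {
    cat("Qualitative call negative: exceeds-MRL question indeterminate\n")
  } else {
    cat(sprintf("Positive; intensity %.5g at %g cm-1 vs threshold %.5g: %s\n",
                x$peak_intensity, x$peak_position, x$threshold,
                if (x$exceeds) "AT OR ABOVE the decision concentration"
                else "below the decision concentration"))
  }
  invisible(x)
}

#' Read and write a trained intensity model as JSON
#'
#' Format: `{analyte, peak_cm1, mean, sd, n, z, threshold,
#' normality: {stat, p, pass}, confidence}`.
#'
#' @param path file path.
#' @export
read_intensity_model <- function(path) {
  if (!file.exists(path)) .stop_input(paste0("no such file: ", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("peak_cm1", "mean", "sd", "n", "z", "threshold", "confidence")
  if (!all(need %in% names(doc)))
    .stop_input("intensity model JSON is missing required fields")
  structure(list(peak_position = doc$peak_cm1, mean = doc$mean, sd = doc$sd,
                 n = as.integer(doc$n), z = doc$z, confidence = doc$confidence,
                 threshold = doc$threshold,
                 mean_ci = isTRUE(doc$mean_ci),
                 normality = list(stat = doc$normality$stat,
                                  p = doc$normality$p,
                                  pass = doc$normality$pass),
                 usable = !isFALSE(doc$normality$pass),
                 analyte = doc$analyte),
            class = "intensity_model")
}

#' @rdname read_intensity_model
#' @param model an `intensity_model`.
#' @param analyte analyte name recorded in the file.
#' @export
write_intensity_model <- function(model, path, analyte = NULL) {
  if (!inherits(model, "intensity_model")) .stop_input("model must be an intensity_model")
  jsonlite::write_json(
    list(analyte = analyte %||% model$analyte %||% "analyte",
         peak_cm1 = model$peak_position, mean = model$mean, sd = model$sd,
         n = model$n, z = model$z, threshold = model$threshold,
         mean_ci = model$mean_ci %||% FALSE,
         normality = model$normality, confidence = model$confidence),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
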