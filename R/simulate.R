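# Synthetic SERS data: spectra with Gaussian-distributed, concentration-
# dependent peak amplitudes on a Lorentzian line shape, and binomial
# detection-count tables driven by a logistic POD function. All randomness
# goes through R's RNG, so set.seed() gives bit-identical reruns.

#' Specify a simulated SERS peak
#'
#' @param position peak centre, cm-1.
#' @param base_mean mean apex amplitude (counts) at the reference
#'   concentration.
#' @param width half-width of the Lorentzian line shape, cm-1.
#' @param rel_sd between-replicate relative standard deviation of the
#'   amplitude (SD / mean).
#' @return one-row data frame.
#' @export
sim_peak <- function(position, base_mean, width = 6, rel_sd = 0.1) {
  if (width <= 0) .stop_input("width must be > 0")
  if (rel_sd < 0) .stop_input("rel_sd must be >= 0")
  if (base_mean < 0) .stop_input("base_mean must be >= 0")
  data.frame(position = position, base_mean = base_mean,
             width = width, rel_sd = rel_sd)
}

#' Default carbendazim-like peak set
#'
#' Six peaks at the characteristic shifts of carbendazim in apple, with
#' amplitudes chosen so the dominant 630 cm-1 peak trains a threshold near
#' 1.4e4 counts at the 5 mg/kg reference concentration.
#'
#' @param rel_sd relative amplitude SD applied to every peak, default 0.1.
#' @export
cbz_sim_peaks <- function(rel_sd = 0.1) {
  rbind(sim_peak(630, 16000, 6, rel_sd),
        sim_peak(728,  8500, 6, rel_sd),
        sim_peak(1000, 11000, 6, rel_sd),
        sim_peak(1218,  6500, 6, rel_sd),
        sim_peak(1260,  5200, 6, rel_sd),
        sim_peak(1315,  7400, 6, rel_sd))
}

#' Configuration of the spectrum simulator
#'
#' @param shift_range acquisition window, cm-1 (default 200-2000, covering
#'   all carbendazim characteristic peaks).
#' @param step grid step, cm-1.
#' @param peaks data frame of [sim_peak()] rows.
#' @param reference_concentration concentration (mg/kg) at which peak
#'   amplitudes equal `base_mean`; default 5 (the carbendazim MRL in apple).
#' @param response_exponent exponent of the amplitude-concentration
#'   response, `mean = base_mean * (c / c_ref)^exponent`; 1 is linear,
#'   values below 1 emulate the sublinear response typical of SERS.
#' @param baseline polynomial coefficients of the baseline, evaluated in
#'   the normalised coordinate `u = (shift - min) / (max - min)` in
#'   `[0, 1]` (constant term first).
#' @param noise_sd additive Gaussian noise SD, counts.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(shift_range = c(200, 2000), step = 1,
                       peaks = cbz_sim_peaks(), reference_concentration = 5,
                       response_exponent = 1, baseline = c(200, -100, 40),
                       noise_sd = 30) {
  if (step <= 0) .stop_input("step must be > 0")
  if (reference_concentration <= 0) .stop_input("reference_concentration must be > 0")
  if (noise_sd < 0) .stop_input("noise_sd must be >= 0")
  if (diff(shift_range) <= 0) .stop_input("shift_range must be increasing")
  structure(list(shift_range = shift_range, step = step, peaks = peaks,
                 reference_concentration = reference_concentration,
                 response_exponent = response_exponent,
                 baseline = baseline, noise_sd = noise_sd),
            class = "sim_config")
}

.baseline_at <- function(shift, coefs) {
  u <- (shift - min(shift)) / (max(shift) - min(shift))
  drop(outer(u, seq_along(coefs) - 1, `^`) %*% coefs)
}

#' Simulate one SERS spectrum
#'
#' Each peak's apex amplitude is drawn from a Gaussian with mean
#' `base_mean * (c / c_ref)^exponent` and SD `rel_sd` times that mean,
#' truncated at zero (counts cannot be negative; at `rel_sd < 0.3` the
#' truncation is a negligible departure from exact normality). The
#' amplitude multiplies a Lorentzian line shape
#' `1 / (1 + ((shift - position) / width)^2)`, peaks are summed over the
#' polynomial baseline, additive Gaussian noise is applied and the result
#' clamped at zero.
#'
#' @param concentration spiked concentration, mg/kg, `>= 0`.
#' @param cfg a [sim_config()].
#' @param sample_id optional sample identifier stored in the spectrum.
#' @return a [raman_spectrum()] with the concentration recorded in its
#'   metadata.
#' @examples
#' set.seed(7)
#' s <- simulate_spectrum(5, sim_config())
#' @export
simulate_spectrum <- function(concentration, cfg = sim_config(),
                              sample_id = NULL) {
  if (!inherits(cfg, "sim_config")) .stop_input("cfg must be a sim_config")
  if (concentration < 0) .stop_input("concentration must be >= 0")
  shift <- seq(cfg$shift_range[1], cfg$shift_range[2], by = cfg$step)
  y <- if (all(cfg$baseline == 0)) numeric(length(shift))
       else .baseline_at(shift, cfg$baseline)
  scale <- (concentration / cfg$reference_concentration)^cfg$response_exponent
  for (i in seq_len(nrow(cfg$peaks))) {
    p <- cfg$peaks[i, ]
    mu <- p$base_mean * scale
    amp <- max(0, stats::rnorm(1, mu, p$rel_sd * mu))
    y <- y + amp / (1 + ((shift - p$position) / p$width)^2)
  }
  if (cfg$noise_sd > 0) y <- y + stats::rnorm(length(shift), 0, cfg$noise_sd)
  raman_spectrum(shift, pmax(y, 0), sample_id = sample_id,
                 concentration = concentration)
}

#' Simulate binomial detection counts along a logistic POD function
#'
#' The generating POD is `plogis(slope * (log(c) - log(c50)))` for `c > 0`
#' and exactly 0 at `c = 0` (a blank cannot be detected); `x` at each
#' concentration is a binomial draw.
#'
#' @param concentrations spiked concentrations, mg/kg.
#' @param N replicates per concentration.
#' @param c50 concentration of 50% detection, mg/kg.
#' @param slope logistic steepness on the log-concentration scale, `> 0`.
#' @return data frame `concentration, x, N` suitable for [pod_curve()],
#'   with the generating probability attached as attribute `"pod_true"`.
#' @export
simulate_counts <- function(concentrations, N, c50, slope) {
  if (N < 1) .stop_input("N must be >= 1")
  if (slope <= 0) .stop_input("slope must be > 0")
  if (c50 <= 0) .stop_input("c50 must be > 0")
  p <- ifelse(concentrations == 0, 0,
              stats::plogis(slope * (log(concentrations) - log(c50))))
  out <- data.frame(concentration = concentrations,
                    x = stats::rbinom(length(p), N, p),
                    N = as.integer(N))
  attr(out, "pod_true") <- p
  out
}

#' Generate a complete synthetic spiking study on disk
#'
#' Emulates a spiked-sample validation design: `n` spectra at each of the
#' given concentrations, plus `n_train` training spectra at the reference
#' concentration, written as spectrum CSV files with a manifest CSV
#' (`path,concentration_mg_per_kg,role`) consumable by
#' [cmd_train_semiquant()]. Roles are assigned relative to the
#' configuration's reference concentration: `blank` (0), `test_low`
#' (below half the reference), `test_half` (half), `test_full`
#' (reference), `train` for the training spectra.
#'
#' Reproducible: the same seed gives byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param concentrations spiked levels, mg/kg; default the seven-level
#'   design `{0, 0.05, 0.1, 0.5, 1, 2.5, 5}`.
#' @param n spectra per level.
#' @param cfg a [sim_config()].
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @param n_train additional training spectra at the reference
#'   concentration, default 0.
#' @return the manifest data frame, invisibly; also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_study <- function(dir, concentrations = c(0, 0.05, 0.1, 0.5, 1, 2.5, 5),
                           n = 5, cfg = sim_config(), seed = NULL, n_train = 0) {
  if (n < 1) .stop_input("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cref <- cfg$reference_concentration
  role_of <- function(conc) {
    if (conc == 0) "blank"
    else if (isTRUE(all.equal(conc, cref))) "test_full"
    else if (isTRUE(all.equal(conc, cref / 2))) "test_half"
    else "test_low"
  }
  rows <- list()
  emit <- function(conc, idx, role) {
    id <- sprintf("%s_c%s_%03d", role, gsub("[.]", "p", format(conc)), idx)
    fname <- paste0(id, ".csv")
    s <- simulate_spectrum(conc, cfg, sample_id = id)
    write_spectrum(s, file.path(dir, fname))
    data.frame(path = fname, concentration_mg_per_kg = conc, role = role)
  }
  for (i in seq_len(n_train))
    rows[[length(rows) + 1L]] <- emit(cref, i, "train")
  for (conc in concentrations)
    for (i in seq_len(n))
      rows[[length(rows) + 1L]] <- emit(conc, i, role_of(conc))
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
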