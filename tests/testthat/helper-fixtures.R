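# Shared fixtures: published validation count tables shipped with the
# package, an independently coded Wilson-interval oracle, and noise-free
# synthetic spectra with peaks at known positions.

fixture_path <- function(name) {
  system.file("extdata", name, package = "podscreen", mustWork = TRUE)
}

load_counts <- function(name) read_count_table(fixture_path(name))

# Wilson score interval in proportion (p-hat) form — an algebraically
# different arrangement from the package's count-based formulas, using the
# same fixed constants (z = 1.9600, z^2 = 3.8415, z^2/2 = 1.9207,
# z^2/4 = 0.9604).
wilson_oracle <- function(x, N) {
  p <- x / N
  denom <- 1 + 3.8415 / N
  centre <- p + 1.9207 / N
  half <- 1.9600 * sqrt(p * (1 - p) / N + 0.9604 / N^2)
  c(lcl = (centre - half) / denom, ucl = (centre + half) / denom)
}

# noise-free spectrum on a 1 cm-1 grid with Lorentzian peaks injected at
# given positions/heights; flat zero baseline
flat_spectrum_with_peaks <- function(positions, heights, width = 6,
                                     from = 200, to = 2000) {
  shift <- seq(from, to, by = 1)
  y <- numeric(length(shift))
  for (i in seq_along(positions))
    y <- y + heights[i] / (1 + ((shift - positions[i]) / width)^2)
  raman_spectrum(shift, y)
}

expect_printed_cell <- function(value, printed) {
  value <- unname(value)
  printed <- unname(printed)
  # published tables mix 3-decimal and 2-decimal-padded rounding
  ok <- isTRUE(all.equal(round(value, 3), printed, tolerance = 1e-9)) ||
        isTRUE(all.equal(round(value, 2), round(printed, 2), tolerance = 1e-9))
  expect_true(ok, label = sprintf("computed %.6f reproduces printed %.3f",
                                  value, printed))
}
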