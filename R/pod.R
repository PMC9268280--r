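# Probability-of-detection (POD) estimation for binary-output screening
# assays, with the score-type 95% confidence limits used in rapid-method
# validation. Constants are fixed at the 95% level (z = 1.9600, z^2 = 3.8415,
# z^2/2 = 1.9207, z^2/4 = 0.9604) so that reported limits are bit-compatible
# with published validation tables; there is deliberately no generic-z mode.

.Z      <- 1.9600
.ZSQ    <- 3.8415
.HALFZ  <- 1.9207
.QUARTZ <- 0.9604

.stop_input <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("podscreen_input_error", "error", "condition")))
}

.stop_method <- function(msg) {
  stop(errorCondition(msg, class = c("podscreen_method_error", "error", "condition")))
}

# vectorised CI engine; x and N recycled to common length
.pod_ci <- function(x, N) {
  pod <- x / N
  root <- sqrt(pmax(x - x^2 / N + .QUARTZ, 0))
  lcl <- (x + .HALFZ - .Z * root) / (N + .ZSQ)
  ucl <- (x + .HALFZ + .Z * root) / (N + .ZSQ)
  # boundary branches replace the interior formula entirely
  zero <- x == 0
  full <- x == N
  lcl[zero] <- 0
  ucl[zero] <- .ZSQ / (N[zero] + .ZSQ)
  pod[zero] <- 0
  lcl[full] <- N[full] / (N[full] + .ZSQ)
  ucl[full] <- 1
  pod[full] <- 1
  cbind(pod = pod, lcl = lcl, ucl = ucl)
}

.check_counts <- function(x, N) {
  if (length(x) != length(N)) .stop_input("x and N must have the same length")
  if (any(!is.finite(x)) || any(!is.finite(N))) .stop_input("x and N must be finite")
  if (any(x != round(x)) || any(N != round(N))) .stop_input("x and N must be whole numbers")
  if (any(N < 1)) .stop_input("N must be >= 1")
  if (any(x < 0) || any(x > N)) .stop_input("x must satisfy 0 <= x <= N")
}

#' Probability of detection with 95% confidence limits
#'
#' Estimates the probability of detection (POD) of a binary screening assay
#' from `x` positive calls out of `N` replicates, with the score-type 95%
#' confidence interval conventional in rapid-method validation. The interior
#' case (`0 < x < N`) uses
#' \deqn{LCL, UCL = \frac{x + 1.9207 \mp 1.9600\sqrt{x - x^2/N + 0.9604}}{N + 3.8415},}
#' which is the Wilson score interval written in counts at z = 1.96. The
#' boundary cases collapse to `LCL = 0, UCL = 3.8415/(N + 3.8415)` when
#' `x = 0` and `LCL = N/(N + 3.8415), UCL = 1` when `x = N`.
#'
#' Values are returned unrounded; display rounding is left to callers (see
#' [write_pod_report()] for the fixed-point report format).
#'
#' @param x integer count of positive results, `0 <= x <= N`.
#' @param N integer number of replicates tested, `N >= 1`.
#' @return An object of class `"pod_estimate"`: a list with components
#'   `pod`, `lcl`, `ucl`, `x`, `N`.
#' @examples
#' pod_estimate(40, 50)  # POD 0.80, CI (0.670, 0.888)
#' pod_estimate(0, 10)   # POD 0, upper limit 0.278
#' @seealso [pod_curve()], [dpod_estimate()]
#' @export
pod_estimate <- function(x, N) {
  if (length(x) != 1L || length(N) != 1L) .stop_input("x and N must be scalars")
  .check_counts(x, N)
  ci <- .pod_ci(x, N)
  structure(
    list(pod = unname(ci[1, "pod"]), lcl = unname(ci[1, "lcl"]),
         ucl = unname(ci[1, "ucl"]), x = as.integer(x), N = as.integer(N)),
    class = "pod_estimate"
  )
}

#' @export
print.pod_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("POD %s/%d = %.*f, 95%% CI [%.*f, %.*f]\n",
              x$x, x$N, digits, x$pod, digits, x$lcl, digits, x$ucl))
  invisible(x)
}

#' Difference of two probabilities of detection (dPOD)
#'
#' Computes the signed POD difference between a candidate method (or
#' laboratory) `a` and a reference `b`, with 95% confidence limits obtained
#' by combining the component interval half-widths in quadrature:
#' \deqn{LCL = dPOD - \sqrt{(POD_I - LCL_I)^2 + (POD_{II} - UCL_{II})^2}}
#' \deqn{UCL = dPOD + \sqrt{(POD_I - UCL_I)^2 + (POD_{II} - LCL_{II})^2}}
#'
#' The point estimate is signed (`a` minus `b`); published consistency tables
#' conventionally report its absolute value, available as `abs_dpod`.
#'
#' @param a,b objects of class `"pod_estimate"`; `a` is the method under
#'   evaluation, `b` the reference.
#' @return An object of class `"dpod_estimate"`: list with `dpod`, `lcl`,
#'   `ucl`, `abs_dpod`, and the two component estimates `a` and `b`.
#' @examples
#' dpod_estimate(pod_estimate(40, 50), pod_estimate(50, 50))
#' @export
dpod_estimate <- function(a, b) {
  if (!inherits(a, "pod_estimate") || !inherits(b, "pod_estimate"))
    .stop_input("a and b must be pod_estimate objects")
  d <- a$pod - b$pod
  lcl <- d - sqrt((a$pod - a$lcl)^2 + (b$pod - b$ucl)^2)
  ucl <- d + sqrt((a$pod - a$ucl)^2 + (b$pod - b$lcl)^2)
  structure(
    list(dpod = d, lcl = lcl, ucl = ucl, abs_dpod = abs(d), a = a, b = b),
    class = "dpod_estimate"
  )
}

#' @export
print.dpod_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("dPOD = %.*f (|dPOD| = %.*f), 95%% CI [%.*f, %.*f]\n",
              digits, x$dpod, digits, x$abs_dpod,
              digits, x$lcl, digits, x$ucl))
  invisible(x)
}

#' Fit a POD curve from a detection count table
#'
#' The central model object of the validation workflow: one POD estimate per
#' spiked concentration, ordered by concentration. The limit of detection,
#' per-concentration performance rates and between-method consistency are all
#' read from this object ([lod()], [method_metrics()],
#' [consistency_evaluation()]).
#'
#' @param counts a data frame with numeric columns `concentration` (mg/kg,
#'   `>= 0`, unique values), `x` (positive calls) and `N` (replicates), such
#'   as returned by [read_count_table()] or [simulate_counts()].
#' @return An object of class `"pod_curve"`: a list with component `points`,
#'   a data frame with columns `concentration, x, N, pod, lcl, ucl` sorted by
#'   concentration, and the matched `call`.
#' @examples
#' counts <- data.frame(concentration = c(0, 0.5, 5), x = c(0, 30, 40),
#'                      N = c(10, 40, 40))
#' fit <- pod_curve(counts)
#' fit
#' coef(fit)
#' @export
pod_curve <- function(counts) {
  if (!is.data.frame(counts) || !all(c("concentration", "x", "N") %in% names(counts)))
    .stop_input("counts must be a data frame with columns concentration, x, N")
  if (nrow(counts) < 1L) .stop_input("counts must have at least one row")
  conc <- counts$concentration
  if (any(!is.finite(conc)) || any(conc < 0))
    .stop_input("concentrations must be finite and >= 0")
  if (anyDuplicated(conc)) .stop_input("concentrations must be unique")
  .check_counts(counts$x, counts$N)
  ord <- order(conc)
  ci <- .pod_ci(counts$x[ord], counts$N[ord])
  points <- data.frame(
    concentration = conc[ord],
    x = as.integer(counts$x[ord]),
    N = as.integer(counts$N[ord]),
    pod = ci[, "pod"], lcl = ci[, "lcl"], ucl = ci[, "ucl"],
    row.names = NULL
  )
  structure(list(points = points, call = match.call()), class = "pod_curve")
}

#' @export
print.pod_curve <- function(x, digits = 3, ...) {
  cat("POD curve (", nrow(x$points), " concentrations)\n", sep = "")
  print(cbind(x$points[1:3],
              round(x$points[c("pod", "lcl", "ucl")], digits)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.pod_curve <- function(object, ...) {
  stats::setNames(object$points$pod, format(object$points$concentration))
}

#' @export
as.data.frame.pod_curve <- function(x, ...) x$points

#' @export
summary.pod_curve <- function(object, threshold = 0.95, ...) {
  out <- list(points = object$points,
              metrics = method_metrics(object),
              lod = suppressWarnings(lod(object, threshold)),
              threshold = threshold)
  class(out) <- "summary.pod_curve"
  out
}

#' @export
print.summary.pod_curve <- function(x, digits = 3, ...) {
  cat("POD curve with performance rates\n\n")
  tab <- merge(x$points, x$metrics, by = "concentration")
  num <- vapply(tab, is.numeric, logical(1)) & !(names(tab) %in% c("concentration", "x", "N"))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  if (is.na(x$lod)) {
    cat(sprintf("\nNo tested concentration reaches POD > %.2f; LOD not established.\n",
                x$threshold))
  } else {
    cat(sprintf("\nLOD (smallest concentration with POD > %.2f): %g mg/kg\n",
                x$threshold, x$lod))
  }
  invisible(x)
}

#' Limit of detection from a POD curve
#'
#' The LOD of a qualitative screening method is the smallest tested non-zero
#' concentration whose POD exceeds `threshold` (default 0.95, the sensitivity
#' requirement of rapid-screening validation guidelines).
#'
#' If some higher tested concentration falls back below the threshold the
#' smallest qualifying concentration is still returned, with a warning: the
#' POD model assumes detection probability is monotone in concentration.
#'
#' @param object a [pod_curve()] fit.
#' @param threshold POD that must be exceeded (strictly), default 0.95.
#' @param ... unused.
#' @return the LOD in mg/kg, or `NA_real_` if no concentration qualifies.
#' @export
lod <- function(object, threshold = 0.95, ...) UseMethod("lod")

#' @rdname lod
#' @export
lod.pod_curve <- function(object, threshold = 0.95, ...) {
  pts <- object$points
  keep <- pts$concentration > 0 & pts$pod > threshold
  if (!any(keep)) return(NA_real_)
  i <- which(keep)[1L]
  above <- pts$concentration > pts$concentration[i]
  if (any(above & pts$pod <= threshold))
    warning("POD falls back below the threshold above the reported LOD; ",
            "the curve is not monotone", call. = FALSE)
  pts$concentration[i]
}

#' Sensitivity, specificity and false call rates along a POD curve
#'
#' At concentration zero the POD is the false positive rate and its
#' complement the specificity; at non-zero concentrations the POD is the
#' sensitivity and its complement the false negative rate. Each rate is
#' reported only where it is defined (`NA` elsewhere).
#'
#' @param object a [pod_curve()] fit.
#' @return data frame with columns `concentration`, `sensitivity`,
#'   `specificity`, `false_positive_rate`, `false_negative_rate`.
#' @export
method_metrics <- function(object) {
  if (!inherits(object, "pod_curve")) .stop_input("object must be a pod_curve")
  pts <- object$points
  blank <- pts$concentration == 0
  data.frame(
    concentration = pts$concentration,
    sensitivity = ifelse(blank, NA_real_, pts$pod),
    specificity = ifelse(blank, 1 - pts$pod, NA_real_),
    false_positive_rate = ifelse(blank, pts$pod, NA_real_),
    false_negative_rate = ifelse(blank, NA_real_, 1 - pts$pod)
  )
}

#' Consistency of two POD curves via per-concentration dPOD
#'
#' Compares a method (or laboratory) against a reference on an identical
#' concentration grid. At each concentration the signed dPOD with its 95%
#' interval is computed; the curves are declared consistent from the smallest
#' concentration `consistent_from` such that every tested concentration at or
#' above it agrees. By default agreement means the point estimate satisfies
#' `|dPOD| <= tol` with `tol = 0`, the convention of published consistency
#' tables; set `use_ci = TRUE` to instead require the dPOD confidence
#' interval to cover zero.
#'
#' @param curve_a [pod_curve()] for the method/laboratory under evaluation.
#' @param curve_b [pod_curve()] for the reference.
#' @param tol tolerance on `|dPOD|` for point-estimate agreement, default 0.
#' @param use_ci declare agreement where the dPOD 95% CI covers zero.
#' @return An object of class `"pod_consistency"`: list with `table` (one row
#'   per concentration: both counts and PODs, `dpod`, `lcl`, `ucl`,
#'   `abs_dpod`, `consistent`), `consistent_from` (mg/kg, `NA` if the highest
#'   concentration disagrees), `tol` and `use_ci`.
#' @export
consistency_evaluation <- function(curve_a, curve_b, tol = 0, use_ci = FALSE) {
  if (!inherits(curve_a, "pod_curve") || !inherits(curve_b, "pod_curve"))
    .stop_input("curve_a and curve_b must be pod_curve objects")
  pa <- curve_a$points
  pb <- curve_b$points
  if (nrow(pa) != nrow(pb) || !isTRUE(all.equal(pa$concentration, pb$concentration)))
    .stop_input("the two curves must share an identical concentration grid")
  rows <- lapply(seq_len(nrow(pa)), function(i) {
    d <- dpod_estimate(pod_estimate(pa$x[i], pa$N[i]), pod_estimate(pb$x[i], pb$N[i]))
    data.frame(concentration = pa$concentration[i],
               x1 = pa$x[i], N1 = pa$N[i], pod1 = pa$pod[i],
               lcl1 = pa$lcl[i], ucl1 = pa$ucl[i],
               x2 = pb$x[i], N2 = pb$N[i], pod2 = pb$pod[i],
               lcl2 = pb$lcl[i], ucl2 = pb$ucl[i],
               dpod = d$dpod, lcl = d$lcl, ucl = d$ucl, abs_dpod = d$abs_dpod)
  })
  tab <- do.call(rbind, rows)
  tab$consistent <- if (use_ci) tab$lcl <= 0 & tab$ucl >= 0 else tab$abs_dpod <= tol
  # smallest concentration from which agreement holds through the top of the grid
  consistent_from <- NA_real_
  n <- nrow(tab)
  if (tab$consistent[n]) {
    i <- n
    while (i > 1L && tab$consistent[i - 1L]) i <- i - 1L
    consistent_from <- tab$concentration[i]
  }
  structure(list(table = tab, consistent_from = consistent_from,
                 tol = tol, use_ci = use_ci),
            class = "pod_consistency")
}

#' @export
print.pod_consistency <- function(x, digits = 3, ...) {
  cat("POD consistency evaluation (",
      if (x$use_ci) "CI covers zero" else sprintf("|dPOD| <= %g", x$tol),
      ")\n\n", sep = "")
  show <- x$table[c("concentration", "x1", "N1", "pod1", "x2", "N2", "pod2",
                    "abs_dpod", "consistent")]
  show[c("pod1", "pod2", "abs_dpod")] <-
    lapply(show[c("pod1", "pod2", "abs_dpod")], round, digits = digits)
  print(show, row.names = FALSE)
  if (is.na(x$consistent_from)) {
    cat("\nMethods disagree at the highest tested concentration.\n")
  } else {
    cat(sprintf("\nConsistent for all tested concentrations >= %g mg/kg\n",
                x$consistent_from))
  }
  invisible(x)
}

#' Plot a POD curve or a dPOD profile
#'
#' For a `pod_curve`, draws POD against concentration with the 95% confidence
#' band; for a `pod_consistency`, draws the signed dPOD with its interval.
#' Presentation only — no analysis result depends on these plots.
#'
#' @param x a `pod_curve` or `pod_consistency` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pod_curve <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$concentration, pts$pod, type = "n", ylim = c(0, 1),
                 xlab = "Spiked concentration (mg/kg)",
                 ylab = "Probability of detection", ...)
  graphics::polygon(c(pts$concentration, rev(pts$concentration)),
                    c(pts$lcl, rev(pts$ucl)),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  graphics::lines(pts$concentration, pts$pod, type = "b", pch = 16,
                  col = "steelblue4")
  graphics::abline(h = 0.95, lty = 2, col = "grey40")
  invisible(x)
}

#' @rdname plot.pod_curve
#' @export
plot.pod_consistency <- function(x, ...) {
  tab <- x$table
  ylim <- range(tab$lcl, tab$ucl, 0)
  graphics::plot(tab$concentration, tab$dpod, type = "b", pch = 16, ylim = ylim,
                 xlab = "Spiked concentration (mg/kg)", ylab = "dPOD", ...)
  graphics::arrows(tab$concentration, tab$lcl, tab$concentration, tab$ucl,
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Read a detection count table
#'
#' Reads a CSV with header `concentration,x,N` (concentration in mg/kg,
#' `x` positives out of `N` replicates).
#'
#' @param path file path.
#' @return data frame suitable for [pod_curve()].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) .stop_input(paste0("no such file: ", path))
  tab <- utils::read.csv(path)
  need <- c("concentration", "x", "N")
  if (!all(need %in% names(tab)))
    .stop_input("count table must have columns concentration,x,N")
  tab[need]
}

.fixed3 <- function(v) formatC(v, format = "f", digits = 3)

#' Write a POD or consistency report as fixed-point CSV
#'
#' Mirrors the column order of published validation tables:
#' `concentration,x,N,POD,LCL,UCL` for a single curve, with the second
#' method's columns and `dPOD` appended for a consistency evaluation.
#' Proportions are written with three decimals; the dPOD column carries the
#' conventional absolute value.
#'
#' @param x a `pod_curve` or `pod_consistency` object.
#' @param path output CSV path.
#' @return the formatted data frame, invisibly.
#' @export
write_pod_report <- function(x, path) {
  if (inherits(x, "pod_curve")) {
    pts <- x$points
    out <- data.frame(concentration = pts$concentration, x = pts$x, N = pts$N,
                      POD = .fixed3(pts$pod), LCL = .fixed3(pts$lcl),
                      UCL = .fixed3(pts$ucl))
  } else if (inherits(x, "pod_consistency")) {
    tab <- x$table
    out <- data.frame(concentration = tab$concentration,
                      x = tab$x1, N = tab$N1, POD = .fixed3(tab$pod1),
                      LCL = .fixed3(tab$lcl1), UCL = .fixed3(tab$ucl1),
                      x2 = tab$x2, N2 = tab$N2, POD2 = .fixed3(tab$pod2),
                      LCL2 = .fixed3(tab$lcl2), UCL2 = .fixed3(tab$ucl2),
                      dPOD = .fixed3(tab$abs_dpod))
  } else {
    .stop_input("x must be a pod_curve or pod_consistency")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
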