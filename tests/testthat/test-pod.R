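# POD estimation, dPOD, curves, LOD, performance rates, consistency.

test_that("pod_estimate reproduces the three formula branches", {
  # interior branch, published cell
  e <- pod_estimate(40, 50)
  expect_equal(e$pod, 0.8)
  expect_equal(e$lcl, 0.6696, tolerance = 1e-4)
  expect_equal(e$ucl, 0.8876, tolerance = 1e-4)
  # x = 0 branch
  z <- pod_estimate(0, 10)
  expect_equal(z$pod, 0)
  expect_equal(z$lcl, 0)
  expect_equal(z$ucl, 3.8415 / 13.8415)
  # x = N branch
  f <- pod_estimate(40, 40)
  expect_equal(f$pod, 1)
  expect_equal(f$ucl, 1)
  expect_equal(f$lcl, 40 / 43.8415)
  # interior branch, frozen from direct evaluation of the formulas
  d <- pod_estimate(2, 40)
  expect_equal(d$pod, 0.05)
  expect_equal(d$lcl, 0.0138181277, tolerance = 1e-6)
  expect_equal(d$ucl, 0.1650398037, tolerance = 1e-6)
})

test_that("pod_estimate rejects out-of-domain counts", {
  expect_error(pod_estimate(-1, 10), class = "podscreen_input_error")
  expect_error(pod_estimate(11, 10), class = "podscreen_input_error")
  expect_error(pod_estimate(0, 0), class = "podscreen_input_error")
  expect_error(pod_estimate(2.5, 10), class = "podscreen_input_error")
})

test_that("interval estimates agree with an independent Wilson oracle", {
  for (N in c(1, 7, 23, 40, 50, 120)) {
    for (x in unique(round(seq(1, N - 1, length.out = 8)))) {
      if (x < 1 || x > N - 1) next
      e <- pod_estimate(x, N)
      w <- wilson_oracle(x, N)
      expect_equal(e$lcl, unname(w["lcl"]), tolerance = 1e-9)
      expect_equal(e$ucl, unname(w["ucl"]), tolerance = 1e-9)
    }
  }
})

test_that("interval estimates respect ordering and boundary invariants", {
  set.seed(11)
  for (i in 1:200) {
    N <- sample(1:200, 1)
    x <- sample(0:N, 1)
    e <- pod_estimate(x, N)
    expect_true(0 <= e$lcl && e$lcl <= e$pod && e$pod <= e$ucl && e$ucl <= 1)
  }
})

test_that("interval width shrinks as N grows at fixed x/N", {
  widths <- vapply(c(10, 20, 40, 80, 160), function(N) {
    e <- pod_estimate(0.8 * N, N)
    e$ucl - e$lcl
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("dpod_estimate matches the quadrature-combination formulas", {
  # published consistency cell: SERS 40/50 vs HPLC 50/50
  d <- dpod_estimate(pod_estimate(40, 50), pod_estimate(50, 50))
  expect_equal(d$abs_dpod, 0.200)
  # frozen from direct evaluation with unrounded component limits
  d2 <- dpod_estimate(pod_estimate(25, 40), pod_estimate(34, 40))
  expect_equal(d2$dpod, -0.225)
  expect_equal(d2$lcl, -0.3988631126, tolerance = 1e-6)
  expect_equal(d2$ucl, -0.0315254680, tolerance = 1e-6)
  # identical inputs
  same <- dpod_estimate(pod_estimate(30, 40), pod_estimate(30, 40))
  expect_equal(same$dpod, 0)
  expect_true(same$lcl <= 0 && same$ucl >= 0)
})

test_that("dpod point estimate is antisymmetric", {
  set.seed(3)
  for (i in 1:50) {
    N1 <- sample(5:60, 1); N2 <- sample(5:60, 1)
    a <- pod_estimate(sample(0:N1, 1), N1)
    b <- pod_estimate(sample(0:N2, 1), N2)
    expect_equal(dpod_estimate(a, b)$dpod, -dpod_estimate(b, a)$dpod)
  }
})

test_that("pod_curve sorts, validates, and maps counts through pod_estimate", {
  counts <- data.frame(concentration = c(5, 0, 0.5), x = c(40, 0, 39),
                       N = c(40, 10, 40))
  fit <- pod_curve(counts)
  expect_s3_class(fit, "pod_curve")
  expect_equal(fit$points$concentration, c(0, 0.5, 5))
  expect_equal(fit$points$pod, c(0, 39 / 40, 1))
  expect_error(pod_curve(data.frame(concentration = c(1, 1), x = c(1, 2),
                                    N = c(10, 10))),
               class = "podscreen_input_error")
  one <- pod_curve(data.frame(concentration = 0, x = 0, N = 10))
  expect_equal(nrow(one$points), 1L)
  expect_equal(one$points$pod, 0)
})

test_that("empirical PODs from a logistic generator are near-monotone", {
  set.seed(101)
  conc <- c(0, 0.05, 0.1, 0.5, 1, 2.5, 5)
  counts <- simulate_counts(conc, N = 200, c50 = 0.2, slope = 3)
  fit <- pod_curve(counts)
  # allow small sampling wiggle at N = 200
  expect_true(all(diff(fit$points$pod) > -0.08))
  expect_equal(fit$points$pod[1], 0)
})

test_that("LOD is the smallest non-zero concentration exceeding the threshold", {
  fit <- pod_curve(load_counts("cbz_qualitative_counts.csv"))
  expect_equal(lod(fit), 0.5)
  expect_equal(lod(fit, threshold = 0.999), 1.0)
  all_zero <- pod_curve(data.frame(concentration = c(0, 1, 2),
                                   x = c(0, 0, 0), N = c(10, 10, 10)))
  expect_true(is.na(lod(all_zero)))
})

test_that("LOD warns when the curve is non-monotone above the LOD", {
  dip <- pod_curve(data.frame(concentration = c(0.5, 1, 2),
                              x = c(40, 20, 40), N = c(40, 40, 40)))
  expect_warning(lod(dip), "not monotone")
  expect_equal(suppressWarnings(lod(dip)), 0.5)
})

test_that("performance rates complement the POD where defined", {
  fit <- pod_curve(load_counts("cbz_qualitative_counts.csv"))
  m <- method_metrics(fit)
  blank <- m$concentration == 0
  expect_equal(m$false_positive_rate[blank], 0)
  expect_equal(m$specificity[blank], 1)
  expect_true(all(is.na(m$sensitivity[blank])))
  nz <- !blank
  expect_equal(m$sensitivity[nz] + m$false_negative_rate[nz], rep(1, sum(nz)))
  expect_equal(m$sensitivity[m$concentration == 0.05], 0)
  expect_equal(m$false_negative_rate[m$concentration == 0.05], 1)
  expect_equal(m$sensitivity[nz], fit$points$pod[nz])
})

test_that("consistency evaluation finds the agreement concentration", {
  sers <- pod_curve(load_counts("cbz_sers_counts.csv"))
  hplc <- pod_curve(load_counts("cbz_hplc_counts.csv"))
  cons <- consistency_evaluation(sers, hplc)
  expect_equal(cons$consistent_from, 2.5)
  expect_equal(cons$table$abs_dpod[cons$table$concentration == 0.10], 0.200)

  lab1 <- pod_curve(load_counts("cbz_semiquant_lab1_counts.csv"))
  lab2 <- pod_curve(load_counts("cbz_semiquant_lab2_counts.csv"))
  expect_equal(consistency_evaluation(lab1, lab2)$consistent_from, 5.0)

  ident <- consistency_evaluation(sers, sers)
  expect_equal(ident$consistent_from, min(sers$points$concentration))
  expect_true(all(ident$table$dpod == 0))

  expect_error(consistency_evaluation(sers, lab1),
               class = "podscreen_input_error")
})

test_that("consistency in CI mode covers more concentrations than tol = 0", {
  lab1 <- pod_curve(load_counts("cbz_qual_lab1_counts.csv"))
  lab2 <- pod_curve(load_counts("cbz_qual_lab2_counts.csv"))
  point <- consistency_evaluation(lab1, lab2)
  ci <- consistency_evaluation(lab1, lab2, use_ci = TRUE)
  expect_true(sum(ci$table$consistent) >= sum(point$table$consistent))
})

test_that("count tables and reports round-trip through CSV", {
  fit <- pod_curve(load_counts("cbz_qualitative_counts.csv"))
  tmp <- withr::local_tempfile(fileext = ".csv")
  out <- write_pod_report(fit, tmp)
  back <- utils::read.csv(tmp, colClasses = "character")
  expect_equal(names(back), c("concentration", "x", "N", "POD", "LCL", "UCL"))
  expect_equal(back$LCL[back$concentration == "0.5"], "0.871")
  # consistency report mirrors the two-method table shape
  cons <- consistency_evaluation(fit, fit)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  rep2 <- write_pod_report(cons, tmp2)
  expect_true(all(c("x2", "N2", "POD2", "dPOD") %in% names(rep2)))
})
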