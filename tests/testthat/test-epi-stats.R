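test_that("1-in-X incidence estimates round half away from zero", {
  expect_equal(incidence_estimate(15, 401660)$one_in, 26777)
  expect_equal(incidence_estimate(10, 401660)$one_in, 40166)
  expect_equal(incidence_estimate(127, 401660)$one_in, 3163)
  expect_equal(incidence_estimate(2, 3)$one_in, 2)       # 1.5 rounds up
  est0 <- incidence_estimate(0, 1000)
  expect_true(is.na(est0$one_in))
  expect_equal(est0$rate_low, 0)
  expect_identical(est0$ci_one_in[["rarer"]], Inf)
  expect_gt(est0$rate_high, 0)
  expect_error(incidence_estimate(5, 4), "exceed")
})

test_that("interval methods match their independent base-R counterparts", {
  cases <- list(c(15, 401660), c(0, 50), c(3, 1000), c(127, 401660),
                c(50, 50))
  for (kn in cases) {
    k <- kn[1]; n <- kn[2]
    cp <- ci_rate(k, n, "clopper_pearson")
    ref_cp <- stats::binom.test(k, n)$conf.int
    expect_equal(cp, as.numeric(ref_cp), tolerance = 1e-6)

    w <- ci_rate(k, n, "wilson")
    ref_w <- stats::prop.test(k, n, correct = FALSE)$conf.int
    expect_equal(w, as.numeric(ref_w), tolerance = 1e-6)

    if (k < n) {  # Poisson approximation is for rare events
      pe <- ci_rate(k, n, "poisson_exact")
      ref_p <- stats::poisson.test(k)$conf.int / n
      expect_equal(pe, as.numeric(ref_p), tolerance = 1e-6)
    }
    # the point estimate sits inside every interval
    for (m in c("clopper_pearson", "wilson", "poisson_exact")) {
      ci <- ci_rate(k, n, m)
      expect_lte(ci[1], k / n)
      expect_gte(ci[2], min(k / n, 1))
    }
  }
  expect_error(ci_rate(3, 10, "bootstrap"), "arg")
})

test_that("spectrum shares and incidences reproduce from diagnosis counts", {
  tab <- utils::read.delim(system.file("extdata", "table3_spectrum.tsv",
                                       package = "nbscreen"))
  diagnoses <- tibble::tibble(
    patient_id = seq_len(sum(tab$patients)),
    condition = rep(tab$condition, tab$patients))
  sp <- spectrum_summary(diagnoses, n_screened = 401660)
  expect_identical(sp$n_patients, 153L)
  aamd <- sp$categories[sp$categories$category == "AAMD", ]
  expect_identical(aamd$count, 79L)
  expect_equal(aamd$percent, 51.63)
  expect_equal(aamd$one_in, 5084)
  famd <- sp$categories[sp$categories$category == "FAMD", ]
  expect_equal(famd$percent, 28.76)

  single <- spectrum_summary(
    tibble::tibble(patient_id = 1, condition = "Phenylketonuria"), 5000)
  expect_equal(single$conditions$percent, 100)
  expect_equal(single$conditions$one_in, 5000)

  expect_error(spectrum_summary(
    tibble::tibble(patient_id = 1, condition = "Unknown disease"), 100),
    "without category")
})

test_that("chi-square tests agree with a brute-force expected-count oracle", {
  set.seed(19)
  for (i in 1:20) {
    m <- matrix(stats::rpois(6, lambda = sample(5:200, 1)) + 1, 3)
    counts <- tibble::tibble(variable = "v",
                             stratum = paste0("s", 1:3),
                             unaffected = m[, 1], patients = m[, 2])
    got <- compare_groups(counts)
    exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
    stat <- sum((m - exp_counts)^2 / exp_counts)
    expect_equal(got$statistic, stat, tolerance = 1e-10)
    expect_equal(got$df, (nrow(m) - 1) * 1, ignore_attr = TRUE)
  }
})

test_that("identical case proportions give a null chi-square", {
  counts <- tibble::tibble(variable = "v", stratum = c("a", "b"),
                           unaffected = c(1000, 2000), patients = c(10, 20))
  got <- compare_groups(counts)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_rounded, 1)
})

test_that("strata are excluded before testing and emptiness is an error", {
  counts <- tibble::tibble(variable = "v",
                           stratum = c("a", "No record"),
                           unaffected = c(10, 5), patients = c(1, 0))
  expect_error(compare_groups(counts), "fewer than 2 strata")
})

test_that("one-way ANOVA matches the equal-variance F test", {
  set.seed(23)
  x <- c(stats::rnorm(200, 7.35, 2), stats::rnorm(50, 6.98, 2))
  g <- rep(c("unaffected", "patient"), c(200, 50))
  got <- compare_continuous(x, g)
  ref <- stats::oneway.test(x ~ g, var.equal = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})
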