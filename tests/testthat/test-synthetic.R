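small_params <- function(n = 20000, seed = 11, ...) {
  cohort_params(n_newborns = n, seed = seed, fp_inflation = 0, ...)
}

test_that("cohort generation is reproducible and respects degenerate rates", {
  pm <- small_params()
  co1 <- generate_cohort(pm)
  co2 <- generate_cohort(pm)
  expect_identical(co1, co2)
  other <- generate_cohort(small_params(seed = 12))
  expect_false(identical(co1$true_condition, other$true_condition))

  none <- small_params(n = 5000)
  none$prevalences[] <- 0
  expect_identical(sum(!is.na(generate_cohort(none)$true_condition)), 0L)
})

test_that("observed per-condition counts stay in the exact binomial band", {
  pm <- small_params(n = 401660, seed = 3)
  co <- generate_cohort(pm)
  counts <- table(co$true_condition)
  # familywise 95% band (Bonferroni over the 22 conditions)
  alpha <- 0.05 / length(pm$prevalences)
  for (cond in names(pm$prevalences)) {
    k <- if (cond %in% names(counts)) as.integer(counts[[cond]]) else 0L
    band <- stats::qbinom(c(alpha / 2, 1 - alpha / 2), pm$n_newborns,
                          pm$prevalences[[cond]])
    expect_true(k >= band[1] && k <= band[2],
                info = sprintf("%s: %d outside [%d, %d]", cond, k,
                               band[1], band[2]))
  }
  # demographics are sampled independently of disease state
  aff <- !is.na(co$true_condition)
  expect_gt(stats::chisq.test(table(co$gender[co$gender != "No record"],
                                    aff[co$gender != "No record"]))$p.value,
            1e-4)
})

test_that("genotype draws follow the configured allele spectra", {
  spectra <- builtin_allele_spectra()
  pcud <- spectra[["Primary carnitine uptake defect"]]
  f <- pcud$alleles$freq[pcud$alleles$label == "SLC22A5:c.1400C>G"]
  expect_equal(f, 0.5)
  set.seed(5)
  g <- generate_genotype("Primary carnitine uptake defect", pcud, 4000)
  expect_true(all(lengths(g) == 2L))
  hom <- mean(vapply(g, function(x)
    all(x == "SLC22A5:c.1400C>G"), logical(1)))
  # closed form: homozygosity probability is the squared allele frequency
  expect_lt(abs(hom - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))

  single <- pcud
  single$alleles <- tibble::tibble(label = "only", freq = 1)
  expect_identical(unique(generate_genotype("x", single, 50)),
                   list(c("only", "only")))

  hmet <- spectra[["Hypermethioninemia"]]
  expect_identical(hmet$inheritance, "dominant_or_recessive")
  set.seed(6)
  gh <- generate_genotype("Hypermethioninemia", hmet, 2000,
                          dominant_single_prob = 12 / 13)
  p1 <- mean(lengths(gh) == 1L)
  expect_lt(abs(p1 - 12 / 13), 3 * sqrt((12 / 13) * (1 / 13) / 2000))

  expect_error(generate_genotype("x", NULL), "missing allele spectrum")
})

test_that("affected profiles fire their condition's screening group", {
  pm <- small_params(n = 4000, seed = 21)
  co <- generate_cohort(pm)
  # plant every condition densely to measure sensitivity per condition
  conds <- names(pm$prevalences)
  co$true_condition <- rep_len(conds, nrow(co))
  panel <- builtin_panel()
  prof <- generate_profiles(co, pm, panel)
  scr <- screen_profiles(prof$values, panel)
  map <- condition_screen_group()
  for (cond in conds) {
    idx <- co$true_condition == cond
    hit <- mean(scr$positive[idx, map[[cond]]])
    expect_gte(hit, 0.99)
  }
})

test_that("without tail inflation the unaffected population screens clean", {
  pm <- small_params(n = 20000, seed = 8)
  pm$prevalences[] <- 0
  co <- generate_cohort(pm)
  prof <- generate_profiles(co, pm)
  rate <- mean(screen_profiles(prof$values)$any_positive)
  expect_lt(rate, 1e-3)
})

test_that("recall profiles regress unaffected deviations, keep shifts", {
  pm <- small_params(n = 3000, seed = 9)
  pm$fp_inflation <- 0.5
  pm$retest_attenuation <- 0.8
  co <- generate_cohort(pm)
  co$true_condition <- c(rep("Phenylketonuria", 500),
                         rep(NA_character_, nrow(co) - 500))
  co$genotype <- vector("list", nrow(co))
  init <- generate_profiles(co, pm)
  scr1 <- screen_profiles(init$values)
  idx <- which(scr1$any_positive)
  rec <- generate_recall_profiles(init, idx, co, pm)
  scr2 <- screen_profiles(rec$values)
  aff <- !is.na(co$true_condition[idx])
  # persistent marker shift: affected re-fire; attenuation: most FPs clear
  expect_gte(mean(scr2$any_positive[aff]), 0.99)
  expect_lt(mean(scr2$any_positive[!aff]), 0.25)
  # reproducible
  rec2 <- generate_recall_profiles(init, idx, co, pm)
  expect_identical(rec$values, rec2$values)
})

test_that("calibration hits the target initial-positive rate", {
  pm <- cohort_params(n_newborns = 150000, seed = 13)
  pm$fp_inflation <- calibrate_fp_inflation(pm, n_pilot = 50000)
  expect_gt(pm$fp_inflation, 0)
  expect_lt(pm$fp_inflation, 0.2)
  co <- generate_cohort(pm)
  prof <- generate_profiles(co, pm)
  rate <- mean(screen_profiles(prof$values)$any_positive)
  expect_lt(abs(rate - 0.028), 0.0025)
})

test_that("parameter validation rejects malformed configurations", {
  expect_error(cohort_params(retest_attenuation = 1.5), "retest_attenuation")
  expect_error(cohort_params(fp_inflation = 1), "fp_inflation")
  bad_margin <- demographic_margins()
  bad_margin$gender <- c(Male = 0.6, Female = 0.6)
  expect_error(cohort_params(margins = bad_margin), "sum to 1")
  bad_target <- condition_marker_targets()
  bad_target[["Phenylketonuria"]] <- c(NOT_AN_ANALYTE = 5)
  expect_error(cohort_params(marker_targets = bad_target),
               "unknown analyte")
  pm <- cohort_params()
  expect_error(generate_profiles(generate_cohort(small_params(n = 10)), pm),
               "fp_inflation is unset")
})
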