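pkg_variants <- function() suppressWarnings(load_variant_table())

test_that("the packaged variant table loads with the published block sizes", {
  v <- pkg_variants()
  pku <- v[v$condition == "Phenylketonuria", ]
  expect_identical(sum(pku$alleles), 24L)
  expect_identical(unique(pku$n_patients), 12L)
  expect_identical(sum(pku$cdna != "undetectable"), 17L)
  # dominant hypermethioninemia: fewer than 2 alleles per patient is legal
  hmet <- v[v$condition == "Hypermethioninemia", ]
  expect_identical(sum(hmet$alleles), 14L)
  expect_identical(unique(hmet$n_patients), 13L)
})

test_that("per-variant statistics reproduce the published hotspot numbers", {
  v <- pkg_variants()
  check <- function(cond, cdna, rf, pct) {
    s <- summarize_condition(v, cond)
    row <- s$variants[s$variants$cdna == cdna, ]
    expect_equal(row$rf_percent, rf, info = paste(cond, cdna))
    expect_equal(row$patient_percent, pct, info = paste(cond, cdna))
  }
  check("Phenylketonuria", "c.728G>A", 20.8, 41.7)
  check("Mild hyperphenylalaninemia", "c.158G>A", 25.0, 50.0)
  check("Primary carnitine uptake defect", "c.1400C>G", 50.0, 80.0)
  check("Short chain acyl-CoA dehydrogenase deficiency", "c.1031A>G",
        42.9, 71.4)
  check("Hypermethioninemia", "c.791G>A", 71.4, 76.9)
  check("Methylmalonic acidemia", "c.1663G>A", 15.0, 30.0)
  # homozygous single-patient condition
  check("Argininosuccinate aciduria", "c.331C>T", 100.0, 100.0)
})

test_that("relative frequencies sum to 100 within rounding, with sane bounds", {
  v <- pkg_variants()
  for (cond in unique(v$condition)) {
    s <- summarize_condition(v, cond)
    expect_lt(abs(sum(s$variants$rf_percent) - 100), 0.5)
    expect_true(all(s$variants$patient_percent <= 100))
    expect_true(all(s$variants$alleles >= s$variants$cases))
  }
})

test_that("hotspot ranking filters and orders by RF then carriage", {
  v <- pkg_variants()
  pcud <- rank_hotspots(summarize_condition(v, "Primary carnitine uptake defect"))
  expect_identical(pcud$cdna[1], "c.1400C>G")
  expect_equal(pcud$rf_percent[1], 50.0)
  hmet <- rank_hotspots(summarize_condition(v, "Hypermethioninemia"))
  expect_identical(hmet$cdna[1], "c.791G>A")
  expect_equal(hmet$rf_percent[1], 71.4)
  # all-singleton spectrum yields no hotspots at min_cases = 2
  tyr <- rank_hotspots(summarize_condition(v, "Tyrosinemia"),
                       min_rf = 10, min_cases = 2)
  expect_identical(nrow(tyr), 0L)
  # undetectable mass is never a hotspot even when frequent
  ctln <- rank_hotspots(summarize_condition(v, "Citrullinemia"))
  expect_false("undetectable" %in% ctln$cdna)
})

test_that("distinct-mutation tallies pool phenotype blocks of one gene", {
  t <- tally_pathogenicity(pkg_variants())
  expect_identical(t$n_reported, 89L)
  expect_identical(t$n_novel, 51L)
  expect_identical(t$n_distinct, 140L)
  # the shared PAH allele appears in both hyperphenylalaninemia blocks but
  # is counted once
  v <- pkg_variants()
  shared <- v[v$cdna == "c.728G>A", ]
  expect_identical(nrow(shared), 2L)
  t_pah <- tally_pathogenicity(shared)
  expect_identical(t_pah$n_distinct, 1L)
  empty <- tally_pathogenicity(v[0, ])
  expect_identical(empty$n_reported, 0L)
})

write_variant_fixture <- function(rows) {
  header <- "condition\tgene\talleles\tcdna\tprotein\treported\tpathogenicity\tcases\tn_patients"
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(header, rows), path)
  path
}

test_that("table validation enforces the variant-record invariants", {
  # more than two alleles for a single carrier
  bad <- write_variant_fixture("X\tG1\t3\tc.1A>G\tp.K1E\tY\tP\t1\t2")
  expect_error(load_variant_table(bad), "more than 2 alleles per carrier")
  # malformed nucleotide string
  mal <- write_variant_fixture("X\tG1\t1\tnot_hgvs\tp.K1E\tY\tP\t1\t2")
  expect_error(load_variant_table(mal), "malformed cDNA")
  # legacy forms are accepted after normalisation
  legacy <- write_variant_fixture(c(
    "X\tG1\t1\tc.IVS16ins3Kb\t\tY\tP\t1\t3",
    "X\tG1\t1\t1197A>T\tp.V399X\tY\tP\t1\t3",
    "X\tG1\t1\tC.1165A>G\tp.M389V\tN\tLP\t1\t3"))
  v <- load_variant_table(legacy)
  expect_identical(nrow(v), 3L)
  expect_identical(v$cdna[2], "1197A>T")   # stored verbatim
  # a homozygote written as two identical rows collapses to one record
  hom <- write_variant_fixture(c(
    "X\tG1\t1\tc.5C>T\tp.T2M\tY\tP\t1\t1",
    "X\tG1\t1\tc.5C>T\tp.T2M\tY\tP\t1\t1"))
  vh <- load_variant_table(hom)
  expect_identical(nrow(vh), 1L)
  expect_identical(vh$alleles, 2L)
  expect_identical(vh$cases, 1L)
  # undetectable placeholder with 2 alleles is accepted, denominator only
  und <- write_variant_fixture(c(
    "X\tG1\t2\tc.5C>T\tp.T2M\tY\tP\t1\t2",
    "X\t\t2\tundetectable\t\t\tundetectable\t2\t2"))
  vu <- load_variant_table(und)
  s <- summarize_condition(vu, "X")
  expect_identical(s$total_alleles, 4L)
  expect_equal(s$variants$rf_percent[s$variants$cdna == "c.5C>T"], 50.0)
  expect_identical(tally_pathogenicity(vu)$n_distinct, 1L)
})

test_that("simulated genotypes recover the configured allele spectra", {
  pm <- cohort_params(n_newborns = 60000, seed = 17, fp_inflation = 0)
  pm$prevalences <- pm$prevalences * 20
  co <- generate_cohort(pm)
  obs <- observed_allele_spectrum(co)
  spectra <- builtin_allele_spectra()
  checked <- 0
  for (cond in unique(obs$condition)) {
    sp <- spectra[[cond]]$alleles
    sub <- obs[obs$condition == cond, ]
    m <- sum(sub$count)
    for (j in seq_len(nrow(sp))) {
      if (m * sp$freq[j] < 5) next
      got <- sub$freq[match(sp$label[j], sub$label)]
      if (is.na(got)) got <- 0
      se <- sqrt(sp$freq[j] * (1 - sp$freq[j]) / m)
      expect_lte(abs(got - sp$freq[j]), 3 * se,
                label = paste(cond, sp$label[j]))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 30)
})
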