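test_that("derived markers evaluate as sums and ratios with undefined guards", {
  expect_equal(eval_marker(c(PHE = 150, TYR = 50), "PHE/TYR"), 3.0)
  expect_true(is.na(eval_marker(c(PHE = 150, TYR = 0), "PHE/TYR")))
  expect_equal(eval_marker(c(LEU = 200, ILE = 100, `PRO-OH` = 50),
                           "LEU+ILE+PRO-OH"), 350)
  # missing member analyte -> undefined
  expect_true(is.na(eval_marker(c(LEU = 200, ILE = 100), "LEU+ILE+PRO-OH")))
  expect_equal(eval_marker(c(C3 = 3, C0 = 10), "C3/C0"), 0.3)
  expect_error(eval_marker(c(PHE = 1), "NOT_A_MARKER"), "unknown marker")
})

test_that("rules apply printed operators exactly, strict at the boundary", {
  p <- builtin_panel()
  pcud_rule <- p$groups[[which(vapply(p$groups, `[[`, "", "group_id") == "PCUD")]]$rules[[1]]
  expect_true(eval_rule(c(C0 = 5.0), pcud_rule, p))
  expect_false(eval_rule(c(C0 = 9.5), pcud_rule, p))   # strict "<" at cut-off
  r <- rule(comparison("PHE", ">", 100), comparison("PHE/TYR", ">", 1.2))
  expect_false(eval_rule(c(PHE = 150, TYR = 140), r, p))  # ratio 1.07
  expect_true(eval_rule(c(PHE = 150, TYR = 50), r, p))
  # the one printed ">=" cut-off admits equality
  lchadd <- p$groups[[which(vapply(p$groups, `[[`, "", "group_id") == "LCHADD_TFP")]]$rules[[1]]
  at_boundary <- reference_profile(`C16-OH` = 0.2, `C18:1-OH` = 0.06,
                                   `C18-OH` = 0.1)
  expect_true(eval_rule(at_boundary, lchadd, p))
  expect_false(eval_rule(reference_profile(`C16-OH` = 0.2,
                                           `C18:1-OH` = 0.0599,
                                           `C18-OH` = 0.1), lchadd, p))
})

test_that("screening flags the expected groups on canonical profiles", {
  p <- builtin_panel()
  # frank hyperphenylalaninemia fires all three rules of its group, nothing else
  res <- screen_profile(reference_profile(PHE = 150, TYR = 50), p)
  pos <- names(Filter(function(f) f$positive, res$flags))
  expect_identical(pos, "PKU_MHPA_BH4")
  expect_identical(res$flags[["PKU_MHPA_BH4"]]$fired_rules, 1:3)
  # mid-normal reference vector satisfies no rule of any group
  res_ref <- screen_profile(analyte_reference(), p)
  expect_length(Filter(function(f) f$positive, res_ref$flags), 0)
  # degenerate all-zero profile fires exactly the low-marker rules
  zero <- stats::setNames(rep(0, length(analyte_reference())),
                          names(analyte_reference()))
  res0 <- screen_profile(zero, p)
  expect_setequal(names(Filter(function(f) f$positive, res0$flags)),
                  c("OTC", "PCUD"))
})

test_that("screening is deterministic and missing analytes degrade gracefully", {
  p <- builtin_panel()
  m <- random_profiles(20)
  expect_identical(screen_profiles(m, p), screen_profiles(m, p))
  partial <- m[, setdiff(colnames(m), "TYR"), drop = FALSE]
  expect_warning(res <- screen_profiles(partial, p), "missing analyte")
  # comparisons on TYR-based ratios are false, PHE-only rules still fire
  high_phe <- reference_profile(PHE = 500)
  expect_warning(
    res1 <- screen_profiles(matrix(high_phe[names(high_phe) != "TYR"], 1,
                                   dimnames = list(NULL, setdiff(names(high_phe), "TYR"))),
                            p),
    "missing analyte")
  expect_true(res1$positive[1, "PKU_MHPA_BH4"])   # via rule 2, PHE > 130
})

test_that("hyperphenylalaninemia subtypes split at 120 and 360 umol/L", {
  expect_identical(classify_hpa_subtype(c(400, 200, 119)),
                   c("PKU", "M_HPA", "BELOW_THRESHOLD"))
  expect_identical(classify_hpa_subtype(360), "PKU")
  expect_identical(classify_hpa_subtype(120), "M_HPA")
  expect_error(classify_hpa_subtype(-1), "non-negative")
})

test_that("raising a one-directional analyte never unflags its group", {
  p <- builtin_panel()
  mono <- monotone_increasing_analytes(p)
  set.seed(42)
  m <- random_profiles(300)
  res <- screen_profiles(m, p)
  for (gid in names(mono)) {
    for (a in mono[[gid]]) {
      bumped <- m
      bumped[, a] <- bumped[, a] * 1.5
      res2 <- screen_profiles(bumped, p)
      was_pos <- res$positive[, gid]
      expect_true(all(res2$positive[was_pos, gid]),
                  info = paste("group", gid, "analyte", a))
    }
  }
})

test_that("the engine agrees with a brute-force printed-string evaluator", {
  p <- builtin_panel()
  set.seed(7)
  m <- random_profiles(1000)
  res <- screen_profiles(m, p)
  for (i in seq_len(nrow(m))) {
    oracle <- oracle_positive_groups(m[i, ])
    expect_identical(unname(res$positive[i, names(oracle)]), unname(oracle),
                     info = paste("profile", i))
  }
})
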