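#!/usr/bin/env Rscript

# Step 4: cohort-characteristic comparisons between unaffected newborns and
# patients. Categorical strata are tested with Pearson chi-square (no
# continuity correction, "No record" excluded); the same tests are run on a
# synthetic cohort, where demographics are generated independently of
# disease state, as a negative control.

suppressPackageStartupMessages(library(nbscreen))

dir.create("results", recursive = TRUE, showWarnings = FALSE)

program <- compare_groups(table_characteristics())
cat("program characteristic tests:\n")
print(as.data.frame(program[, c("variable", "statistic", "df", "p_rounded")]))
utils::write.table(program, "results/characteristics_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# negative control on a synthetic cohort (no demographic-disease coupling)
params <- cohort_params(n_newborns = 401660, seed = 20140601,
                        fp_inflation = 0)
cohort <- generate_cohort(params)
affected <- !is.na(cohort$true_condition)
vars <- c(gender = "gender", gestational_age = "gestational_age_band",
          birth_weight = "birth_weight_band",
          fetus_number = "fetus_number",
          register_region = "register_region",
          household_registration = "household_registration")
sim_counts <- do.call(rbind, lapply(names(vars), function(v) {
  t <- table(cohort[[vars[[v]]]], affected)
  tibble::tibble(variable = v, stratum = rownames(t),
                 unaffected = as.integer(t[, 1]),
                 patients = as.integer(t[, 2]))
}))
sim <- compare_groups(sim_counts)
utils::write.table(sim, "results/characteristics_tests_synthetic.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("synthetic-cohort p-values (expect no association): %s\n",
            paste(sprintf("%s %.3f", sim$variable, sim$p_rounded),
                  collapse = ", ")))

# age at initial testing, one-way ANOVA on the synthetic cohort
age <- compare_continuous(cohort$age_at_initial_testing_days,
                          ifelse(affected, "patient", "unaffected"))
cat(sprintf("age at initial testing ANOVA: F = %.3f, p = %.3f\n",
            age$statistic, age$p_value))
cat("wrote results/characteristics_tests*.tsv\n")
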