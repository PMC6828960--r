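#!/usr/bin/env Rscript

# Step 3: incidence and disease-spectrum epidemiology from the program's
# diagnosis counts: per-condition and per-category 1-in-X estimates with
# exact (Clopper-Pearson) 95% intervals, category shares of all patients,
# and the overall incidence excluding the two questionable-phenotype
# conditions (SCADD, 3-MCCD).

suppressPackageStartupMessages(library(nbscreen))

dir.create("results", recursive = TRUE, showWarnings = FALSE)
n_screened <- 401660

tab <- utils::read.delim(system.file("extdata", "table3_spectrum.tsv",
                                     package = "nbscreen"))
diagnoses <- tibble::tibble(patient_id = seq_len(sum(tab$patients)),
                            condition = rep(tab$condition, tab$patients))
sp <- spectrum_summary(diagnoses, n_screened)

fmt_est <- function(k) {
  est <- incidence_estimate(k, n_screened)
  sprintf("1/%d (1/%s-1/%s)", est$one_in,
          format(est$ci_one_in[["rarer"]], big.mark = ","),
          format(est$ci_one_in[["commoner"]], big.mark = ","))
}
out <- rbind(
  tibble::tibble(level = sp$categories$category, count = sp$categories$count,
                 percent = sp$categories$percent,
                 incidence = vapply(sp$categories$count, fmt_est, "")),
  tibble::tibble(level = sp$conditions$condition, count = sp$conditions$count,
                 percent = sp$conditions$percent,
                 incidence = vapply(sp$conditions$count, fmt_est, "")))
utils::write.table(out, "results/incidence_table.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

questionable <- c("Short chain acyl-CoA dehydrogenase deficiency",
                  "3-Methylcrotonyl-CoA carboxylase deficiency")
k_overall <- sum(tab$patients[!tab$condition %in% questionable])
overall <- incidence_estimate(k_overall, n_screened)
cat(sprintf("overall incidence excluding SCADD and 3-MCCD: %d cases, 1/%d\n",
            k_overall, overall$one_in))
cat(sprintf("category shares: %s\n",
            paste(sprintf("%s %.2f%%", sp$categories$category,
                          sp$categories$percent), collapse = ", ")))
cat("wrote results/incidence_table.tsv\n")
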