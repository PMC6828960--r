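#!/usr/bin/env Rscript

# Step 5: variant-spectrum statistics. Summarises every condition's allele
# table (RF%, patient carriage), ranks hotspot variants, tallies distinct
# reported/novel mutations, and checks that genotypes drawn by the
# synthetic-cohort generator recover the configured allele spectra.

suppressPackageStartupMessages(library(nbscreen))

dir.create("results", recursive = TRUE, showWarnings = FALSE)

variants <- suppressWarnings(load_variant_table())
conds <- unique(variants$condition)

summaries <- do.call(rbind, lapply(conds, function(cond) {
  s <- summarize_condition(variants, cond)
  tibble::tibble(condition = cond, s$variants,
                 total_alleles = s$total_alleles, n_patients = s$n_patients)
}))
utils::write.table(summaries, "results/variant_spectrum.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

hotspots <- do.call(rbind, lapply(conds, function(cond) {
  h <- rank_hotspots(summarize_condition(variants, cond),
                     min_rf = 10, min_cases = 2)
  if (nrow(h) == 0) return(NULL)
  tibble::tibble(condition = cond, h)
}))
utils::write.table(hotspots, "results/hotspots.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("hotspot variants (RF >= 10%%, >= 2 carriers) in %d conditions\n",
            length(unique(hotspots$condition))))
top <- hotspots[order(-hotspots$rf_percent), ][1:5, ]
print(as.data.frame(top[, c("condition", "gene", "cdna", "rf_percent",
                            "patient_percent")]))

tally <- tally_pathogenicity(variants)
cat(sprintf("distinct mutations: %d (%d reported, %d novel)\n",
            tally$n_distinct, tally$n_reported, tally$n_novel))

# allele-spectrum recovery from simulated genotypes
params <- cohort_params(n_newborns = 401660, seed = 20140601,
                        fp_inflation = 0)
cohort <- generate_cohort(params)
obs <- observed_allele_spectrum(cohort)
spectra <- builtin_allele_spectra()
recovery <- do.call(rbind, lapply(unique(obs$condition), function(cond) {
  sp <- spectra[[cond]]$alleles
  sub <- obs[obs$condition == cond, ]
  tibble::tibble(condition = cond, label = sp$label,
                 configured = sp$freq,
                 observed = ifelse(is.na(match(sp$label, sub$label)), 0,
                                   sub$freq[match(sp$label, sub$label)]),
                 n_alleles = sum(sub$count))
}))
utils::write.table(recovery, "results/allele_recovery.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
dev <- with(recovery[recovery$n_alleles * recovery$configured >= 5, ],
            max(abs(observed - configured) /
                  sqrt(configured * (1 - configured) / n_alleles)))
cat(sprintf("max |observed - configured| over binomial SE: %.2f\n", dev))
cat("wrote results/variant_spectrum.tsv, hotspots.tsv, allele_recovery.tsv\n")
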