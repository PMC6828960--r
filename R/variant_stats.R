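#' Load a variant table
#'
#' Reads a TSV of per-condition variant observations (one row per distinct
#' variant per condition block) with columns `condition`, `gene`, `alleles`
#' (mutant allele count), `cdna` (HGVS-style nucleotide change, stored
#' verbatim), `protein`, `reported` (Y/N), `pathogenicity` (P, LP, P/LP, US,
#' CIP, NP), `cases` (patients carrying the variant) and `n_patients`
#' (patients in the condition block). Alleles not resolved by sequencing
#' appear as `cdna == "undetectable"` placeholder rows that contribute to
#' the allele denominator only.
#'
#' Homozygous single-patient observations may be written either as one row
#' with `alleles = 2` or two identical rows; duplicates are merged. cDNA
#' strings are validated against a tolerant `c.`-prefix grammar (allowing
#' substitutions, `del`/`dup`/`ins` forms, intronic offsets and legacy
#' `IVS` notation) after normalising case and missing prefixes, but are
#' never rewritten in the output.
#'
#' @param path TSV path; defaults to the packaged variant table.
#' @return tibble of validated variant records.
#' @export
load_variant_table <- function(path = system.file("extdata",
                                                  "table4_variants.tsv",
                                                  package = "nbscreen")) {
  v <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                           na.strings = NULL,
                                           colClasses = "character"))
  required <- c("condition", "gene", "alleles", "cdna", "protein",
                "reported", "pathogenicity", "cases", "n_patients")
  missing <- setdiff(required, names(v))
  if (length(missing) > 0)
    stop("variant table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  v$alleles <- as.integer(v$alleles)
  v$cases <- as.integer(v$cases)
  v$n_patients <- as.integer(v$n_patients)

  # normalise duplicated rows (a homozygote written as two identical
  # records) to a single record: allele counts add, carrier counts do not
  key <- paste(v$condition, v$gene, v$cdna, v$protein, sep = "\r")
  if (anyDuplicated(key)) {
    alleles <- tapply(v$alleles, key, sum)
    cases <- tapply(v$cases, key, max)
    first <- !duplicated(key)
    v <- v[first, ]
    v$alleles <- unname(alleles[key[first]])
    v$cases <- unname(cases[key[first]])
  }

  detected <- v$cdna != "undetectable"
  bad <- detected & !grepl(hgvs_cdna_grammar(), normalize_cdna(v$cdna))
  if (any(bad))
    stop("malformed cDNA string(s): ",
         paste(unique(v$cdna[bad]), collapse = ", "), call. = FALSE)
  if (any(v$alleles < 1 | v$cases < 1))
    stop("allele and case counts must be >= 1", call. = FALSE)
  if (any(v$alleles > 2 * v$cases))
    stop("more than 2 alleles per carrier for variant(s): ",
         paste(v$cdna[v$alleles > 2 * v$cases], collapse = ", "),
         call. = FALSE)
  tot <- rowsum(v$alleles, v$condition)
  npat <- tapply(v$n_patients, v$condition, function(x) unique(x)[1])
  over <- rownames(tot)[tot[, 1] > 2 * npat[rownames(tot)]]
  # a warning, not an error: published tables footnote blocks whose allele
  # totals exceed 2 per patient (dominant alleles, partial sequencing)
  if (length(over) > 0)
    warning("condition(s) totalling more than 2 alleles per patient: ",
            paste(over, collapse = ", "), call. = FALSE)
  v
}

# Tolerant HGVS-like cDNA grammar: substitutions (c.728G>A), deletions /
# duplications / insertions (c.852_855delTATG, c.1679dupA, c.729_730insTT),
# intronic and UTR offsets (c.1315+6T>A, c.442-1G>A, c.278-31_278-18del) and
# legacy intron notation (c.IVS16ins3Kb).
hgvs_cdna_grammar <- function() {
  pos <- "[-*]?\\d+([-+]\\d+)?"
  paste0("^c\\.(",
         "IVS\\d+(ins|del|dup)[0-9A-Za-z]+",
         "|", pos, "(_", pos, ")?((del|dup|ins)[ACGTacgt0-9A-Za-z]*",
         "|[ACGT]>[ACGT])",
         ")$")
}

normalize_cdna <- function(x) {
  x <- gsub("\\s+", "", x)
  x <- sub("^C\\.", "c.", x)
  ifelse(grepl("^c\\.", x), x, paste0("c.", x))
}

normalize_protein <- function(x) {
  x <- gsub("\\s+", "", x)
  x <- sub("^/$", "", x)
  x <- sub("^P\\.", "p.", x)
  ifelse(x == "" | grepl("^p\\.", x), x, paste0("p.", x))
}

#' Summarise the variant spectrum of one condition
#'
#' Per-variant relative allele frequency
#' `RF% = 100 * alleles / total alleles` (the denominator includes
#' undetectable placeholder alleles) and patient carriage
#' `patient% = 100 * cases / n_patients`, both rounded half away from zero
#' to 1 decimal, ranked by RF% descending with ties broken lexicographically
#' by cDNA string.
#'
#' @param variants tibble from [load_variant_table()].
#' @param condition condition name present in `variants`.
#' @return a list of class `nbs_variant_summary`: `condition`,
#'   `total_alleles`, `n_patients`, and `variants` tibble with `rf_percent`
#'   and `patient_percent`.
#' @examples
#' s <- summarize_condition(load_variant_table(), "Phenylketonuria")
#' s$variants[s$variants$cdna == "c.728G>A", c("rf_percent", "patient_percent")]
#' @export
summarize_condition <- function(variants, condition) {
  sub <- variants[variants$condition == condition, ]
  if (nrow(sub) == 0)
    stop("no variant records for condition: ", condition, call. = FALSE)
  total <- sum(sub$alleles)
  npat <- unique(sub$n_patients)
  if (length(npat) != 1)
    stop("inconsistent n_patients within condition block", call. = FALSE)
  sub$rf_percent <- round_half_away(100 * sub$alleles / total, 1)
  sub$patient_percent <- round_half_away(100 * sub$cases / npat, 1)
  sub <- sub[order(-sub$rf_percent, sub$cdna), ]
  structure(list(condition = condition, total_alleles = total,
                 n_patients = npat,
                 variants = sub[, c("gene", "cdna", "protein", "reported",
                                    "pathogenicity", "alleles", "rf_percent",
                                    "cases", "patient_percent")]),
            class = "nbs_variant_summary")
}

#' @export
print.nbs_variant_summary <- function(x, ...) {
  cat(sprintf("<variant spectrum %s: %d alleles in %d patients, %d entries>\n",
              x$condition, x$total_alleles, x$n_patients, nrow(x$variants)))
  print(x$variants)
  invisible(x)
}

#' Rank hotspot variants of a condition
#'
#' Hotspots are recurrent variants: relative allele frequency at least
#' `min_rf` percent and carried by at least `min_cases` patients, ranked by
#' RF% then case count (descending). Undetectable placeholder mass is never
#' a hotspot.
#'
#' @param summary an `nbs_variant_summary` from [summarize_condition()].
#' @param min_rf minimum RF% (percent).
#' @param min_cases minimum patient count.
#' @return tibble of qualifying variants in rank order (possibly empty).
#' @export
rank_hotspots <- function(summary, min_rf = 10, min_cases = 2) {
  v <- summary$variants
  v <- v[v$cdna != "undetectable" & v$rf_percent >= min_rf &
           v$cases >= min_cases, ]
  v[order(-v$rf_percent, -v$cases, v$cdna), ]
}

#' Tally distinct mutations by reported status and pathogenicity
#'
#' Counts distinct variants across all condition blocks, keyed by gene,
#' normalised cDNA and normalised protein change, so the same allele listed
#' under two phenotype blocks of one gene (e.g. the PKU and mild-HPA blocks
#' of PAH) is counted once. Undetectable placeholders are excluded.
#'
#' @param variants tibble from [load_variant_table()].
#' @return a list: `n_distinct`, `n_reported`, `n_novel`, and `by_class`
#'   tibble of reported-status x pathogenicity counts.
#' @examples
#' tally_pathogenicity(load_variant_table())[c("n_reported", "n_novel")]
#' @export
tally_pathogenicity <- function(variants) {
  v <- variants[variants$cdna != "undetectable", ]
  if (nrow(v) == 0)
    return(list(n_distinct = 0L, n_reported = 0L, n_novel = 0L,
                by_class = tibble::tibble(reported = character(),
                                          pathogenicity = character(),
                                          n = integer())))
  key <- paste(v$gene, normalize_cdna(v$cdna), normalize_protein(v$protein),
               sep = "\r")
  v <- v[!duplicated(key), ]
  by_class <- as.data.frame(table(reported = v$reported,
                                  pathogenicity = v$pathogenicity),
                            responseName = "n", stringsAsFactors = FALSE)
  by_class <- tibble::as_tibble(by_class[by_class$n > 0, ])
  list(n_distinct = nrow(v),
       n_reported = sum(v$reported == "Y"),
       n_novel = sum(v$reported == "N"),
       by_class = by_class)
}

#' Summarise simulated genotypes as an observed allele spectrum
#'
#' Pools the allele labels of a synthetic cohort's affected newborns per
#' condition, for comparison against the configured spectrum.
#'
#' @param cohort output of [generate_cohort()].
#' @return tibble: `condition`, `label`, `count`, `freq`.
#' @export
observed_allele_spectrum <- function(cohort) {
  aff <- cohort[!is.na(cohort$true_condition), ]
  out <- lapply(split(aff$genotype, aff$true_condition), function(g) {
    tab <- table(unlist(g))
    tibble::tibble(label = names(tab), count = as.integer(tab),
                   freq = as.integer(tab) / sum(tab))
  })
  res <- do.call(rbind, out)
  res$condition <- rep(names(out), vapply(out, nrow, integer(1)))
  res[, c("condition", "label", "count", "freq")]
}
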