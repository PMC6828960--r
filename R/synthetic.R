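#' Default per-condition prevalences
#'
#' Per-condition birth prevalences of the 22 observed inborn errors of
#' metabolism, taken as the packaged case counts over the screened
#' denominator (401,660 newborns).
#'
#' @return named numeric vector of rates, one per condition.
#' @export
table_prevalences <- function() {
  tab <- utils::read.delim(system.file("extdata", "table3_spectrum.tsv",
                                       package = "nbscreen"),
                           check.names = FALSE)
  stats::setNames(tab$patients / 401660, tab$condition)
}

#' Condition categories (amino acid / organic acid / fatty acid disorders)
#'
#' @return named character vector mapping condition name to one of
#'   `"AAMD"`, `"OAMD"`, `"FAMD"`.
#' @export
condition_categories <- function() {
  tab <- utils::read.delim(system.file("extdata", "table3_spectrum.tsv",
                                       package = "nbscreen"),
                           check.names = FALSE)
  stats::setNames(tab$category, tab$condition)
}

#' Packaged cohort-characteristic counts
#'
#' The screened program's demographic strata (gender, gestational-age bands,
#' birth-weight bands, fetus number, register region, household registration)
#' with unaffected and patient counts, including explicit "No record" strata.
#'
#' @return tibble with columns `variable`, `stratum`, `unaffected`,
#'   `patients`.
#' @export
table_characteristics <- function() {
  tibble::as_tibble(utils::read.delim(
    system.file("extdata", "table2_characteristics.tsv", package = "nbscreen"),
    check.names = FALSE))
}

#' Demographic sampling margins
#'
#' Marginal stratum probabilities per demographic variable, derived from the
#' packaged characteristic counts (unaffected + patients, normalised within
#' each variable). "No record" is retained as an explicit missing category.
#'
#' @return named list of named probability vectors.
#' @export
demographic_margins <- function() {
  tab <- table_characteristics()
  out <- list()
  for (v in unique(tab$variable)) {
    sub <- tab[tab$variable == v, ]
    n <- sub$unaffected + sub$patients
    out[[v]] <- stats::setNames(n / sum(n), sub$stratum)
  }
  out
}

#' Reference analyte levels for unaffected newborns
#'
#' Geometric means (panel units) for every analyte of the packaged panel.
#' These are package-defined stand-ins placed so that every positive rule of
#' the packaged panel lies several log-SDs away from the unaffected core
#' distribution; they are not population reference ranges.
#'
#' @return named numeric vector of geometric means.
#' @export
analyte_reference <- function() {
  c(ALA = 250, ARG = 20, CIT = 12, GLY = 350, LEU = 110, ILE = 55,
    `PRO-OH` = 25, MET = 22, ORN = 80, PHE = 55, PRO = 180, TYR = 60,
    VAL = 120, SA = 0.5,
    C0 = 25, C2 = 25, C3 = 2, C4 = 0.18, C5 = 0.1, `C5:1` = 0.01,
    C6 = 0.04, C6DC = 0.05, C8 = 0.08, `C8:1` = 0.08, C10 = 0.1,
    `C10:1` = 0.08, `C10:2` = 0.03, C12 = 0.1, `C12:1` = 0.08, C14 = 0.15,
    `C14:1` = 0.1, `C14:2` = 0.03, `C14-OH` = 0.01, C16 = 3, `C16:1` = 0.3,
    `C16-OH` = 0.015, `C16:1-OH` = 0.01, C18 = 0.9, `C18:1` = 1.3,
    `C18:2` = 0.3, `C18-OH` = 0.01, `C18:1-OH` = 0.015, `C18:2-OH` = 0.01,
    `C3DC+C4-OH` = 0.12, `C4DC+C5-OH` = 0.18, `C5DC+C6-OH` = 0.08)
}

#' Marker shifts applied to affected newborns
#'
#' For each condition, the geometric-mean targets of the analytes its disease
#' process elevates (or depletes), chosen so the condition's screening group
#' fires its first positive rule with a wide margin: elevated markers sit at
#' 2.5x their rule-1 cut-off, depleted markers at 0.4x.
#'
#' @return named list: per condition, a named numeric vector of analyte
#'   geometric-mean targets.
#' @export
condition_marker_targets <- function() {
  list(
    "Phenylketonuria"                                   = c(PHE = 600),
    "Mild hyperphenylalaninemia"                        = c(PHE = 200),
    "Tetrahydrobiopterin deficiency"                    = c(PHE = 300),
    "Hypermethioninemia"                                = c(MET = 175),
    "Citrullinemia type I"                              = c(CIT = 125),
    "Citrullinemia type II"                             = c(CIT = 125),
    "Argininosuccinate aciduria"                        = c(CIT = 125),
    "Ornithine transcarbamylase deficiency"             = c(CIT = 2.2),
    "Tyrosinemia"                                       = c(TYR = 1000),
    "Maple syrup urine disease"                         = c(LEU = 575, ILE = 290, `PRO-OH` = 130),
    "3-Methylcrotonyl-CoA carboxylase deficiency"       = c(`C4DC+C5-OH` = 1.75),
    "Methylmalonic acidemia"                            = c(C3 = 18.75),
    "Propionic acidemia"                                = c(C3 = 18.75),
    "Isobutyryl coa dehydrogenase deficiency"           = c(C4 = 1.75),
    "Isovaleric acidemia"                               = c(C5 = 2),
    "2-Methylbutyrylglycinuria"                         = c(C5 = 2),
    "Malonic acidemia"                                  = c(`C3DC+C4-OH` = 2),
    "Primary carnitine uptake defect"                   = c(C0 = 3.8),
    "Short chain acyl-CoA dehydrogenase deficiency"     = c(C4 = 1.75),
    "Very long chain acyl-CoA dehydrogenase deficiency" = c(`C14:1` = 1.25),
    "Medium chain acyl-CoA dehydrogenase deficiency"    = c(C8 = 0.75),
    "Glutaric aciduria type I"                          = c(`C5DC+C6-OH` = 1)
  )
}

#' Condition to screening-group mapping
#'
#' Maps each diagnosable condition to the panel row its biochemical
#' signature fires (e.g. both citrullinemia types flag through elevated
#' citrulline on the ASA row).
#'
#' @return named character vector: condition -> group id of
#'   [builtin_panel()].
#' @export
condition_screen_group <- function() {
  c("Phenylketonuria"                                   = "PKU_MHPA_BH4",
    "Mild hyperphenylalaninemia"                        = "PKU_MHPA_BH4",
    "Tetrahydrobiopterin deficiency"                    = "PKU_MHPA_BH4",
    "Hypermethioninemia"                                = "HCY_HMET",
    "Citrullinemia type I"                              = "ASA",
    "Citrullinemia type II"                             = "ASA",
    "Argininosuccinate aciduria"                        = "ASA",
    "Ornithine transcarbamylase deficiency"             = "OTC",
    "Tyrosinemia"                                       = "H-TYR",
    "Maple syrup urine disease"                         = "MSUD",
    "3-Methylcrotonyl-CoA carboxylase deficiency"       = "3MCC_MCD_2M3HBA_3MGA_HMG",
    "Methylmalonic acidemia"                            = "MUT_PROP",
    "Propionic acidemia"                                = "MUT_PROP",
    "Isobutyryl coa dehydrogenase deficiency"           = "IBG_EMA",
    "Isovaleric acidemia"                               = "IVA_2MBG",
    "2-Methylbutyrylglycinuria"                         = "IVA_2MBG",
    "Malonic acidemia"                                  = "MAL",
    "Primary carnitine uptake defect"                   = "PCUD",
    "Short chain acyl-CoA dehydrogenase deficiency"     = "SCADD",
    "Very long chain acyl-CoA dehydrogenase deficiency" = "VLCADD",
    "Medium chain acyl-CoA dehydrogenase deficiency"    = "MCADD",
    "Glutaric aciduria type I"                          = "GA-I")
}

#' Assemble cohort-simulation parameters
#'
#' @param n_newborns cohort size.
#' @param seed integer master seed; every random stream is derived from it.
#' @param prevalences named per-condition rates (default
#'   [table_prevalences()]).
#' @param margins demographic margins (default [demographic_margins()]).
#' @param analyte_gm per-analyte geometric means (default
#'   [analyte_reference()]).
#' @param core_gsd geometric SD of the unaffected core component.
#' @param tail_gsd_mult multiplier on the log-SD for the inflated-variance
#'   (false-positive) mixture component.
#' @param fp_inflation mixture weight of the inflated component in `[0, 1)`;
#'   `NULL` until set, typically via [calibrate_fp_inflation()].
#' @param retest_attenuation fraction rho in `[0, 1]` by which an unaffected
#'   specimen's log-deviation regresses to the mean on recall; see
#'   [calibrate_retest_attenuation()].
#' @param affected_sensitivity probability an affected newborn expresses its
#'   biochemical phenotype (marker shift) at all.
#' @param dominant_single_prob probability a dominant-or-recessive condition
#'   carries a single allele.
#' @param marker_targets per-condition analyte targets (default
#'   [condition_marker_targets()]).
#' @return a list of class `nbs_cohort_params`.
#' @export
cohort_params <- function(n_newborns = 401660, seed = 1,
                          prevalences = table_prevalences(),
                          margins = demographic_margins(),
                          analyte_gm = analyte_reference(),
                          core_gsd = 1.12, tail_gsd_mult = 5,
                          fp_inflation = NULL, retest_attenuation = 0.5,
                          affected_sensitivity = 1,
                          dominant_single_prob = 12 / 13,
                          marker_targets = condition_marker_targets()) {
  p <- structure(list(
    n_newborns = as.integer(n_newborns), seed = as.integer(seed),
    prevalences = prevalences, margins = margins, analyte_gm = analyte_gm,
    core_gsd = core_gsd, tail_gsd_mult = tail_gsd_mult,
    fp_inflation = fp_inflation, retest_attenuation = retest_attenuation,
    affected_sensitivity = affected_sensitivity,
    dominant_single_prob = dominant_single_prob,
    marker_targets = marker_targets), class = "nbs_cohort_params")
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p, panel = NULL) {
  stopifnot(p$n_newborns >= 1)
  if (any(p$prevalences < 0 | p$prevalences >= 1))
    stop("prevalences must lie in [0, 1)", call. = FALSE)
  if (sum(p$prevalences) >= 1)
    stop("prevalences sum to >= 1", call. = FALSE)
  if (p$retest_attenuation < 0 || p$retest_attenuation > 1)
    stop("retest_attenuation must lie in [0, 1]", call. = FALSE)
  if (!is.null(p$fp_inflation) &&
      (p$fp_inflation < 0 || p$fp_inflation >= 1))
    stop("fp_inflation must lie in [0, 1)", call. = FALSE)
  for (m in p$margins) {
    if (abs(sum(m) - 1) > 1e-6)
      stop("demographic margins must sum to 1", call. = FALSE)
  }
  for (cond in names(p$prevalences)) {
    tg <- p$marker_targets[[cond]]
    if (is.null(tg))
      stop("no marker targets for condition: ", cond, call. = FALSE)
    bad <- setdiff(names(tg), names(p$analyte_gm))
    if (length(bad) > 0)
      stop("marker target references unknown analyte(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Packaged allele spectra per condition
#'
#' Relative allele frequencies derived from the packaged variant table
#' (detected alleles plus "undetectable" placeholder mass), split by gene for
#' the combined citrullinemia block. Hypermethioninemia is flagged
#' dominant-or-recessive; all other conditions are autosomal recessive.
#'
#' @return named list per condition with `alleles` (tibble: `label`, `freq`)
#'   and `inheritance`.
#' @export
builtin_allele_spectra <- function() {
  # the packaged table is known to carry footnoted blocks whose allele totals
  # exceed 2 per patient; the loader already flags that for external tables
  v <- suppressWarnings(load_variant_table())
  pick <- function(cond, genes = NULL) {
    sub <- v[v$condition == cond, ]
    if (!is.null(genes)) sub <- sub[sub$gene %in% genes, ]
    label <- ifelse(sub$cdna == "undetectable", "undetectable",
                    paste0(sub$gene, ":", sub$cdna))
    tibble::tibble(label = label, freq = sub$alleles / sum(sub$alleles))
  }
  conds <- names(table_prevalences())
  out <- lapply(conds, function(cond) {
    src <- switch(cond,
      "Citrullinemia type II" = pick("Citrullinemia", c("SLC25A13", "")),
      "Citrullinemia type I"  = pick("Citrullinemia", "ASS1"),
      "Glutaric aciduria type I" = pick("Glutaric aciduria I"),
      pick(cond))
    list(condition = cond, alleles = src,
         inheritance = if (cond == "Hypermethioninemia")
           "dominant_or_recessive" else "recessive")
  })
  stats::setNames(out, conds)
}

#' Draw genotypes from an allele spectrum
#'
#' Recessive conditions draw two independent alleles; dominant-or-recessive
#' conditions draw a single allele with probability `dominant_single_prob`.
#'
#' @param condition condition name (for error messages).
#' @param spectrum one element of [builtin_allele_spectra()].
#' @param n number of genotypes to draw.
#' @param dominant_single_prob single-allele probability for
#'   dominant-or-recessive inheritance.
#' @return list of character vectors of allele labels (length 1 or 2).
#' @export
generate_genotype <- function(condition, spectrum, n = 1,
                              dominant_single_prob = 12 / 13) {
  if (is.null(spectrum)) stop("missing allele spectrum for ", condition)
  labs <- spectrum$alleles$label
  pr <- spectrum$alleles$freq
  draw <- function(k) sample(labs, k, replace = TRUE, prob = pr)
  lapply(seq_len(n), function(i) {
    if (spectrum$inheritance == "dominant_or_recessive" &&
        stats::runif(1) < dominant_single_prob) draw(1) else draw(2)
  })
}

#' Generate a synthetic newborn cohort
#'
#' Disease states are independent Bernoulli draws at the configured
#' prevalences (at most one condition per newborn); demographics are sampled
#' from the marginal proportions independently of disease state. Affected
#' newborns receive genotypes from the packaged allele spectra; unaffected
#' newborns carry none. Reproducible given `params$seed`.
#'
#' @param params an [cohort_params()] object.
#' @param spectra allele spectra (default [builtin_allele_spectra()]).
#' @return tibble with one row per newborn: identifiers, demographic strata,
#'   `age_at_initial_testing_days`, `true_condition` (`NA` for unaffected)
#'   and a `genotype` list-column.
#' @export
generate_cohort <- function(params, spectra = builtin_allele_spectra()) {
  validate_cohort_params(params)
  n <- params$n_newborns
  with_seed(child_seed(params$seed, 1), {
    prev <- params$prevalences
    cond_draw <- sample(c(names(prev), NA_character_), n, replace = TRUE,
                        prob = c(prev, 1 - sum(prev)))
    demo <- lapply(params$margins, function(m)
      sample(names(m), n, replace = TRUE, prob = m))
    # age at initial testing: log-normal matched to mean 7.35, SD 8.14 days
    m <- 7.35; s <- 8.14
    sdlog <- sqrt(log(1 + s^2 / m^2))
    meanlog <- log(m) - sdlog^2 / 2
    age <- pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
    genotype <- vector("list", n)
    for (cond in names(prev)) {
      idx <- which(!is.na(cond_draw) & cond_draw == cond)
      if (length(idx) > 0)
        genotype[idx] <- generate_genotype(cond, spectra[[cond]], length(idx),
                                           params$dominant_single_prob)
    }
    tibble::tibble(
      newborn_id = sprintf("NB%07d", seq_len(n)),
      gender = demo$gender,
      gestational_age_band = demo$gestational_age,
      birth_weight_band = demo$birth_weight,
      fetus_number = demo$fetus_number,
      register_region = demo$register_region,
      household_registration = demo$household_registration,
      age_at_initial_testing_days = age,
      true_condition = cond_draw,
      genotype = genotype)
  })
}

# Log-scale geometric-mean matrix for a cohort: baseline reference values,
# with each affected (and phenotype-expressing) newborn's target analytes
# overridden by its condition's marker targets.
cohort_logmu <- function(cohort, params, shifted) {
  codes <- names(params$analyte_gm)
  n <- nrow(cohort)
  logmu <- matrix(rep(log(params$analyte_gm), each = n), n,
                  dimnames = list(NULL, codes))
  for (cond in names(params$marker_targets)) {
    idx <- which(shifted & !is.na(cohort$true_condition) &
                   cohort$true_condition == cond)
    if (length(idx) == 0) next
    tg <- params$marker_targets[[cond]]
    logmu[idx, names(tg)] <- rep(log(tg), each = length(idx))
  }
  logmu
}

#' Generate initial-tier metabolite profiles for a cohort
#'
#' Unaffected newborns draw every analyte from a two-component log-normal
#' mixture: a core component (`core_gsd`) and, with probability
#' `fp_inflation`, an inflated-variance component (`core_gsd^tail_gsd_mult`
#' on the log scale) that produces the program's false-positive load.
#' Affected newborns draw their condition's target analytes around the
#' shifted geometric means (core noise), unless the phenotype is suppressed
#' (`affected_sensitivity < 1`).
#'
#' @param cohort output of [generate_cohort()].
#' @param params an [cohort_params()] with non-`NULL` `fp_inflation`.
#' @param panel screening panel (analyte set must cover `params$analyte_gm`).
#' @return a list of class `nbs_profiles`: `values` (matrix, columns are
#'   analyte codes), `meta` (tibble: `newborn_id`, `tail`, `shifted`), and
#'   `tier = "initial"`.
#' @export
generate_profiles <- function(cohort, params, panel = builtin_panel()) {
  validate_cohort_params(params)
  if (is.null(params$fp_inflation))
    stop("fp_inflation is unset; call calibrate_fp_inflation() first",
         call. = FALSE)
  n <- nrow(cohort)
  codes <- names(params$analyte_gm)
  uncovered <- setdiff(panel_analyte_codes(panel), codes)
  if (length(uncovered) > 0)
    stop("no reference level for panel analyte(s): ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  with_seed(child_seed(params$seed, 2), {
    affected <- !is.na(cohort$true_condition)
    shifted <- affected & stats::runif(n) < params$affected_sensitivity
    # inflated-variance mixture applies to specimens without a biochemical
    # phenotype; an expressed phenotype dominates any assay excursion
    tail <- !shifted & stats::runif(n) < params$fp_inflation
    sd0 <- log(params$core_gsd)
    sdv <- ifelse(tail, sd0 * params$tail_gsd_mult, sd0)
    logmu <- cohort_logmu(cohort, params, shifted)
    z <- matrix(stats::rnorm(n * length(codes)), n)
    values <- exp(logmu + sdv * z)
    colnames(values) <- codes
    structure(list(values = values,
                   meta = tibble::tibble(newborn_id = cohort$newborn_id,
                                         tail = tail, shifted = shifted),
                   tier = "initial"),
              class = "nbs_profiles")
  })
}

#' Generate recall-tier profiles for a subset of newborns
#'
#' On recall, an unaffected specimen's log-deviation from its geometric mean
#' regresses toward zero by the attenuation fraction rho
#' (`retest_attenuation`) and fresh core measurement noise is added; an
#' affected newborn's marker shift persists (its deviation is measured from
#' the shifted mean, so only assay noise regresses).
#'
#' @param initial an `nbs_profiles` object from [generate_profiles()].
#' @param idx integer indices (rows of the cohort) to recall.
#' @param cohort the cohort used for `initial`.
#' @param params the same [cohort_params()].
#' @return an `nbs_profiles` list with `values` for `idx` rows and
#'   `tier = "recall"`.
#' @export
generate_recall_profiles <- function(initial, idx, cohort, params) {
  stopifnot(inherits(initial, "nbs_profiles"), initial$tier == "initial")
  rho <- params$retest_attenuation
  codes <- colnames(initial$values)
  with_seed(child_seed(params$seed, 3), {
    sub <- cohort[idx, , drop = FALSE]
    logmu <- cohort_logmu(sub, params, initial$meta$shifted[idx])
    dev <- log(initial$values[idx, , drop = FALSE]) - logmu
    sd0 <- log(params$core_gsd)
    z <- matrix(stats::rnorm(length(dev)), nrow(dev))
    values <- exp(logmu + (1 - rho) * dev + sd0 * z)
    colnames(values) <- codes
    structure(list(values = values,
                   meta = tibble::tibble(newborn_id = sub$newborn_id,
                                         tail = initial$meta$tail[idx],
                                         shifted = initial$meta$shifted[idx]),
                   idx = idx, tier = "recall"),
              class = "nbs_profiles")
  })
}

#' Calibrate the false-positive mixture weight to a target recall rate
#'
#' Estimates, by pilot simulation, the screen-positive probability of the
#' core and inflated-variance components of the unaffected mixture, and
#' solves the mixture weight so that the unaffected initial-positive rate
#' equals `target_rate` (the screening program's recall rate).
#'
#' @param params an [cohort_params()]; its `fp_inflation` is ignored.
#' @param panel screening panel.
#' @param target_rate target initial-positive rate among unaffected
#'   newborns.
#' @param n_pilot pilot specimens simulated per component.
#' @param seed RNG seed for the pilot.
#' @return the calibrated mixture weight (numeric scalar in `[0, 1)`).
#' @export
calibrate_fp_inflation <- function(params, panel = builtin_panel(),
                                   target_rate = 0.028, n_pilot = 100000,
                                   seed = params$seed) {
  codes <- names(params$analyte_gm)
  sd0 <- log(params$core_gsd)
  rate_at <- function(sdv, s) with_seed(child_seed(s, 11), {
    z <- matrix(stats::rnorm(n_pilot * length(codes)), n_pilot)
    v <- exp(matrix(rep(log(params$analyte_gm), each = n_pilot), n_pilot) + sdv * z)
    colnames(v) <- codes
    mean(screen_profiles(v, panel)$any_positive)
  })
  base <- rate_at(sd0, seed)
  tail <- rate_at(sd0 * params$tail_gsd_mult, seed + 1)
  if (tail <= target_rate)
    stop("inflated component fires too rarely to reach the target rate",
         call. = FALSE)
  w <- (target_rate - base) / (tail - base)
  max(0, min(w, 1 - 1e-9))
}

#' Calibrate recall regression-to-mean to a target retest-positive rate
#'
#' Finds, by bisection over pilot simulations, the attenuation fraction rho
#' such that an unaffected newborn that screened positive on the initial
#' specimen re-fires on the recall specimen with probability
#' `target_refire`.
#'
#' @param params an [cohort_params()] with calibrated `fp_inflation`.
#' @param panel screening panel.
#' @param target_refire target P(recall positive | initial false positive).
#' @param n_pilot pilot false-positive candidates simulated.
#' @param seed RNG seed.
#' @return calibrated rho in `[0, 1]`.
#' @export
calibrate_retest_attenuation <- function(params, panel = builtin_panel(),
                                         target_refire = 0.0552,
                                         n_pilot = 60000,
                                         seed = params$seed) {
  codes <- names(params$analyte_gm)
  sd0 <- log(params$core_gsd)
  sdt <- sd0 * params$tail_gsd_mult
  with_seed(child_seed(seed, 12), {
    logmu <- matrix(rep(log(params$analyte_gm), each = n_pilot), n_pilot)
    z <- matrix(stats::rnorm(n_pilot * length(codes)), n_pilot)
    v1 <- exp(logmu + sdt * z)
    colnames(v1) <- codes
    fired <- screen_profiles(v1, panel)$any_positive
    dev <- (sdt * z)[fired, , drop = FALSE]
    mu <- logmu[fired, , drop = FALSE]
    z2 <- matrix(stats::rnorm(length(dev)), nrow(dev))
    refire_at <- function(rho) {
      v2 <- exp(mu + (1 - rho) * dev + sd0 * z2)
      colnames(v2) <- codes
      mean(screen_profiles(v2, panel)$any_positive)
    }
    lo <- 0; hi <- 1
    if (refire_at(0) <= target_refire) return(0)
    for (i in 1:25) {
      mid <- (lo + hi) / 2
      if (refire_at(mid) > target_refire) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
}
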