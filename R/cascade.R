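#' Cascade compliance parameters
#'
#' Stage-compliance probabilities of the two-tier screening workflow. The
#' defaults reproduce the program's printed compliance: 94.30% of initial
#' positives provided a second specimen and 98.36% of suspect positives
#' attended diagnostic testing; confirmation of a referred true case is
#' assumed certain, and 138/153 of diagnosed patients undergo sequencing.
#'
#' @param p_recall_compliance probability a flagged newborn provides a second
#'   specimen.
#' @param p_referral_compliance probability a suspect positive attends
#'   diagnostic testing.
#' @param p_diagnosis_given_referral per-condition (or scalar) probability a
#'   referred true case is confirmed.
#' @param p_sequenced probability a diagnosed patient is referred to genetic
#'   analysis.
#' @return a list of class `nbs_cascade_params`.
#' @export
cascade_params <- function(p_recall_compliance = 10606 / 11247,
                           p_referral_compliance = 720 / 732,
                           p_diagnosis_given_referral = 1,
                           p_sequenced = 138 / 153) {
  p <- list(p_recall_compliance = p_recall_compliance,
            p_referral_compliance = p_referral_compliance,
            p_diagnosis_given_referral = p_diagnosis_given_referral,
            p_sequenced = p_sequenced)
  bad <- unlist(p) < 0 | unlist(p) > 1
  if (any(bad)) stop("compliance probabilities must lie in [0, 1]")
  structure(p, class = "nbs_cascade_params")
}

#' Run the two-tier screening cascade over a synthetic cohort
#'
#' Initial positivity comes from screening the initial-tier profiles;
#' recall, referral and sequencing compliance are Bernoulli; second-tier
#' positivity comes from screening freshly generated recall profiles
#' (regression to the mean for unaffected deviations, persistent marker
#' shifts for affected newborns). Referred true cases are confirmed with the
#' configured per-condition probability; unaffected newborns are never
#' falsely diagnosed.
#'
#' @param cohort output of [generate_cohort()].
#' @param params an [cohort_params()] with calibrated `fp_inflation`.
#' @param cparams an [cascade_params()].
#' @param panel screening panel.
#' @return tibble with one row per newborn: `newborn_id`, `true_condition`,
#'   `initial_positive`, `recalled`, `second_specimen`, `second_positive`,
#'   `referred`, `diagnosed_condition`, `sequenced`, and the initial and
#'   recall phenylalanine readings (`phe_initial`, `phe_recall`) for
#'   downstream hyperphenylalaninemia subtyping.
#' @export
run_cascade <- function(cohort, params, cparams = cascade_params(),
                        panel = builtin_panel()) {
  n <- nrow(cohort)
  initial <- generate_profiles(cohort, params, panel)
  scr1 <- screen_profiles(initial$values, panel)
  initial_positive <- scr1$any_positive

  with_seed(child_seed(params$seed, 4), {
    recalled <- initial_positive
    second_specimen <- recalled &
      stats::runif(n) < cparams$p_recall_compliance

    second_positive <- rep(FALSE, n)
    phe_recall <- rep(NA_real_, n)
    idx <- which(second_specimen)
    if (length(idx) > 0) {
      recall <- generate_recall_profiles(initial, idx, cohort, params)
      scr2 <- screen_profiles(recall$values, panel)
      second_positive[idx] <- scr2$any_positive
      phe_recall[idx] <- recall$values[, "PHE"]
    }

    referred <- second_positive &
      stats::runif(n) < cparams$p_referral_compliance

    p_diag <- cparams$p_diagnosis_given_referral
    affected <- !is.na(cohort$true_condition)
    p_i <- rep(0, n)
    p_i[affected] <- if (length(p_diag) == 1) p_diag else
      p_diag[cohort$true_condition[affected]]
    diagnosed <- referred & affected & stats::runif(n) < p_i
    diagnosed_condition <- ifelse(diagnosed, cohort$true_condition,
                                  NA_character_)
    sequenced <- diagnosed & stats::runif(n) < cparams$p_sequenced

    tibble::tibble(
      newborn_id = cohort$newborn_id,
      true_condition = cohort$true_condition,
      initial_positive = initial_positive,
      recalled = recalled,
      second_specimen = second_specimen,
      second_positive = second_positive,
      referred = referred,
      diagnosed_condition = diagnosed_condition,
      sequenced = sequenced,
      phe_initial = initial$values[, "PHE"],
      phe_recall = phe_recall)
  })
}

check_cascade_monotone <- function(records) {
  diagnosed <- !is.na(records$diagnosed_condition)
  ok <- all(records$recalled <= records$initial_positive) &&
    all(records$second_specimen <= records$recalled) &&
    all(records$second_positive <= records$second_specimen) &&
    all(records$referred <= records$second_positive) &&
    all(diagnosed <= records$referred) &&
    all(records$sequenced <= diagnosed)
  if (!ok) stop("cascade stage flags violate monotonicity", call. = FALSE)
  invisible(TRUE)
}

#' Summarise a screening cascade
#'
#' Stage counts and the program-level rates, each over its immediate parent
#' stage: recall rate over all screened, recollection rate over initial
#' positives, suspect rate over second specimens, referral rate over suspect
#' positives. Rates are percentages rounded half away from zero to 2
#' decimals; a rate with an empty parent stage is `NA`.
#'
#' @param records output of [run_cascade()], or any tibble with the stage
#'   flag columns (monotonicity is enforced).
#' @return a list of class `nbs_cascade_summary` with the six counts and
#'   four rates.
#' @export
summarize_cascade <- function(records) {
  check_cascade_monotone(records)
  n <- nrow(records)
  counts <- list(
    n_screened = n,
    n_initial_positive = sum(records$initial_positive),
    n_second_specimen = sum(records$second_specimen),
    n_suspect_positive = sum(records$second_positive),
    n_referred = sum(records$referred),
    n_diagnosed = sum(!is.na(records$diagnosed_condition)))
  rate <- function(num, den) if (den == 0) NA_real_ else
    round_half_away(100 * num / den, 2)
  structure(c(counts, list(
    recall_rate = rate(counts$n_initial_positive, counts$n_screened),
    recollection_rate = rate(counts$n_second_specimen,
                             counts$n_initial_positive),
    suspect_rate = rate(counts$n_suspect_positive,
                        counts$n_second_specimen),
    referral_rate = rate(counts$n_referred, counts$n_suspect_positive))),
    class = "nbs_cascade_summary")
}

#' Build cascade stage records from printed program counts
#'
#' Convenience constructor for recomputing program-level rates from reported
#' stage totals (e.g. screened / initial positive / second specimen /
#' suspect positive / referred), without per-newborn data.
#'
#' @param n_screened,n_initial_positive,n_second_specimen
#'   stage totals, each no larger than its parent stage.
#' @param n_suspect_positive,n_referred,n_diagnosed later stage totals.
#' @return tibble of minimal per-newborn stage flags reproducing the counts.
#' @export
cascade_records_from_counts <- function(n_screened, n_initial_positive,
                                        n_second_specimen,
                                        n_suspect_positive, n_referred,
                                        n_diagnosed = 0) {
  counts <- c(n_screened, n_initial_positive, n_second_specimen,
              n_suspect_positive, n_referred, n_diagnosed)
  if (any(diff(counts[1:5]) > 0) || n_diagnosed > n_referred)
    stop("stage counts must be non-increasing along the cascade")
  flag <- function(k) seq_len(n_screened) <= k
  tibble::tibble(
    newborn_id = sprintf("NB%07d", seq_len(n_screened)),
    true_condition = NA_character_,
    initial_positive = flag(n_initial_positive),
    recalled = flag(n_initial_positive),
    second_specimen = flag(n_second_specimen),
    second_positive = flag(n_suspect_positive),
    referred = flag(n_referred),
    diagnosed_condition = ifelse(flag(n_diagnosed), "diagnosed",
                                 NA_character_),
    sequenced = FALSE)
}

#' @export
print.nbs_cascade_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<cascade: %d screened, %d initial positive (%.2f%%), ",
    "%d second specimens (%.2f%%), %d suspect positive (%.2f%%), ",
    "%d referred (%.2f%%), %d diagnosed>\n"),
    x$n_screened, x$n_initial_positive, x$recall_rate,
    x$n_second_specimen, x$recollection_rate,
    x$n_suspect_positive, x$suspect_rate,
    x$n_referred, x$referral_rate, x$n_diagnosed))
  invisible(x)
}
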