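#' Binomial rate confidence intervals
#'
#' Three selectable 95% (by default) interval methods for a rare-event rate
#' `k / n`, implemented from their defining equations:
#' \describe{
#'   \item{wilson}{score interval: inverts the normal test on the score
#'     scale, `(p + z^2/2n +/- z * sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)`.}
#'   \item{clopper_pearson}{exact interval from the beta quantiles
#'     `qbeta(a/2; k, n-k+1)` and `qbeta(1-a/2; k+1, n-k)`.}
#'   \item{poisson_exact}{treats `k` as Poisson (rare-event limit); gamma
#'     quantile bounds divided by `n`, upper bound capped at 1.}
#' }
#'
#' @param k number of cases, `0 <= k <= n`.
#' @param n number screened, `> 0`.
#' @param method one of `"wilson"`, `"clopper_pearson"`, `"poisson_exact"`.
#' @param conf confidence level.
#' @return numeric `c(rate_low, rate_high)` with
#'   `0 <= rate_low <= k/n <= rate_high <= 1`.
#' @export
ci_rate <- function(k, n, method = c("clopper_pearson", "wilson",
                                     "poisson_exact"), conf = 0.95) {
  method <- match.arg(method)
  stopifnot(n > 0, k >= 0, k <= n)
  a <- 1 - conf
  if (method == "wilson") {
    z <- stats::qnorm(1 - a / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lims <- c(centre - half, centre + half)
  } else if (method == "clopper_pearson") {
    lo <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
    hi <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
    lims <- c(lo, hi)
  } else {
    lo <- if (k == 0) 0 else stats::qgamma(a / 2, k) / n
    hi <- stats::qgamma(1 - a / 2, k + 1) / n
    lims <- c(lo, min(hi, 1))
  }
  pmin(pmax(lims, 0), 1)
}

#' Estimate a 1-in-X incidence with confidence interval
#'
#' The point estimate is reported in the screening literature's `1/X` form
#' with `X = round(n / k)` (half away from zero). The interval is computed
#' on the rate scale by the selected method and transformed to the same
#' `1/X` form, rarer bound first. With zero cases the point estimate is
#' undefined and only the upper rate bound is reported.
#'
#' @param k case count.
#' @param n screened count; errors if `k > n`.
#' @param ci_method passed to [ci_rate()].
#' @param condition optional condition label.
#' @return a list of class `nbs_incidence`: `condition`, `k`, `n`, `one_in`,
#'   `ci_method`, `rate_low`, `rate_high`, `ci_one_in`
#'   (`c(rarer, commoner)` denominators).
#' @examples
#' incidence_estimate(15, 401660)$one_in   # 26777
#' @export
incidence_estimate <- function(k, n, ci_method = "clopper_pearson",
                               condition = NA_character_) {
  stopifnot(n > 0, k >= 0)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  ci <- ci_rate(k, n, ci_method)
  one_in <- if (k >= 1) round_half_away(n / k) else NA_real_
  ci_one_in <- c(
    rarer = if (ci[1] > 0) round_half_away(1 / ci[1]) else Inf,
    commoner = round_half_away(1 / ci[2]))
  structure(list(condition = condition, k = k, n = n, one_in = one_in,
                 ci_method = ci_method, rate_low = ci[1], rate_high = ci[2],
                 ci_one_in = ci_one_in),
            class = "nbs_incidence")
}

#' @export
print.nbs_incidence <- function(x, ...) {
  est <- if (is.na(x$one_in)) "undefined (0 cases)" else
    sprintf("1/%s", format(x$one_in, big.mark = ","))
  cat(sprintf("<incidence %s: %d/%d = %s (95%% CI 1/%s-1/%s, %s)>\n",
              x$condition, x$k, x$n, est,
              format(x$ci_one_in[["rarer"]], big.mark = ","),
              format(x$ci_one_in[["commoner"]], big.mark = ","),
              x$ci_method))
  invisible(x)
}

#' Disease-spectrum summary
#'
#' Per-category and per-condition patient counts, percentage shares of all
#' patients, and 1-in-X incidence estimates.
#'
#' @param diagnoses tibble/data.frame with columns `patient_id`, `condition`
#'   and optionally `category`; when `category` is absent every condition
#'   must be mapped by `categories`.
#' @param n_screened screened denominator for the incidence estimates.
#' @param categories named map condition -> category (default
#'   [condition_categories()]).
#' @param ci_method passed to [incidence_estimate()].
#' @param percent_digits decimals for percentage shares.
#' @return a list of class `nbs_spectrum`: `n_patients`, `categories` and
#'   `conditions` tibbles with `count`, `percent`, `one_in`.
#' @export
spectrum_summary <- function(diagnoses, n_screened,
                             categories = condition_categories(),
                             ci_method = "clopper_pearson",
                             percent_digits = 2) {
  if (!"category" %in% names(diagnoses)) {
    unmapped <- setdiff(unique(diagnoses$condition), names(categories))
    if (length(unmapped) > 0)
      stop("condition(s) without category mapping: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    diagnoses$category <- categories[diagnoses$condition]
  }
  total <- nrow(diagnoses)
  summarise_by <- function(key) {
    counts <- table(diagnoses[[key]])
    tb <- tibble::tibble(
      level = names(counts),
      count = as.integer(counts),
      percent = round_half_away(100 * as.integer(counts) / total,
                                percent_digits))
    names(tb)[1] <- key
    tb$one_in <- vapply(tb$count, function(k)
      incidence_estimate(k, n_screened, ci_method)$one_in, numeric(1))
    tb[order(-tb$count), ]
  }
  structure(list(n_patients = total,
                 categories = summarise_by("category"),
                 conditions = summarise_by("condition")),
            class = "nbs_spectrum")
}

#' Compare cohort characteristics between unaffected newborns and patients
#'
#' Pearson chi-square tests (no continuity correction) on each categorical
#' variable's strata x \{unaffected, patients\} table, after dropping
#' "No record" strata and any stratum with no newborns at all. P-values are
#' additionally reported rounded to 3 decimals, matching program-report
#' style.
#'
#' @param counts tibble with columns `variable`, `stratum`, `unaffected`,
#'   `patients` (default: the packaged program counts).
#' @param drop_strata stratum labels excluded before testing.
#' @return tibble: `variable`, `statistic`, `df`, `p_value`, `p_rounded`.
#' @export
compare_groups <- function(counts = table_characteristics(),
                           drop_strata = "No record") {
  out <- lapply(unique(counts$variable), function(v) {
    sub <- counts[counts$variable == v & !(counts$stratum %in% drop_strata), ]
    sub <- sub[sub$unaffected + sub$patients > 0, ]
    if (nrow(sub) < 2)
      stop("variable '", v, "' has fewer than 2 strata after exclusions",
           call. = FALSE)
    m <- as.matrix(sub[, c("unaffected", "patients")])
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    tibble::tibble(variable = v,
                   statistic = unname(ct$statistic),
                   df = unname(ct$parameter),
                   p_value = ct$p.value,
                   p_rounded = round_half_away(ct$p.value, 3))
  })
  do.call(rbind, out)
}

#' One-way analysis of variance for a continuous characteristic
#'
#' @param values numeric vector (e.g. age at initial testing in days).
#' @param group factor/character of group membership (unaffected / patient).
#' @return tibble: `statistic` (F), `df1`, `df2`, `p_value`, `p_rounded`.
#' @export
compare_continuous <- function(values, group) {
  fit <- stats::anova(stats::lm(values ~ factor(group)))
  tibble::tibble(statistic = fit$`F value`[1],
                 df1 = fit$Df[1], df2 = fit$Df[2],
                 p_value = fit$`Pr(>F)`[1],
                 p_rounded = round_half_away(fit$`Pr(>F)`[1], 3))
}
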