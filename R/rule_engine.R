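#' Construct a metabolite profile for one specimen
#'
#' @param values named numeric vector of analyte concentrations (panel units);
#'   names are analyte codes. Values must be non-negative; analytes absent
#'   from the vector are treated as missing.
#' @param specimen_id,newborn_id identifiers.
#' @param collection_day integer days after birth at collection.
#' @param tier `"initial"` or `"recall"`.
#' @return a list of class `nbs_profile`.
#' @export
metabolite_profile <- function(values, specimen_id = "specimen",
                               newborn_id = specimen_id, collection_day = 3L,
                               tier = c("initial", "recall")) {
  tier <- match.arg(tier)
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (any(values < 0, na.rm = TRUE)) stop("analyte values must be non-negative")
  structure(list(specimen_id = specimen_id, newborn_id = newborn_id,
                 collection_day = as.integer(collection_day), tier = tier,
                 values = values),
            class = "nbs_profile")
}

profile_values <- function(profile) {
  if (inherits(profile, "nbs_profile")) profile$values else profile
}

#' Evaluate an analyte or derived marker on a profile
#'
#' Sums are sums of member analytes; ratios are numerator-sum /
#' denominator-sum. The value is `NA` (undefined) when any member analyte is
#' missing or a ratio's denominator sum is zero.
#'
#' @param profile an `nbs_profile` or named numeric vector.
#' @param marker analyte code or derived-marker name; must resolve in `panel`.
#' @param panel an `nbs_panel`.
#' @return numeric value, or `NA` when undefined.
#' @export
eval_marker <- function(profile, marker, panel = builtin_panel()) {
  vals <- profile_values(profile)
  codes <- panel_analyte_codes(panel)
  if (marker %in% codes) {
    return(if (marker %in% names(vals)) unname(vals[[marker]]) else NA_real_)
  }
  dm_names <- vapply(panel$derived_markers, function(m) m$name, character(1))
  i <- match(marker, dm_names)
  if (is.na(i)) stop("unknown marker: ", marker, call. = FALSE)
  m <- panel$derived_markers[[i]]
  if (!all(m$numerator %in% names(vals))) return(NA_real_)
  num <- sum(vals[m$numerator])
  if (length(m$denominator) == 0) return(unname(num))
  if (!all(m$denominator %in% names(vals))) return(NA_real_)
  den <- sum(vals[m$denominator])
  if (is.na(den) || den == 0) return(NA_real_)
  unname(num / den)
}

apply_op <- function(x, op, threshold) {
  out <- switch(op,
                ">"  = x > threshold,
                ">=" = x >= threshold,
                "<"  = x < threshold,
                "<=" = x <= threshold,
                stop("invalid operator: ", op))
  out[is.na(out)] <- FALSE   # undefined markers never satisfy a cut-off
  out
}

#' Evaluate one positive rule on a profile
#'
#' True iff every comparison in the rule holds. Comparisons on undefined
#' markers (missing analyte, zero denominator) evaluate to `FALSE`; cut-offs
#' are applied exactly as printed, so a value equal to a strict cut-off is
#' negative.
#'
#' @param profile an `nbs_profile` or named numeric vector.
#' @param rule an `nbs_rule`.
#' @param panel an `nbs_panel`.
#' @return logical scalar.
#' @export
eval_rule <- function(profile, rule, panel = builtin_panel()) {
  for (cmp in rule$comparisons) {
    v <- eval_marker(profile, cmp$marker, panel)
    if (!apply_op(v, cmp$op, cmp$threshold)) return(FALSE)
  }
  TRUE
}

# Build the n x marker matrix of analyte + derived-marker values for a
# numeric matrix / data.frame of profiles (columns named by analyte code).
# Missing analytes become NA columns (with one warning).
marker_matrix <- function(values, panel) {
  if (is.data.frame(values)) {
    values <- as.matrix(values[, sapply(values, is.numeric), drop = FALSE])
  }
  codes <- panel_analyte_codes(panel)
  missing <- setdiff(codes, colnames(values))
  if (length(missing) > 0) {
    warning("profiles are missing analyte(s): ", paste(missing, collapse = ", "),
            "; affected comparisons evaluate FALSE", call. = FALSE)
  }
  n <- nrow(values)
  M <- matrix(NA_real_, n, length(codes), dimnames = list(NULL, codes))
  present <- intersect(codes, colnames(values))
  M[, present] <- values[, present]
  for (m in panel$derived_markers) {
    num <- rowSums(M[, m$numerator, drop = FALSE])
    if (length(m$denominator) == 0) {
      v <- num
    } else {
      den <- rowSums(M[, m$denominator, drop = FALSE])
      v <- num / den
      v[!is.na(den) & den == 0] <- NA_real_
    }
    M <- cbind(M, v)
    colnames(M)[ncol(M)] <- m$name
  }
  M
}

#' Screen many profiles against a panel (vectorised)
#'
#' @param values numeric matrix or data.frame, one row per specimen, columns
#'   named by analyte code.
#' @param panel an `nbs_panel`.
#' @param detail if `TRUE`, also return the per-rule firing matrices.
#' @return a list with `positive` (n x groups logical matrix, columns are
#'   group ids), `any_positive` (logical vector), and when `detail = TRUE`
#'   `fired` (list per group of n x rules logical matrices).
#' @export
screen_profiles <- function(values, panel = builtin_panel(), detail = FALSE) {
  M <- marker_matrix(values, panel)
  n <- nrow(M)
  gids <- vapply(panel$groups, function(g) g$group_id, character(1))
  positive <- matrix(FALSE, n, length(gids), dimnames = list(NULL, gids))
  fired <- if (detail) stats::setNames(vector("list", length(gids)), gids)
  for (gi in seq_along(panel$groups)) {
    g <- panel$groups[[gi]]
    rule_hits <- matrix(FALSE, n, length(g$rules))
    for (ri in seq_along(g$rules)) {
      hit <- rep(TRUE, n)
      for (cmp in g$rules[[ri]]$comparisons) {
        hit <- hit & apply_op(M[, cmp$marker], cmp$op, cmp$threshold)
      }
      rule_hits[, ri] <- hit
    }
    positive[, gi] <- rowSums(rule_hits) > 0
    if (detail) fired[[gi]] <- rule_hits
  }
  out <- list(positive = positive, any_positive = rowSums(positive) > 0)
  if (detail) out$fired <- fired
  out
}

#' Screen a single profile against a panel
#'
#' @param profile an `nbs_profile` or named numeric vector of analyte values.
#' @param panel an `nbs_panel`.
#' @return a list of class `nbs_screen_result` with `specimen_id`, `flags`
#'   (per group id: `positive` and integer `fired_rules`), and
#'   `derived_values` (every marker referenced by any rule).
#' @examples
#' res <- screen_profile(c(PHE = 150, TYR = 50))
#' res$flags[["PKU_MHPA_BH4"]]
#' @export
screen_profile <- function(profile, panel = builtin_panel()) {
  vals <- profile_values(profile)
  row <- matrix(vals, 1, dimnames = list(NULL, names(vals)))
  res <- screen_profiles(row, panel, detail = TRUE)
  M <- suppressWarnings(marker_matrix(row, panel))
  used <- unique(panel_comparisons(panel)$marker)
  flags <- lapply(seq_along(panel$groups), function(gi) {
    hits <- which(res$fired[[gi]][1, ])
    list(positive = res$positive[1, gi], fired_rules = as.integer(hits))
  })
  names(flags) <- colnames(res$positive)
  structure(list(
    specimen_id = if (inherits(profile, "nbs_profile")) profile$specimen_id else "specimen",
    flags = flags,
    derived_values = stats::setNames(as.numeric(M[1, used]), used)
  ), class = "nbs_screen_result")
}

#' @export
print.nbs_screen_result <- function(x, ...) {
  pos <- names(Filter(function(f) f$positive, x$flags))
  cat(sprintf("<screen result '%s': %s>\n", x$specimen_id,
              if (length(pos) == 0) "negative" else paste(pos, collapse = ", ")))
  invisible(x)
}

#' Subtype hyperphenylalaninemia by blood phenylalanine
#'
#' Classical PKU is defined by Phe at or above 360 umol/L, mild
#' hyperphenylalaninemia (M-HPA) by Phe in [120, 360) umol/L; below 120
#' umol/L the specimen is below the disease threshold.
#'
#' @param phe numeric vector of phenylalanine concentrations in umol/L;
#'   must be non-negative.
#' @return character vector with levels `"PKU"`, `"M_HPA"`,
#'   `"BELOW_THRESHOLD"`.
#' @examples
#' classify_hpa_subtype(c(400, 200, 119))
#' @export
classify_hpa_subtype <- function(phe) {
  if (any(phe < 0, na.rm = TRUE)) stop("phe must be non-negative")
  out <- ifelse(phe >= 360, "PKU", ifelse(phe >= 120, "M_HPA", "BELOW_THRESHOLD"))
  out
}
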