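#' Screening panel data structures
#'
#' A screening panel bundles the measured analytes (amino acids,
#' acylcarnitines, free carnitine C0, succinylacetone SA), derived markers
#' (sums of isobaric channels and ratios such as PHE/TYR), and per-condition
#' positive rules. Each condition group carries 1-3 rules; a group flags
#' positive when any single rule holds, and a rule holds when all of its
#' comparisons hold (OR of ANDs).
#'
#' @name panel-types
NULL

#' Construct an analyte definition
#'
#' @param code short channel code, e.g. `"PHE"`, `"C0"`. Isobaric species
#'   quantified jointly by flow-injection MS/MS keep their composite code,
#'   e.g. `"C5DC+C6-OH"`.
#' @param display_name human-readable name; defaults to the code.
#' @param unit concentration unit label carried verbatim (no conversion).
#' @return a list of class `nbs_analyte`.
#' @export
analyte <- function(code, display_name = code, unit = "nmol/L") {
  stopifnot(is.character(code), nchar(code) > 0, nchar(unit) > 0)
  structure(list(code = code, display_name = display_name, unit = unit),
            class = "nbs_analyte")
}

#' Construct a derived marker (sum or ratio of analytes)
#'
#' A derived marker with an empty denominator is a plain sum of its numerator
#' analytes; otherwise it is numerator-sum / denominator-sum.
#'
#' @param name marker name as it appears in rules, e.g. `"PHE/TYR"`.
#' @param numerator character vector of analyte codes (summed).
#' @param denominator character vector of analyte codes (summed), or empty.
#' @return a list of class `nbs_derived_marker`.
#' @export
derived_marker <- function(name, numerator, denominator = character()) {
  stopifnot(is.character(name), length(numerator) >= 1)
  structure(list(name = name,
                 numerator = as.character(numerator),
                 denominator = as.character(denominator)),
            class = "nbs_derived_marker")
}

#' Construct a single threshold comparison
#'
#' @param marker analyte code or derived-marker name.
#' @param op one of `">"`, `">="`, `"<"`, `"<="`. Strict unless the cut-off is
#'   printed with an equality.
#' @param threshold finite numeric cut-off in the marker's unit.
#' @return a list of class `nbs_comparison`.
#' @export
comparison <- function(marker, op, threshold) {
  stopifnot(op %in% c(">", ">=", "<", "<="), is.finite(threshold))
  structure(list(marker = marker, op = op, threshold = as.numeric(threshold)),
            class = "nbs_comparison")
}

#' Construct a positive rule (conjunction of comparisons)
#'
#' @param ... `comparison()` objects; all must hold for the rule to fire.
#' @return a list of class `nbs_rule`.
#' @export
rule <- function(...) {
  comps <- list(...)
  stopifnot(length(comps) >= 1)
  structure(list(comparisons = comps), class = "nbs_rule")
}

#' Construct a condition group (one panel row)
#'
#' Conditions that share the same biochemical signature (e.g. PKU, M-HPA and
#' BH4 deficiency, all flagged by elevated Phe) share one row and one set of
#' rules; disambiguation happens downstream at diagnosis.
#'
#' @param group_id stable identifier for the row.
#' @param conditions character vector of member condition names.
#' @param rules list of 1-3 `rule()` objects (disjunctive).
#' @param omim optional character vector of OMIM ids.
#' @return a list of class `nbs_condition_group`.
#' @export
condition_group <- function(group_id, conditions, rules, omim = character()) {
  stopifnot(length(conditions) >= 1, length(rules) >= 1, length(rules) <= 3)
  structure(list(group_id = group_id,
                 conditions = as.character(conditions),
                 rules = rules,
                 omim = as.character(omim)),
            class = "nbs_condition_group")
}

#' Assemble a screening panel
#'
#' @param analytes list of [analyte()] definitions.
#' @param derived_markers list of [derived_marker()] definitions.
#' @param groups list of [condition_group()] rows.
#' @param version free-text version tag.
#' @return a list of class `nbs_panel`.
#' @seealso [builtin_panel()], [validate_panel()], [load_panel()]
#' @export
new_panel <- function(analytes, derived_markers, groups, version = "unversioned") {
  p <- structure(list(analytes = analytes,
                      derived_markers = derived_markers,
                      groups = groups,
                      version = version),
                 class = "nbs_panel")
  issues <- validate_panel(p)
  if (length(issues) > 0)
    stop("invalid panel:\n  ", paste(issues, collapse = "\n  "), call. = FALSE)
  p
}

#' @export
print.nbs_panel <- function(x, ...) {
  cat(sprintf("<nbs_panel '%s': %d analytes, %d derived markers, %d condition groups>\n",
              x$version, length(x$analytes), length(x$derived_markers),
              length(x$groups)))
  invisible(x)
}

panel_analyte_codes <- function(panel) {
  vapply(panel$analytes, function(a) a$code, character(1))
}

panel_marker_names <- function(panel) {
  c(panel_analyte_codes(panel),
    vapply(panel$derived_markers, function(m) m$name, character(1)))
}

#' List every comparison in a panel as a table
#'
#' One row per inequality, in rule order. Useful for auditing a panel against
#' its printed source.
#'
#' @param panel an `nbs_panel`.
#' @return a tibble with columns `group_id`, `rule_index`, `marker`, `op`,
#'   `threshold`.
#' @export
panel_comparisons <- function(panel) {
  rows <- list()
  for (g in panel$groups) {
    for (ri in seq_along(g$rules)) {
      for (cmp in g$rules[[ri]]$comparisons) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          group_id = g$group_id, rule_index = ri,
          marker = cmp$marker, op = cmp$op, threshold = cmp$threshold)
      }
    }
  }
  do.call(rbind, rows)
}

#' Validate a panel against its structural invariants
#'
#' Reports, never throws. Checked: unique analyte codes, non-empty units,
#' derived markers referencing only declared analytes, unique marker names,
#' 1-3 rules per group with at least one comparison each, every comparison
#' resolving to exactly one analyte or derived marker, and a valid operator
#' with a finite threshold.
#'
#' @param panel an `nbs_panel` (or a bare list shaped like one).
#' @return character vector of issues; empty when the panel is valid.
#' @export
validate_panel <- function(panel) {
  issues <- character()
  codes <- vapply(panel$analytes, function(a) a$code %||% "", character(1))
  if (anyDuplicated(codes))
    issues <- c(issues, paste0("duplicate analyte code(s): ",
                               paste(unique(codes[duplicated(codes)]), collapse = ", ")))
  units <- vapply(panel$analytes, function(a) a$unit %||% "", character(1))
  if (any(!nzchar(units)))
    issues <- c(issues, paste0("analyte(s) with empty unit: ",
                               paste(codes[!nzchar(units)], collapse = ", ")))
  dm_names <- vapply(panel$derived_markers, function(m) m$name %||% "", character(1))
  if (anyDuplicated(c(codes, dm_names)))
    issues <- c(issues, "marker namespace not unique (analyte code also used as derived-marker name)")
  for (m in panel$derived_markers) {
    bad <- setdiff(c(m$numerator, m$denominator), codes)
    if (length(bad) > 0)
      issues <- c(issues, sprintf("derived marker '%s' references unknown analyte(s): %s",
                                  m$name, paste(bad, collapse = ", ")))
    if (length(m$numerator) < 1)
      issues <- c(issues, sprintf("derived marker '%s' has an empty numerator", m$name))
  }
  known <- c(codes, dm_names)
  for (g in panel$groups) {
    gid <- g$group_id %||% "<unnamed>"
    if (length(g$conditions) < 1)
      issues <- c(issues, sprintf("group '%s' has no member conditions", gid))
    nr <- length(g$rules)
    if (nr < 1 || nr > 3)
      issues <- c(issues, sprintf("group '%s' has %d rules; 1-3 allowed", gid, nr))
    for (ri in seq_along(g$rules)) {
      comps <- g$rules[[ri]]$comparisons
      if (length(comps) < 1) {
        issues <- c(issues, sprintf("group '%s' rule %d has no comparisons", gid, ri))
        next
      }
      for (cmp in comps) {
        if (!(cmp$marker %in% known))
          issues <- c(issues, sprintf("group '%s' rule %d references unknown marker '%s'",
                                      gid, ri, cmp$marker))
        if (!(cmp$op %in% c(">", ">=", "<", "<=")))
          issues <- c(issues, sprintf("group '%s' rule %d has invalid operator '%s'",
                                      gid, ri, cmp$op))
        if (!is.numeric(cmp$threshold) || !is.finite(cmp$threshold))
          issues <- c(issues, sprintf("group '%s' rule %d has a non-finite threshold", gid, ri))
      }
    }
  }
  gids <- vapply(panel$groups, function(g) g$group_id %||% "", character(1))
  if (anyDuplicated(gids))
    issues <- c(issues, "duplicate group ids")
  issues
}

panel_to_list <- function(panel) {
  list(
    version = panel$version,
    analytes = lapply(panel$analytes, function(a)
      list(code = a$code, display_name = a$display_name, unit = a$unit)),
    derived_markers = lapply(panel$derived_markers, function(m)
      list(name = m$name, numerator = as.list(m$numerator),
           denominator = as.list(m$denominator))),
    groups = lapply(panel$groups, function(g)
      list(id = g$group_id, conditions = as.list(g$conditions),
           omim = as.list(g$omim),
           rules = lapply(g$rules, function(r)
             lapply(r$comparisons, function(cmp)
               list(marker = cmp$marker, op = cmp$op,
                    threshold = cmp$threshold)))))
  )
}

panel_from_list <- function(x) {
  as_chr <- function(v) as.character(unlist(v, use.names = FALSE))
  analytes <- lapply(x$analytes, function(a)
    analyte(a$code, a$display_name %||% a$code, a$unit %||% "nmol/L"))
  dms <- lapply(x$derived_markers, function(m)
    derived_marker(m$name, as_chr(m$numerator), as_chr(m$denominator)))
  groups <- lapply(x$groups, function(g) {
    rules <- lapply(g$rules, function(r) {
      comps <- lapply(r, function(cmp)
        comparison(cmp$marker, cmp$op, as.numeric(cmp$threshold)))
      do.call(rule, comps)
    })
    condition_group(g$id, as_chr(g$conditions), rules, as_chr(g$omim))
  })
  new_panel(analytes, dms, groups, version = x$version %||% "unversioned")
}

#' Load a screening panel from a JSON or YAML config
#'
#' The config schema has top-level keys `version`, `analytes[]`
#' (`{code, display_name, unit}`), `derived_markers[]`
#' (`{name, numerator[], denominator[]}`) and `groups[]`
#' (`{id, conditions[], omim[], rules[][]{marker, op, threshold}}`).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"` or `"yaml"`.
#' @return a validated `nbs_panel`; errors on parse failure or any
#'   [validate_panel()] issue.
#' @export
load_panel <- function(path, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("panel config not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  }
  x <- if (format == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  panel_from_list(x)
}

#' Save a screening panel to a JSON or YAML config
#'
#' `load_panel(save_panel(p, path))` reproduces `p` exactly.
#'
#' @param panel an `nbs_panel`.
#' @param path destination file path.
#' @param format `"auto"` (by extension), `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
save_panel <- function(panel, path, format = c("auto", "json", "yaml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "json"
  }
  x <- panel_to_list(panel)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
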