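# Brute-force screening oracle, independent of the package's panel
# representation: the cut-off sheet is kept as printed inequality strings
# (transcribed verbatim, including inconsistent spacing and the one ">="
# cut-off), re-parsed and re-evaluated from scratch for every profile.

printed_rule_cells <- function() {
  list(
    "PKU_MHPA_BH4" = c("PHE > 100 nmol/L, PHE/TYR > 1.2", "PHE > 130 nmol/L,",
                       "PHE/TYR > 2"),
    "HCY_HMET" = c("MET > 70 nmol/L", "MET > 43 nmol/L, MET/PHE > 0.85"),
    "ASA" = c("CIT > 50 nmol/L", "CIT > 35 nmol/L, ALA/CIT < 8.5"),
    "MSUD" = c("LEU+ILE+PRO-OH > 400 nmol/L",
               "LEU+ILE+PRO-OH > 320 nmol/L, LEU+ILE+PRO-OH/PHE > 5.9, VAL > 250 nmol/L"),
    "OTC" = c("CIT < 5.5 nmol/L", "CIT < 6.5nmol/L, CIT/PHE < 0.12"),
    "H-ORN" = c("ORN > 450 nmol/L", "ORN > 340 nmol/L, ORN/CIT > 24"),
    "H-TYR" = c("TYR > 400 nmol/L",
                "TYR > 350nmol/L, LEU+ILE+PRO-OH/TYR < 0.5, PHE/TYR < 0.15"),
    "H-ARG" = c("ARG > 65 nmol/L", "ARG/PHE > 1.2, ARG > 50 nmol/L"),
    "TYR-I" = c("SA > 2 nmol/L", "SA > 1.2 nmol/L, SA/PHE > 0.03"),
    "H-PRO" = "PRO > 470 nmol/L",
    "MUT_PROP" = c("C3/C0 > 0.3 nmol/L", "C3/C2 > 0.21, C3 > 4.5nmol/L",
                   "C3 > 6.5"),
    "IVA_2MBG" = c("C5 > 0.8 nmol/L", "C5 > 0.4 nmol/L, C5/C0 > 0.02"),
    "3MCC_MCD_2M3HBA_3MGA_HMG" = c("C4DC+C5-OH > 0.7nmol/L",
                                   "C4DC+C5-OH > 0.5nmol/L, (C4DC+C5-OH)/C0 > 0.025"),
    "MADD" = "C5 > 0.4 nmol/L,C4 > 0.5 nmol/L",
    "BKT" = "C5:1 > 0.02nmol/L,C4DC+C5-OH > 0.5nmol/L",
    "MAL" = c("C3DC+C4-OH > 0.8nmol/L",
              "C3DC+C4-OH > 0.45nmol/L, (C3DC+C4-OH)/C10 > 5"),
    "GA-I" = c("C5DC+C6-OH > 0.4nmol/L",
               "C5DC+C6-OH > 0.23nmol/L, (C5DC+C6-OH)/(C3DC+C4-OH) > 2, (C5DC+C6-OH)/(C4DC+C5-OH) > 1.38"),
    "MCADD" = c("C8 > 0.3nmol/L",
                "C6 > 0.11nmol/L, C8 > 0.19nmol/L, C8/C2>=0.01, (C4DC+C5-OH)/C8 < 1"),
    "VLCADD" = c("C14:1 > 0.5nmol/L",
                 "C14:1 > 0.35nmol/L, C14:1/C16 > 0.14, C14:1/C2>=0.02"),
    "LCHADD_TFP" = "C16-OH > 0.06nmol/L,C16-OH/C16 > 0.025,C18:1-OH > = 0.06 nmol/L,C18-OH > 0.03 nmol/L",
    "PCUD" = "C0 < 9.5 nmol/L",
    "CPT-Ia" = c("C0 > 100 nmol/L",
                 "C0/(C16+C18) > 50, C0 > 55 nmol/L, (C16+C18:1)/C2 < 0.08"),
    "CPT-II_CACT" = c("C18 > 1.9 nmol/L, C18:1 > 3 nmol/L",
                      "C16> 12 nmol/L, C16 > 7 nmol/L, C18:1 > 3 nmol/L"),
    "SCADD" = c("C4 > 0.7 nmol/L", "C4 > 0.5 nmol/L, C4/C2 > 0.03"),
    "NKHG" = "GLY > 1100 nmol/L",
    "IBG_EMA" = c("C4 > 0.7 nmol/L", "C4/C3 > 0.45, C4/C2 > 0.03")
  )
}

# one inequality string -> list(marker, op, threshold)
parse_inequality <- function(s) {
  s <- trimws(s)
  m <- regexec("^(.+?)\\s*(>\\s*=|<\\s*=|>=|<=|>|<)\\s*([0-9.]+)\\s*(nmol/L)?$", s)
  parts <- regmatches(s, m)[[1]]
  stopifnot(length(parts) >= 4)
  op <- gsub("\\s", "", parts[3])
  list(marker = trimws(parts[2]), op = op, threshold = as.numeric(parts[4]))
}

parse_rule_cell <- function(cell) {
  parts <- Filter(nzchar, trimws(strsplit(cell, ",")[[1]]))
  lapply(parts, parse_inequality)
}

# paren-aware split of a marker expression on its top-level "/"
split_ratio <- function(expr) {
  depth <- 0
  chars <- strsplit(expr, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (chars[i] == "/" && depth == 0)
      return(c(substr(expr, 1, i - 1), substr(expr, i + 1, nchar(expr))))
  }
  expr
}

# strip parentheses only when they wrap the whole expression
strip_outer_parens <- function(expr) {
  repeat {
    if (!startsWith(expr, "(")) return(expr)
    depth <- 0
    chars <- strsplit(expr, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1
      if (chars[i] == ")") {
        depth <- depth - 1
        if (depth == 0) {
          if (i < length(chars)) return(expr)   # "(...)/X" style: keep
          expr <- substr(expr, 2, nchar(expr) - 1)
          break
        }
      }
    }
  }
}

# evaluate a marker expression against named analyte values; composite
# channel codes (containing "+") resolve atomically before any splitting
oracle_marker_value <- function(expr, vals) {
  expr <- strip_outer_parens(trimws(expr))
  if (expr %in% names(vals)) return(unname(vals[[expr]]))
  sides <- split_ratio(expr)
  if (length(sides) == 2) {
    num <- oracle_marker_value(sides[1], vals)
    den <- oracle_marker_value(sides[2], vals)
    if (is.na(den) || den == 0) return(NA_real_)
    return(num / den)
  }
  parts <- trimws(strsplit(expr, "+", fixed = TRUE)[[1]])
  vals_p <- vapply(parts, function(p) {
    if (p %in% names(vals)) unname(vals[[p]]) else NA_real_
  }, numeric(1))
  sum(vals_p)
}

oracle_positive_groups <- function(vals, cells = printed_rule_cells()) {
  vapply(cells, function(group_cells) {
    any(vapply(group_cells, function(cell) {
      all(vapply(parse_rule_cell(cell), function(cmp) {
        v <- oracle_marker_value(cmp$marker, vals)
        if (is.na(v)) return(FALSE)
        switch(cmp$op,
               ">" = v > cmp$threshold, ">=" = v >= cmp$threshold,
               "<" = v < cmp$threshold, "<=" = v <= cmp$threshold)
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
}

# a full profile at the reference levels, with overrides
reference_profile <- function(...) {
  vals <- analyte_reference()
  over <- c(...)
  vals[names(over)] <- over
  vals
}

# random profiles spanning normal and rule-firing ranges
random_profiles <- function(n, gsd = 2.5) {
  ref <- analyte_reference()
  m <- matrix(stats::rlnorm(n * length(ref), log(rep(ref, each = n)),
                            log(gsd)), n)
  colnames(m) <- names(ref)
  m
}

# per group: analytes whose increase can only preserve/create positivity
# (appear only in the "raising" orientation across the group's rules)
monotone_increasing_analytes <- function(panel) {
  dms <- stats::setNames(panel$derived_markers,
                         vapply(panel$derived_markers, function(m) m$name,
                                character(1)))
  out <- list()
  for (g in panel$groups) {
    dir <- list()   # analyte -> set of orientations seen
    add <- function(a, d) dir[[a]] <<- union(dir[[a]], d)
    for (r in g$rules) for (cmp in r$comparisons) {
      up <- cmp$op %in% c(">", ">=")
      if (cmp$marker %in% names(dms)) {
        m <- dms[[cmp$marker]]
        for (a in m$numerator) add(a, if (up) 1 else -1)
        for (a in m$denominator) add(a, if (up) -1 else 1)
      } else {
        add(cmp$marker, if (up) 1 else -1)
      }
    }
    out[[g$group_id]] <- names(Filter(function(d) identical(d, 1), dir))
  }
  out
}
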