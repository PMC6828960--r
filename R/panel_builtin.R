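#' The packaged 26-condition MS/MS screening panel
#'
#' Returns the default expanded newborn-screening panel used by a large
#' municipal dried-blood-spot program: 26 condition groups over amino acids,
#' acylcarnitines, free carnitine (C0) and succinylacetone (SA), each with 1-3
#' disjunctive positive rules. Comma-separated inequalities within one rule
#' are conjunctive. Units are carried verbatim from the program's cut-off
#' sheet (`nmol/L` for measured analytes; ratios are unitless); the engine is
#' unit-agnostic.
#'
#' Isobaric acylcarnitine species quantified as a single flow-injection
#' channel (e.g. `C5DC+C6-OH`) are single analytes whose code contains `+`;
#' sums across separately measured channels (`LEU+ILE+PRO-OH`) are derived
#' markers.
#'
#' @return a validated `nbs_panel` with exactly 26 condition groups;
#'   bit-identical across calls.
#' @examples
#' p <- builtin_panel()
#' length(p$groups)
#' @export
builtin_panel <- function() {
  aa <- function(code) analyte(code, unit = "nmol/L")
  analytes <- lapply(c(
    # amino acids + succinylacetone
    "ALA", "ARG", "CIT", "GLY", "LEU", "ILE", "PRO-OH", "MET", "ORN", "PHE",
    "PRO", "TYR", "VAL", "SA",
    # free carnitine and acylcarnitines (isobaric channels joint)
    "C0", "C2", "C3", "C4", "C5", "C5:1", "C6", "C6DC", "C8", "C8:1", "C10",
    "C10:1", "C10:2", "C12", "C12:1", "C14", "C14:1", "C14:2", "C14-OH",
    "C16", "C16:1", "C16-OH", "C16:1-OH", "C18", "C18:1", "C18:2", "C18-OH",
    "C18:1-OH", "C18:2-OH", "C3DC+C4-OH", "C4DC+C5-OH", "C5DC+C6-OH"
  ), aa)

  dm <- derived_marker
  derived <- list(
    dm("PHE/TYR", "PHE", "TYR"),
    dm("MET/PHE", "MET", "PHE"),
    dm("ALA/CIT", "ALA", "CIT"),
    dm("LEU+ILE+PRO-OH", c("LEU", "ILE", "PRO-OH")),
    dm("LEU+ILE+PRO-OH/PHE", c("LEU", "ILE", "PRO-OH"), "PHE"),
    dm("LEU+ILE+PRO-OH/TYR", c("LEU", "ILE", "PRO-OH"), "TYR"),
    dm("CIT/PHE", "CIT", "PHE"),
    dm("ORN/CIT", "ORN", "CIT"),
    dm("ARG/PHE", "ARG", "PHE"),
    dm("SA/PHE", "SA", "PHE"),
    dm("C3/C0", "C3", "C0"),
    dm("C3/C2", "C3", "C2"),
    dm("C5/C0", "C5", "C0"),
    dm("(C4DC+C5-OH)/C0", "C4DC+C5-OH", "C0"),
    dm("(C3DC+C4-OH)/C10", "C3DC+C4-OH", "C10"),
    dm("(C5DC+C6-OH)/(C3DC+C4-OH)", "C5DC+C6-OH", "C3DC+C4-OH"),
    dm("(C5DC+C6-OH)/(C4DC+C5-OH)", "C5DC+C6-OH", "C4DC+C5-OH"),
    dm("C8/C2", "C8", "C2"),
    dm("(C4DC+C5-OH)/C8", "C4DC+C5-OH", "C8"),
    dm("C14:1/C16", "C14:1", "C16"),
    dm("C14:1/C2", "C14:1", "C2"),
    dm("C16-OH/C16", "C16-OH", "C16"),
    dm("C0/(C16+C18)", "C0", c("C16", "C18")),
    dm("(C16+C18:1)/C2", c("C16", "C18:1"), "C2"),
    dm("C4/C2", "C4", "C2"),
    dm("C4/C3", "C4", "C3")
  )

  cmp <- comparison
  grp <- function(id, conditions, rules, omim = character())
    condition_group(id, conditions, rules, omim)

  groups <- list(
    grp("PKU_MHPA_BH4", c("PKU", "M-HPA", "BH4 deficiency"), list(
      rule(cmp("PHE", ">", 100), cmp("PHE/TYR", ">", 1.2)),
      rule(cmp("PHE", ">", 130)),
      rule(cmp("PHE/TYR", ">", 2)))),
    grp("HCY_HMET", c("HCY", "H-MET"), list(
      rule(cmp("MET", ">", 70)),
      rule(cmp("MET", ">", 43), cmp("MET/PHE", ">", 0.85)))),
    grp("ASA", "ASA", list(
      rule(cmp("CIT", ">", 50)),
      rule(cmp("CIT", ">", 35), cmp("ALA/CIT", "<", 8.5)))),
    grp("MSUD", "MSUD", list(
      rule(cmp("LEU+ILE+PRO-OH", ">", 400)),
      rule(cmp("LEU+ILE+PRO-OH", ">", 320), cmp("LEU+ILE+PRO-OH/PHE", ">", 5.9),
           cmp("VAL", ">", 250)))),
    grp("OTC", "OTC", list(
      rule(cmp("CIT", "<", 5.5)),
      rule(cmp("CIT", "<", 6.5), cmp("CIT/PHE", "<", 0.12)))),
    grp("H-ORN", "H-ORN", list(
      rule(cmp("ORN", ">", 450)),
      rule(cmp("ORN", ">", 340), cmp("ORN/CIT", ">", 24)))),
    grp("H-TYR", "H-TYR", list(
      rule(cmp("TYR", ">", 400)),
      rule(cmp("TYR", ">", 350), cmp("LEU+ILE+PRO-OH/TYR", "<", 0.5),
           cmp("PHE/TYR", "<", 0.15)))),
    grp("H-ARG", "H-ARG", list(
      rule(cmp("ARG", ">", 65)),
      rule(cmp("ARG/PHE", ">", 1.2), cmp("ARG", ">", 50)))),
    grp("TYR-I", "TYR-I", list(
      rule(cmp("SA", ">", 2)),
      rule(cmp("SA", ">", 1.2), cmp("SA/PHE", ">", 0.03)))),
    grp("H-PRO", "H-PRO", list(
      rule(cmp("PRO", ">", 470)))),
    grp("MUT_PROP", c("MUT", "PROP"), list(
      rule(cmp("C3/C0", ">", 0.3)),
      rule(cmp("C3/C2", ">", 0.21), cmp("C3", ">", 4.5)),
      rule(cmp("C3", ">", 6.5)))),
    grp("IVA_2MBG", c("IVA", "2MBG"), list(
      rule(cmp("C5", ">", 0.8)),
      rule(cmp("C5", ">", 0.4), cmp("C5/C0", ">", 0.02)))),
    grp("3MCC_MCD_2M3HBA_3MGA_HMG", c("3-MCC", "MCD", "2M3HBA", "3MGA", "HMG"), list(
      rule(cmp("C4DC+C5-OH", ">", 0.7)),
      rule(cmp("C4DC+C5-OH", ">", 0.5), cmp("(C4DC+C5-OH)/C0", ">", 0.025)))),
    grp("MADD", "MADD", list(
      rule(cmp("C5", ">", 0.4), cmp("C4", ">", 0.5)))),
    grp("BKT", "BKT", list(
      rule(cmp("C5:1", ">", 0.02), cmp("C4DC+C5-OH", ">", 0.5)))),
    grp("MAL", "MAL", list(
      rule(cmp("C3DC+C4-OH", ">", 0.8)),
      rule(cmp("C3DC+C4-OH", ">", 0.45), cmp("(C3DC+C4-OH)/C10", ">", 5)))),
    grp("GA-I", "GA-I", list(
      rule(cmp("C5DC+C6-OH", ">", 0.4)),
      rule(cmp("C5DC+C6-OH", ">", 0.23),
           cmp("(C5DC+C6-OH)/(C3DC+C4-OH)", ">", 2),
           cmp("(C5DC+C6-OH)/(C4DC+C5-OH)", ">", 1.38)))),
    grp("MCADD", "MCADD", list(
      rule(cmp("C8", ">", 0.3)),
      rule(cmp("C6", ">", 0.11), cmp("C8", ">", 0.19), cmp("C8/C2", ">=", 0.01),
           cmp("(C4DC+C5-OH)/C8", "<", 1)))),
    grp("VLCADD", "VLCADD", list(
      rule(cmp("C14:1", ">", 0.5)),
      rule(cmp("C14:1", ">", 0.35), cmp("C14:1/C16", ">", 0.14),
           cmp("C14:1/C2", ">=", 0.02)))),
    grp("LCHADD_TFP", c("LCHADD", "TFP"), list(
      rule(cmp("C16-OH", ">", 0.06), cmp("C16-OH/C16", ">", 0.025),
           cmp("C18:1-OH", ">=", 0.06), cmp("C18-OH", ">", 0.03)))),
    grp("PCUD", "PCUD", list(
      rule(cmp("C0", "<", 9.5)))),
    grp("CPT-Ia", "CPT-Ia", list(
      rule(cmp("C0", ">", 100)),
      rule(cmp("C0/(C16+C18)", ">", 50), cmp("C0", ">", 55),
           cmp("(C16+C18:1)/C2", "<", 0.08)))),
    grp("CPT-II_CACT", c("CPT-II", "CACT"), list(
      rule(cmp("C18", ">", 1.9), cmp("C18:1", ">", 3)),
      rule(cmp("C16", ">", 12), cmp("C16", ">", 7), cmp("C18:1", ">", 3)))),
    grp("SCADD", "SCADD", list(
      rule(cmp("C4", ">", 0.7)),
      rule(cmp("C4", ">", 0.5), cmp("C4/C2", ">", 0.03)))),
    grp("NKHG", "NKHG", list(
      rule(cmp("GLY", ">", 1100)))),
    grp("IBG_EMA", c("IBG", "EMA"), list(
      rule(cmp("C4", ">", 0.7)),
      rule(cmp("C4/C3", ">", 0.45), cmp("C4/C2", ">", 0.03))))
  )

  new_panel(analytes, derived, groups, version = "suzhou-26-v1")
}
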