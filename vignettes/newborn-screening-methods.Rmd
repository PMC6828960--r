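---
title: "Methods: rule-based expanded newborn screening analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based expanded newborn screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Setting

Expanded newborn screening quantifies some 40+ metabolites — amino acids,
acylcarnitines, free carnitine (C0) and succinylacetone (SA) — in a dried
blood spot by flow-injection tandem mass spectrometry, and flags specimens
for inborn errors of metabolism (IEMs) by fixed cut-off rules. A flagged
newborn is recalled for a second specimen; a newborn positive on both
specimens ("suspect positive") is referred for diagnostic confirmation.
`nbscreen` implements the full analysis chain of such a program: the
machine-readable cut-off panel, the rule engine, a synthetic-cohort
generator, the two-tier cascade, incidence/spectrum epidemiology, and
variant-spectrum (hotspot) statistics.

# The screening panel and rule semantics

The packaged panel (`builtin_panel()`) encodes 26 condition groups. A group
carries one to three *positive rules*; the group flags when **any** rule
holds, and a rule holds when **all** of its comparisons hold (an
OR-of-ANDs). The cut-off sheet the panel transcribes separates comparisons
within one rule cell by commas and never states the connective; the
conjunctive reading is adopted because each successive rule column pairs a
*lower* primary cut-off with corroborating secondary markers — the standard
design of recall rules, where a milder elevation is only actionable with
supporting evidence. This is the package's most consequential
interpretation and is therefore stated prominently here. One documented
edge: the long-chain hydroxyacyl-CoA row lists four inequalities in a
single cell, which under this reading is one very strict conjunctive rule.

Further conventions:

* **Boundary semantics.** Operators are applied exactly as printed: strict
  unless the sheet prints an equality (one cut-off, C18:1-OH >= 0.06, does).
  A value equal to a strict cut-off is negative.
* **Undefined markers.** A ratio with a zero denominator, or any marker with
  a missing member analyte, is undefined; comparisons on undefined markers
  evaluate `FALSE` (screening must not crash on a sparse channel) and the
  engine warns once per screening call.
* **Composite channels.** Isobaric acylcarnitine species that flow-injection
  MS/MS cannot separate (e.g. `C4DC+C5-OH`) are single analytes whose code
  contains `+`; sums over separately measured channels
  (`LEU+ILE+PRO-OH`) are derived markers with explicit member lists.
* **Units.** Concentration cut-offs are carried verbatim from the source
  sheet (`nmol/L`). Screening concentrations are conventionally umol/L and
  the printed magnitudes match umol/L practice, but the intent is not
  second-guessed: the engine is unit-agnostic and trusts the config. No
  unit conversion is performed anywhere.
* **Group-level flags.** Conditions sharing one biochemical signature (PKU,
  mild hyperphenylalaninemia and BH4 deficiency all present as elevated
  Phe) share one row; disambiguation is a diagnosis-stage concern, not the
  engine's.

Hyperphenylalaninemia subtyping follows the clinical convention:
`classify_hpa_subtype()` labels Phe >= 360 umol/L classical PKU, 120-360
umol/L mild HPA (lower bound inclusive, upper exclusive since 360 belongs
to PKU), below 120 umol/L below-threshold.

# The synthetic cohort generator

No raw screening data are distributed with programs of this kind, so the
package ships a generator that emulates the statistical structure the
analyses assume. What it emulates — and what it does not — bounds what a
passing test says about real data.

**Unaffected metabolite profiles** are log-normal per analyte:
concentrations are positive and right-skewed, and a multiplicative noise
model keeps ratios log-normal too. The per-analyte geometric means
(`analyte_reference()`) are package-defined stand-ins, not population
reference ranges (none are published with the cut-off sheet): they are
placed so every cut-off lies at least ~1.8x away from the mean in the rule's
firing direction, which at the default core geometric SD of 1.12 is >= 5 SD
on the log scale — the unaffected core population essentially never fires.

**False positives** come from a two-component mixture rather than from
fattening one distribution: with probability `fp_inflation` a specimen's
log-SD is inflated by `tail_gsd_mult` (default 5x). This makes the
initial-positive rate a single interpretable knob:
`calibrate_fp_inflation()` estimates the per-component firing rates by
pilot simulation (default 100,000 specimens per component) and solves the
mixture weight so the unaffected positive rate equals the program's
reported 2.80% recall rate. The target is a reported program input, not a
fitted quantity.

**Affected newborns** draw their condition's marker analytes around shifted
geometric means: elevated markers at 2.5x their rule-1 cut-off, depleted
markers (free carnitine in carnitine-uptake defect, citrulline in OTC
deficiency) at 0.4x. At the core noise level this gives essentially
complete biochemical sensitivity, consistent with a program that reports
no missed cases; `affected_sensitivity` can suppress the phenotype for
sensitivity experiments. The three Phe-pathway conditions get explicit Phe
targets (600, 200 and 300 umol/L for PKU, mild HPA and BH4 deficiency) so
that downstream Phe-based subtyping is meaningful. One condition per
newborn; comorbidity is not modelled (the program's accounting is one IEM
per patient).

**Recall specimens** regress toward the mean: the new log-deviation is
`(1 - rho)` times the initial deviation plus fresh core measurement noise,
while an affected newborn's shift persists (its deviation is measured from
the *shifted* mean). `calibrate_retest_attenuation()` solves rho by
bisection against the retest-positive rate implied by the reported stage
counts (~5.6% of recollected false positives re-fire, giving the 6.90%
suspect rate).

**Demographics** are drawn from the program's marginal stratum proportions
(gender, gestational-age and birth-weight bands, fetus number, region,
registration), independently of disease state — the program found no
association, and no joint structure is published. "No record" strata are
explicit categories at their observed rates. Age at initial testing is
log-normal matched to the reported mean 7.35 and SD 8.14 days.

**Genotypes** are drawn per condition from the packaged allele spectra
(relative frequencies of the observed variant table, including
"undetectable" placeholder mass). Recessive conditions draw two
independent alleles; hypermethioninemia, which is inherited dominantly or
recessively, draws a single allele with probability 12/13 — the observed
single-allele fraction among its 13 patients.

Not modelled: analytical drift, batch effects, gestational-age-specific
cut-offs, TPN/prematurity interference, comorbidity, and any
genotype-phenotype coupling of marker magnitude. Tests passing on this
generator demonstrate correctness of the analysis chain, not performance
on real screening data.

# The cascade

`run_cascade()` composes: screening of initial profiles; Bernoulli
recollection compliance (default 10,606/11,247); screening of freshly
generated recall profiles; Bernoulli referral compliance (default
720/732); and diagnosis. Diagnostic specificity is assumed perfect —
unaffected newborns are never falsely diagnosed, matching a program that
reports none — and referred true cases confirm with a configurable
per-condition probability (default 1). The subset of diagnosed patients
undergoing genetic analysis is a sampling flag (default 138/153), not a
cascade stage. Each stage rate uses its immediate parent stage as
denominator; this convention is fixed by recomputing all four reported
rates (2.80%, 94.30%, 6.90%, 98.36%) from the reported counts.

# Epidemiological statistics

Incidences are reported in the field's `1/X` form with
`X = round(n / k)` rounded half away from zero (the convention that
reproduces the published denominators; base R's `round()` rounds half to
even). Three interval methods are implemented from their defining
equations and selectable — Wilson score, Clopper-Pearson (beta quantiles)
and exact Poisson (gamma quantiles, appropriate in the rare-event limit) —
with Clopper-Pearson the default: it is exact, standard for rare-disease
counts, and its conservatism is the accepted trade-off. The generating
method of the published intervals is unstated and matches none of the
three on spot checks, so published CI bounds are reported alongside but
never asserted equal; the methods are instead validated against
independent implementations (`binom.test`, `prop.test`, `poisson.test`)
and by empirical coverage at a 1/30,000 event rate.

Cohort characteristics use Pearson chi-square without continuity
correction, with "No record" strata excluded — the combination that
reproduces the published p-values (0.260 gender, 0.166 household
registration, and the other four) exactly to 3 decimals, which anchors the
choice empirically. Continuous characteristics use one-way ANOVA. No
multiple-testing correction is applied (none was in the source analysis).

# Variant statistics

The variant table mirrors the published per-condition blocks: one row per
variant with allele and carrier counts, plus per-block patient totals.
Relative allele frequency uses the block's total allele count — including
"undetectable" placeholder alleles — as denominator, because the published
RF values require it (e.g. 15.0% = 3/20 in a methylmalonic-acidemia block
with 2 undetectable alleles). HGVS-like strings are validated against a
tolerant `c.`-prefix grammar but stored verbatim, legacy forms
(`c.IVS16ins3Kb`, a missing `c.` prefix) included; no transcript
normalisation is attempted.

Distinct mutations are keyed by gene, normalised cDNA *and* normalised
protein change. The protein term matters in exactly one place: the PAH
allele c.331C>T is recorded with two different protein consequences in the
two hyperphenylalaninemia blocks, and the published totals (140 distinct =
89 reported + 51 novel) count it twice; keying on cDNA alone would give
139. Hotspot ranking (`rank_hotspots()`) uses RF% then carrier count, with
package-chosen default thresholds RF >= 10% and >= 2 carriers; the
placeholder mass is never a hotspot.

Two source-data irregularities are handled explicitly: one
hyperphenylalaninemia block's rows sum to 35 alleles against a printed
denominator of 36, so the packaged table carries the unaccounted allele as
an explicit placeholder; and one block's allele total exceeds two per
patient (footnoted in the source), so the per-condition bound is a warning
rather than an error, while the per-variant bound (alleles <= 2 x carriers)
remains fatal.

# Numerical and testing choices

* Rounding throughout is half-away-from-zero (`round_half_away()`), at the
  precision of the corresponding published quantity (2 decimals for stage
  rates and category shares, 1 for RF%, 3 for p-values, integer for 1-in-X
  denominators).
* All randomness flows from one integer seed per parameter object; child
  streams (cohort, initial profiles, recall profiles, cascade compliance,
  calibration pilots) are derived deterministically and stay below 2^31.
* Prevalence-recovery checks use an exact binomial band at **familywise**
  95% (Bonferroni over the 22 conditions). A per-condition 95% band applied
  jointly to 22 independent counts would reject a perfectly correct
  generator in ~43% of runs; the familywise band is the coherent form of
  the "counts recover configured prevalences" property.
* Allele-spectrum recovery is checked within 3 binomial SEs for alleles
  with expected count >= 5 (the normal approximation is meaningless below
  that), with a non-strict bound so degenerate single-allele spectra
  (SE = 0) pass.
* Problem sizes: the full-scale simulation runs at the program's true
  denominator n = 401,660 (about half a minute end to end); calibration
  pilots use 100,000 specimens per mixture component and 60,000
  false-positive candidates; property suites use 1,000 random profiles
  against the brute-force evaluator and 2,000 replicates for CI coverage.
  These sizes make every stochastic tolerance comfortably tight while
  keeping the whole suite in a few minutes.

# Worked example

```{r example}
library(nbscreen)

# screen one specimen
screen_profile(c(PHE = 150, TYR = 50))

# calibrate and run the full program
params <- cohort_params(n_newborns = 401660, seed = 1)
params$fp_inflation <- calibrate_fp_inflation(params)
cohort <- generate_cohort(params)
summarize_cascade(run_cascade(cohort, params))

# epidemiology and variants from the packaged program inputs
incidence_estimate(15, 401660)            # 1/26,777
compare_groups()                          # chi-square per characteristic
rank_hotspots(summarize_condition(load_variant_table(),
                                  "Primary carnitine uptake defect"))
```

# Known limitations

The analyte reference levels are synthetic stand-ins; absolute
concentrations and false-positive structure should not be compared to real
programs. The variant module works at the published aggregate granularity
(per-variant allele/carrier counts), not per-patient genotypes, because
per-patient tables are not published; per-patient inputs can be
represented as single-carrier rows. Published interval bounds and the two
internally inconsistent printed denominators are documented but not
reproduced, by design.
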