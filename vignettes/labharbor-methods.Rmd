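---
title: "labharbor: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{labharbor: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(labharbor)
```

This vignette records how labharbor's pipeline is modelled, the defaults
it ships, the decisions that were genuinely open, and what the synthetic
test bed does and does not demonstrate about real EHR data.

## The harmonization model

Bulk laboratory pulls from an EHR or enterprise data warehouse arrive in
shapes that defeat direct import into a registry: a single free-text
cell may hold a whole panel, the same analyte appears under many source
spellings, units drift between sources, and cells contain tokens such
as "refused" or "canceled" that no numeric field accepts. labharbor
models harmonization as a sequence of total functions over observation
records in which nothing is ever silently dropped:

1. **Ingest** explodes raw exports into one observation per result; a
   token the panel grammar cannot read becomes a *reject* with its
   source row.
2. **Remap** tags each observation with a registry field code from the
   lookup table, or itemizes it as `unmapped_test`.
3. **Clean** accepts exactly the values and units the data dictionary
   allows, itemizing `nonimportable_value`, `unit_mismatch` and
   `invalid_date` exclusions.
4. **De-identify** substitutes registry record ids for patient keys.
5. **Transform** assigns repeating-instrument instances and pivots to
   the REDCap import layout, which is then re-validated field by field
   before any file is written.

Record conservation — `|raw| = |imported| + |itemized exclusions|` — is
an invariant the test suite checks on every pipeline run, and the run
logs report the same counts.

## Data dictionary

The packaged default dictionary defines a repeating `labs` instrument
with 35 number-validated lab fields, one shared collection date
(`date_mdy`) and time (`time_hm`) per instance, and the non-repeating
`subject_status` and `patient_characteristics` instruments the survival
stage reads. The 35 fields are the nine electrolytes/renal/glucose
analytes (na, k, cl, co2, bun, cre, gfr, glu, anion), four general
chemistries (alb, tbili, ca, tp), four liver-function tests (sgpt,
sgot, alkp, glob) and eighteen hematological measures (wbc through
eosp, plus ldh). Derived indices such as the neutrophil-to-lymphocyte
ratio are deliberately *not* stored: they are arithmetic on stored
fields and belong at analysis time. Rarely-resulted extended
differential counts (absolute eosinophils/basophils, immature
granulocytes, nucleated RBCs) were left out of the packaged default,
which is a demonstration schema a registry replaces with its own DD.

Two conventions are worth noting. Dates are represented internally as
calendar dates and rendered as unpadded M/D/Y only at the CSV boundary,
which is the dialect the `date_mdy` validation accepts. And because a
stock REDCap DD CSV does not record which instruments repeat (that is
project configuration), `write_dd_csv()` marks the first field of each
repeating form with `@REPEATING` in the Field Annotation column so the
reader can recover the set; this keeps read/write a true round trip
within a single file.

## Ingest grammar

The untidy export contract is exactly four columns — patient name/MRN,
collection date, collection time, panel cell — and any other column
count is an error naming the offending line, because a shifted column
would otherwise corrupt every token downstream. Within a cell the
default grammar is `NAME VALUE [UNIT]` tokens separated by `;`, where
the value is the last whitespace-separated word that is either a
decimal numeral or a recognized value word (`refused`, `canceled` —
these must parse as observations so the cleaning stage can itemize
them). The grammar is configuration: the original exports this shape
emulates differ by site, and users are expected to adapt the upfront
wrangling while the downstream transformation stays fixed. Rendered
synthetic exports are tab-delimited by default since legitimate source
names contain commas.

Date parsing accepts M/D/Y and ISO Y-M-D; two-digit years are rejected
rather than guessed, the safer behaviour at a PHI boundary.

## Matching, units and values

Test-name matching is exact after trimming, internal-whitespace
collapse and case folding. There is deliberately no fuzzy matching:
a near-miss spelling in clinical data should surface as
`unmapped_test`, not silently bind to the wrong analyte. The packaged
lookup table (~280 entries) carries the seven observed potassium
spellings plus generated suffix variants for every field, at the scale
of a real site table, and is an editable fixture.

Units are enforced, not converted: a value whose unit is not in the
field's allowed set is excluded as `unit_mismatch`. The lookup table's
`scale_factor` (default 1) is the only multiplier ever applied, so any
conversion is explicit and auditable. Comparator values such as
`<0.01` fail number validation and are itemized — lossy but loud, the
conservative default where the upstream practice is unspecified.

## Instances and same-day repeats

One repeating-instrument instance corresponds to one collection event
(`record_id` + date + time), because the instrument shares a single
date/time per instance; all labs drawn together share an instance, and
the same lab drawn twice on one day lands in two instances. An absent
collection time sorts before any timed draw on the same date; equal
datetimes order by source row. If one event carries two results for
the same field, the later one (by source order) opens a new instance
rather than overwriting — and two results for the same field, record,
datetime *and* source position are unrepresentable and raise an
integrity error rather than guessing.

## The survival screen

Overall survival is days from diagnosis to death, censored at the last
follow-up. Baseline selection takes, per subject and lab, the single
value nearest the diagnosis date within a window of 90 days before to
30 days after, ties breaking toward the earlier draw; both the window
and the tie rule are configuration, and the defaults are this
package's choices for a screen where only "date cutoffs" are fixed by
convention. Subjects with no in-window value are absent for that lab
(complete-case per lab).

Each lab is fit untransformed, per unit, in a univariable Cox model.
The partial likelihood uses the **Efron** tie correction — day-resolution
survival times tie often, the correction changes the estimate, and so
the choice is stated rather than silent. The maximizer is Newton
iteration with step-halving (convergence when the step falls below
1e-9, cap 50 iterations); a constant covariate or fewer than two
events is a degenerate-fit error, and non-convergence or `|beta| > 20`
(the signature of monotone likelihood, e.g. perfect separation) yields
a *flagged* result with a warning, never silent output. Confidence
intervals are Wald on the observed information; p-values are two-sided
Wald and raw — no multiplicity correction by default, with
`p_adjust` available for sites that want one. Results order follows
the four registry panels, electrolytes first, sodium first.

The test suite checks the fitter two independent ways: against a
brute-force staged-grid maximization of a naively coded partial
likelihood on tie-free datasets of up to eight subjects (agreement
within 1e-5), and against the survival package's `coxph(ties =
"efron")` across 100 seeded cohorts with ties (agreement within 1e-6,
a cross-check only — the package never calls it at runtime).

## The synthetic test bed

`simulate_cohort()` generates ground truth at desk scale: per-subject
lab values from packaged reference-range normals (e.g. potassium ~
Normal(4.2, 0.4) mmol/L — plausibility scaffolding, not clinical
claims), survival times exponential with hazard
`baseline_hazard * exp(sum(beta * (x - ref_mean)))` so that the
configured log hazard ratios stay per-unit effects, and independent
exponential censoring whose rate is calibrated to the target censored
fraction (exact under the null, approximate under non-null effects).
`render_untidy()` re-serializes the truth into the messy 4-column
shape, drawing source-name variants uniformly from the lookup table and
planting `refused`/`canceled` tokens and off-DD unit variants at
configured rates, with every planted corruption recorded in a manifest;
`inject_errors()` plants digit typos, ISO-malformed dates and value
swaps in finished import tables the same way. All generation is
reproducible from one integer seed.

What the generator deliberately does **not** emulate: longitudinal
trajectories (a subject's lab level is constant across draws),
non-normal value distributions and genuine outliers, informative
censoring, inter-site coding drift beyond name/unit variants, and
free-text outside-hospital reports. Passing round-trip and recovery
tests therefore demonstrates the pipeline's accounting, validation and
statistical machinery — not robustness to every failure mode of real
exports, which is exactly why unmapped and nonconforming data are
surfaced rather than repaired.

Default problem sizes are the package's own testing choices: cohorts
of 20–100 subjects for pipeline properties (20 seeds for round-trip
exactness), 500 subjects for planted-effect recovery, 200 replicates of
300 subjects for confidence-interval coverage of a true hazard ratio
of 2.0 (nominal 95% coverage is asserted within the Monte-Carlo band
93–97%), and pooled null-lab coverage across 20 cohorts. Each suite
run completes in well under a minute per module.

## Known limitations

- The REDCap surface is the CSV import boundary; the API client is a
  stub and live project provisioning is out of scope.
- No HL7v2/FHIR ingestion and no direct Clarity/warehouse connectivity;
  inputs are delimited exports.
- No UCUM unit algebra — unit policy is allow-list plus explicit scale
  factors by design.
- The survival stage is a univariable screen: no multivariable or
  time-varying models, and nothing here supports clinical conclusions.
- The packaged dictionary, lookup table, reference ranges and LOINC map
  are editable demonstration fixtures, not assertions about any
  registry's production configuration.
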