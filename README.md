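# labharbor

**labharbor** turns messy, multi-source electronic health record (EHR)
laboratory exports into validated, de-identified, REDCap-importable
patient-registry records, and runs a univariable Cox overall-survival
screen over baseline labs. It is aimed at clinical research teams that
maintain a multi-institution registry on REDCap: every site uploads the
same data dictionary (DD), runs the same harmonization code against its
local EHR export, and the per-site CSVs aggregate by simple
concatenation.

## What it does

- **Data dictionary** — models the REDCap DD (field types, validation
  rules, the repeating `labs` instrument with 35 lab value fields plus
  shared collection date/time per instance), reads/writes the standard
  REDCap DD CSV, and validates values the way REDCap does at import
  (numbers must be decimal numerals, dates real M/D/Y calendar dates).
- **Ingest** — parses the "untidy" 4-column EHR export (patient
  name/MRN, collection date, time, and a free-text cell holding a whole
  lab panel) and tabular data-warehouse exports; unrecognized tokens are
  rejected with provenance, never dropped.
- **Harmonize** — remaps ~300 source test-name subtypes (e.g. seven
  spellings of potassium) onto the 35 registry field codes via a
  key-value lookup table; drops non-importable values (`refused`,
  `canceled`, comparator strings) and off-DD units into an itemized
  exclusion report; substitutes registry `record_id`s for MRNs using a
  PHI-side crosswalk; assigns one repeating-instrument instance per
  collection event (so same-day repeat draws are preserved); validates
  and writes the REDCap import CSV; aggregates sites; annotates one
  LOINC code per field.
- **Survival** — derives overall survival (diagnosis to death, censored
  at last follow-up), selects each subject's baseline value per lab
  (nearest the diagnosis date within a −90/+30-day window), and fits one
  univariable Cox proportional-hazards model per lab.
- **Quality** — manual-vs-automated agreement rate with a complete
  discrepancy listing, and abstraction-throughput reporting.
- **Synthetic** — a seeded cohort generator with known ground truth,
  corruption injection, and renderers for both raw input shapes, so the
  entire pipeline is testable with no patient data.

## The model at the core

For each lab, with baseline value $x_i$ for subject $i$, the hazard is
$\lambda_i(t) = \lambda_0(t)\,e^{\beta x_i}$. The coefficient maximizes
the Cox partial likelihood; with $D_j$ the set of $d_j$ deaths tied at
time $t_j$ and $R_j$ the risk set, the Efron-corrected log partial
likelihood is

$$
\ell(\beta)=\sum_j\Bigl[\sum_{i\in D_j}\beta x_i-
\sum_{l=0}^{d_j-1}\log\Bigl(\sum_{k\in R_j}e^{\beta x_k}-
\tfrac{l}{d_j}\sum_{k\in D_j}e^{\beta x_k}\Bigr)\Bigr],
$$

maximized by Newton iteration with step-halving. The hazard ratio is
$e^{\hat\beta}$ per unit of the lab (no standardization), the 95% CI is
$e^{\hat\beta\pm1.96\,\mathrm{SE}}$ from the observed information, and
p-values are two-sided Wald — raw, with no multiplicity correction, as
befits a hypothesis-generating screen.

## Worked example

```r
library(labharbor)

truth <- simulate_cohort(sim_config(
  n_subjects = 200, seed = 42, true_log_hr = c(cre = 0.8),
  censor_rate = 0.3,
  corruption = list(refused_rate = 0.02, unit_variant_rate = 0.02)))

r    <- render_untidy(truth)                       # messy 4-column export
rows <- parse_ehr_export(r$lines, delim = "\t")
ex   <- explode_panels(rows)
res  <- harmonize_labs(ex$observations, xwalk = truth$crosswalk)
res$counts
#> $n_raw      6924
#> $n_imported 6628
#> $n_excluded 296
exclusion_counts(res$exclusions)
#> unmapped_test nonimportable_value unit_mismatch invalid_date unknown_patient
#>             0                 143           153            0               0
```

Every raw value is either imported or itemized — `6924 = 6628 + 296` —
and the 296 exclusions are exactly the planted `refused`/`canceled`
tokens and off-DD unit variants. The import table carries the literal
REDCap repeating-instrument columns:

```r
res$table[1:3, 1:5]
#>   record_id redcap_repeat_instrument redcap_repeat_instance lab_date   lab_time
#> 1 A-0001    labs                     1                      7/20/2017  08:58
#> 2 A-0001    labs                     2                      10/8/2017  15:14
#> 3 A-0001    labs                     3                      10/26/2017 13:46
```

The survival screen recovers the planted creatinine effect
(true HR $e^{0.8} \approx 2.23$):

```r
os <- baselabs_os_table(import_to_obs(res$table), truth$status, truth$chars)
render_os_table(os[1:2, ], print = TRUE)
#> Laboratory tests        Hazard ratio (95% CI)    P value
#> Electrolytes/renal/glucose
#> Sodium (na)             0.9460 (0.839-1.07)      0.364
#> Potassium (k)           1.6366 (0.947-2.83)      0.0777
os[os$field_code == "cre", c("hazard_ratio", "ci_low", "ci_high")]
#>   hazard_ratio ci_low ci_high
#>         2.0631  0.680   6.256
```

A command-line wrapper over the same functions lives at
`inst/cli/labharbor`
(`labharbor <simulate|harmonize|validate|aggregate|survival|quality>
--config cfg.yaml [--force] [--seed N]`).

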