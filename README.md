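# adatier

Statistical validation of tiered anti-drug-antibody (ADA) ELISA assays
and seroprevalence estimation, for immunogenicity assessment of
protein therapeutics — the motivating application being pre-existing
antibodies against the bacterial Cas9 nucleases (SaCas9, SpCas9) used
in genome-editing medicines.

ADA testing is tiered: a **screening** assay flags samples whose
blank-corrected OD450 exceeds a statistically determined cut point, a
**confirmatory** assay establishes specificity by competitive inhibition
with excess free antigen, and confirmed positives are **titrated** to an
endpoint dilution. `adatier` implements the statistics of every tier:

* **Screening cut points.** The classical parametric method on untreated
  drug-naive sera — log-transform, Shapiro–Wilk normality check,
  single-pass 1.5 × IQR outlier removal, then
  CP = exp(*m̄* + 1.645 *s*) targeting a 5% false-positive rate — and
  the immune-inhibition alternative for populations with prior pathogen
  exposure: the 95th percentile of antigen-inhibited training ODs
  (Weibull plotting position *p*(*n*+1), which makes the expected
  exceedance of fresh negatives exactly 5%).
* **Confirmatory cut point** on the percent-inhibition scale,
  100 (OD_untreated − OD_inhibited)/OD_untreated, as mean + 1.645 SD
  after outlier removal.
* **Assay precision gating** on a balanced 48 × 3 × 2 × 2 factorial
  panel (576 wells): per-factor one-way ANOVA and Brown–Forsythe
  Levene tests decide between a fixed and a floating cut point.
* **Standard curves**: 4PL fits (Levenberg–Marquardt), limits of
  quantitation by 80–120% back-calculated recovery and ≤ 20% CV, and
  the minimum required serum dilution retaining ≥ 80% of the buffer
  dynamic range.
* **Tiered classification, endpoint titers** (highest dilution above
  blank mean + 2 SD), **isotype summaries**, and **stratified
  prevalence tables** by race, gender and age band.
* A **synthetic plate generator** (donor demographics, seroprevalence,
  4PL response, serum matrix attenuation, nuisance factor effects,
  competitive inhibition, truncated log-normal background) that makes
  the whole cascade testable end to end, plus a shipped synthetic
  200-donor survey fixture reproducing a reported prevalence study's
  marginal tables exactly.

## Worked example

Derive cut points from a 48-donor training panel by the immune-inhibition
method, then estimate seroprevalence in an independent 200-donor survey —
all on generated data with known truth:

```r
library(adatier)
train_cfg <- sim_config(n_donors = 48,  seed = 21)
cfg       <- sim_config(n_donors = 200, seed = 20)

tdon <- generate_donors(train_cfg)
tpm  <- generate_measurements(tdon, train_cfg, antigens = "SaCas9")
tagg <- aggregate_replicates(subtract_blank(tpm, blank_summary(tpm)))
cps  <- train_cutpoints(tagg)
cps$inhibited
#> Cut point: 0.5424 (nonparametric_p95)
#>   n = 48, outliers removed = 0
#>   Shapiro-Wilk p (raw) = 0.0017
cps$confirmatory
#> Cut point: 11.1826 (confirmatory_linear)
#>   n = 48, outliers removed = 7
#>   Shapiro-Wilk p (raw) = 0.0000

don <- generate_donors(cfg)
pm  <- generate_measurements(don, cfg, antigens = "SaCas9")
agg <- aggregate_replicates(subtract_blank(pm, blank_summary(pm)))
out <- classify_donors(agg, cps$inhibited, cps$confirmatory,
                       method = "with_inhibition")
demo <- don[, c("donor_id", "race", "gender", "age_band")]
pt <- prevalence_table(out, demo)
pt[pt$axis == "total", ]
#>   axis stratum n_stratum antigen          method      tier count percent
#>  total   Total       200  SaCas9 with_inhibition screening    24      12
#>  total   Total       200  SaCas9 with_inhibition confirmed    24      12
mean(don$seropositive_sa)   # simulated truth
#> [1] 0.12
```

Reading the output: the inhibited-serum screening cut point (0.54 OD)
was set from antigen-blocked training sera, so true pre-existing
antibodies could not inflate it; the confirmatory threshold (11.2%
inhibition) was exceeded by every screened sample — their specific
binding was suppressed by ~75% — so all 24 screen-positives confirmed,
recovering exactly the 12% of donors this simulated population truly
seropositive.  Note the 7 training "outliers" removed by the
confirmatory pipeline: those are the panel's own seropositive donors,
which is precisely why the trimming step exists.

The shipped 200-donor fixture exercises the reporting layer against a
reported survey's marginals:

```r
fx <- ada_survey_fixture()
pt <- prevalence_table(fx$outcomes, fx$demographics)
pt[pt$axis == "total" & pt$tier == "confirmed" &
   pt$method == "with_inhibition", c("antigen", "count", "percent")]
#>  antigen count percent
#>   SaCas9    20    10.0
#>   SpCas9     5     2.5
```

A thin command-line wrapper with `simulate`, `cutpoint`, `precision`
and `report` subcommands is installed at
`system.file("scripts", "ada-tools.R", package = "adatier")`.

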