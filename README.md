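# crcscreen

Individual-level microsimulation of colorectal cancer (CRC) natural history
and organised faecal-immunochemical-test (FIT) screening, with calibration to
epidemiological targets and a health-economics layer producing
cost-effectiveness (ICER/dominance) and budget-impact analyses.

The package is written for health-economics and screening-programme analysts
who want to evaluate an organised biennial FIT programme (ages 50–69, 20 µg
haemoglobin/g faeces cut-off, European-guideline surveillance after
polypectomy) against a no-screening counterfactual on the *same* simulated
individuals.

## The model

Every simulated person is followed in continuous time from birth to death
along the adenoma–carcinoma sequence:

* **Adenoma onset** is a non-homogeneous Poisson process with intensity
  `Z · λ(a, sex)`, where `λ` is a piecewise-constant baseline by age and sex
  and `Z ~ Gamma(1/ν, 1/ν)` is a personal frailty (mean 1, variance ν)
  producing lesion clustering. Several adenomas can coexist.
* **Adenoma progression**: each lesion independently walks the size states
  ≤5 mm → 6–9 mm → ≥10 mm; in each state an exponential growth time competes
  with an exponential malignant transformation time. Transformation creates a
  preclinical stage I cancer; sizes never regress.
* **Preclinical cancer** progresses through stages I→IV (exponential
  sojourns) competing stage by stage with symptomatic diagnosis. Survival
  after diagnosis is a stage- and sex-specific cure-fraction model,
  `P(T > t) = π_s + (1 − π_s)·e^(−t/µ_s)`, sampled by inverse CDF from a
  persistent per-cancer uniform.
* **Other-cause death** comes from a Gompertz–Makeham life table and truncates
  everything; the realised death age is the minimum of the other-cause and
  cancer death ages.

The screening overlay walks the invitation/surveillance calendar
(participation by age and invitation round, per-lesion FIT sensitivity,
specificity per lesion-free test, diagnostic colonoscopy with polypectomy,
guideline surveillance recalls at 1/3/5 years, complications), cancels the
future cancer of every excised adenoma, and re-draws survival at the detected
(earlier) stage using the cancer's persistent uniform under common random
numbers — so screening can anticipate or remove, but never worsen, an
individual outcome. The economics layer prices event logs (2012 € unit
costs), accrues QALYs (discounted life-years minus colonoscopy, complication
and cancer-care utility losses), and produces the CEA verdict
(ΔC < 0, ΔE > 0 ⟹ *dominant*, otherwise ICER = ΔC/ΔE) and undiscounted
annual budget streams 2009–2038 with colonoscopy demand by purpose.

All shipped natural-history, test-characteristic and participation defaults
are literature-style surrogates meant to be refined with the calibration
module; they emulate a high adenoma-prevalence southern-European population
of 2.23 million (51% women, 2008 reference).

## Worked example

```r
library(crcscreen)
sc <- run_scenario(scenario_config(seed = 7,
                                   population = list(n_simulated = 25000L)))
print(sc)
#> <crc_scenario> seed 7, 25000 simulated individuals (x89.2)
#> <crc_cea> screening vs no screening (discounted at 3%)
#>   incremental cost :     -344.9 million
#>   incremental QALY :   120053.6
#>   verdict          : dominant
#> <crc_bia> 2009-2038: screened 1135.4 M, unscreened 1414.2 M, incremental -278.8 M
```

25,000 simulated individuals stand for the 2.23 M population (scale factor
89.2). Under the default high-prevalence calibration the programme is
**dominant**: it saves €344.9 million (discounted, lifetime horizon) and
gains 120,053.6 QALYs relative to no screening, because treatment savings
from prevented and stage-anticipated cancers exceed the screening costs. The
budget rows are undiscounted 2009–2038 streams.

Because dynamics are independent of unit costs, the same event logs can be
re-priced, e.g. over invitation unit costs:

```r
invitation_cost_sweep(sc$screened, sc$unscreened,
                      scale_factor = sc$manifest$scale_factor,
                      invitation_costs = c(6.06, 25, 50, 100))
#>    invitation_cost delta_cost_meur  verdict   icer
#> 1:            6.06          -344.9 dominant     NA
#> 2:           25.00          -228.2 dominant     NA
#> 3:           50.00           -74.1 dominant     NA
#> 4:          100.00           234.0     icer 1949.2
```

QALYs gained are identical in every row; the verdict flips from dominance to
a positive ICER where the incremental cost crosses zero.

Other entry points: `generate_calibration_targets()` /
`calibrate_parameters()` / `validate_fit()` for fitting natural-history
parameters to prevalence/incidence tables; `run_natural_history()` and
`run_screening()` for the two arms individually; `compute_cea()`,
`compute_bia()`, `tally_costs()`, `tally_qalys()` for the economics;
`write_event_log()` and the `read_*`/`write_*` helpers for the CSV/JSON
interfaces. See the methods vignette (`vignettes/crc-screening-model.Rmd`)
for the model assumptions, parameter meanings and limitations.

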