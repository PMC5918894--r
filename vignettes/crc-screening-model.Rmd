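---
title: "Model and methods: simulating an organised FIT screening programme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: simulating an organised FIT screening programme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## Scope

`crcscreen` simulates, person by person, the natural history of colorectal
cancer along the adenoma–carcinoma sequence, overlays an organised biennial
faecal immunochemical test (FIT) programme for ages 50–69 on the identical
simulated lives, and converts the paired event logs into discounted
cost-effectiveness results and undiscounted budget-impact streams. The
package also ships a synthetic-data generator (life tables, demography,
calibration targets, cost/utility tables) so that every component is testable
end to end with known ground truth, and a derivative-free calibration engine
that fits natural-history parameters to adenoma-prevalence and
cancer-incidence target tables.

## Natural history

Each individual carries a frailty `Z ~ Gamma(1/ν, 1/ν)` (mean 1, variance
`frailty_var`, default ν = 1). Adenomas arise from a Poisson process with
intensity `Z · λ(age, sex)`, where `λ` is piecewise constant on age bands
starting at 20 (people are never born with adenomas). Each adenoma then
evolves independently through the size states ≤5 mm, 6–9 mm, ≥10 mm. In
every state an exponential growth clock (mean dwell `dwell_mean`, default 12
years per step) competes with an exponential malignant-transformation clock
(`transform_rate`; defaults 0, 7e-4, 0.014 per year for the three states).
Transformation starts a preclinical stage I cancer. Preclinical stages I–III
have exponential sojourns (means 2.5, 2.0, 1.5 years) competing with
symptomatic diagnosis (hazards 0.05, 0.20, 0.50 per year); stage IV can only
be diagnosed (hazard 1.0, required positive so no cancer lingers
undiagnosable). Survival from diagnosis uses a stage- and sex-specific
cure-fraction model `P(T > t) = π_s + (1 − π_s) e^{−t/µ_s}` (defaults
π = 0.90/0.75/0.45/0.05, µ = 8/6/4/1.5 years).

All waiting times are exponential. The descriptive state structure fixes the
model; the distributional families were an open design choice, and
exponentials keep the process Markovian in continuous time and make every
kernel analytically checkable (Poisson means, competing-risk probabilities,
geometric death years, exponential sojourns — each verified in the test suite
against closed forms at n = 10,000 within 3 Monte-Carlo standard errors).
Piecewise-exponential refinements can be layered through the calibration
surface without changing the engine.

Survival is sampled by inverse CDF from a persistent per-cancer uniform
`surv_u`. `validate_nh_params()` enforces stochastic ordering across stages
(cure fractions and mean survival non-increasing), which makes the map
`u → T` pointwise monotone in stage: detecting the same cancer at an earlier
stage with the same `u` can only delay or avert the cancer death.

Every parameter above is a structural surrogate: the defaults were chosen
once so that an unscreened cohort reproduces (i) adenoma prevalence rising
from roughly a quarter of men at 50 to above 40% by 70 — the "high
prevalence" regime of southern-European colonoscopy studies — and (ii)
registry-like age-specific cancer incidence (men from ≈95 per 100,000 at
50–54 to ≈550 at 80–84, women about a third lower, lifetime diagnosed risk
near 8%, a pre-screening stage distribution skewed to stages III–IV). They
are starting points for `calibrate_parameters()`, not fitted values of any
specific programme.

## Population and programme

The demography generator distributes 2.23 million people (51% women) over
single ages with a piecewise-linear mid-adulthood bulge, so a large cohort
reaches screening age during the simulated horizon and the unscreened budget
grows with population ageing. Other-cause mortality is Gompertz–Makeham
(`q(a) = 1 − exp(−A − (B/θ)(e^{θ(a+1)} − e^{θa}))`), with parameters giving
2008-style European life expectancy, women above men. Death ages are sampled
conditional on being alive at the 2008 reference age, with uniform placement
within the death year.

Individuals whose simulated cancer would have been symptomatically diagnosed
*before* the 2008 baseline are treated as resected in the past: the cancer
and its parent lesion are removed. This keeps the baseline population
consistent with being alive and undiagnosed in 2008 without rejection
sampling; prevalent diagnosed survivors are out of scope.

The programme starts in 2009 and is fully implemented by 2013. The published
description fixes only those two endpoints, so the roll-out is modelled as a
uniform ramp: each age-eligible person is attached to one of the five years
2009–2013 with equal probability and first invited at the later of that year
and their 50th birthday. People 70 or older in 2009 are never invited; new
cohorts enter until 2038; people already included keep their biennial rounds
until 69 (non-participants stay on the same biennial clock). Routine FIT
stops at 69, but surveillance colonoscopy pathways continue past 69
(`surveillance_after_69`, default on).

## Screening mechanics

A FIT on a lesion-free person is positive with probability
`1 − fit_specificity`; otherwise each lesion triggers independently with its
class sensitivity and no extra false-positive channel. Colonoscopy detects
each lesion independently (reach folded into sensitivity), excises every
detected adenoma, and can cause a complication only when a polypectomy was
performed. Detected preclinical cancer becomes a screen diagnosis at the
stage occupied at that instant. Surveillance dispositions follow the
priority-ordered rules (1-year recall: any adenoma > 20 mm or ≥5 adenomas;
3-year: any > 10 mm or 3–4 adenomas; FIT in 5 years: 1–2 adenomas < 10 mm; a
negative colonoscopy returns to routine biennial FIT — a 10-year exclusion
is the published alternative and can be configured through the rule set).
Because lesions are modelled as size classes, rule evaluation uses
representative diameters (4, 7, 12 mm), with a persistent per-lesion draw
letting a large lesion exceed 20 mm with probability `large_gt20_prob`
(default 0.15). Surveillance appointments are attended with the colonoscopy
compliance probability, the same parameter as post-FIT compliance.

The correlated false-negative scenario flags a fraction
`systematic_fn_fraction` of lesions as persistently FIT-undetectable. The
deciding uniform is drawn once per lesion during natural history, and the
flag follows the lesion into its preclinical-cancer phase: a systematic FIT
miss is treated as a property of the lesion (non-bleeding), not of single
test rounds. Because the uniform pre-exists, toggling the scenario re-uses
the identical natural history and per-person screening streams.

Three sub-seeds (population, natural history, screening) derive
deterministically from the master seed, and every person owns a screening
RNG substream. Consequences relied on by the tests: the unscreened arm is
byte-identical across scenarios sharing a master seed and natural-history
parameters; paired correlated/independent runs agree draw for draw until a
person's pathway first diverges; and with common random numbers no simulated
person dies earlier with screening than without. On that last point one
modelling choice matters: a screen-detected cancer re-draws survival from the
detected stage with the same uniform *and is floored at the counterfactual
cancer death age*. Without the floor, detecting a cancer earlier at an
unchanged stage would start the survival clock earlier and manufacture a
lead-time harm; with it, screening is benefit-or-neutral per individual,
which is the intended reading of stage anticipation here. Overdiagnosis is
still possible (a screen-detected cancer whose symptomatic diagnosis would
never have happened), and it carries treatment costs and utility losses.

## Economics

Costs are 2012 euros, booked in the calendar year of the event, discounted
at 3% to base year 2009 for the CEA (the published description states the
rate; base year and annual compounding are this package's choice), and left
undiscounted for the BIA, which windows 2009–2038 while the CEA keeps the
lifetime horizon. Unit costs: invitation €6.06, FIT analysis €0.99,
consultation after a positive €78, colonoscopy €461.30/€281.30 with/without
polypectomy, complication €5157, initial treatment €6968/€12,765/€13,075 for
stages I–III (none for stage IV), €404 per follow-up year for stages I–III,
€24,255 per year lived with stage IV disease. Follow-up durations are
unpublished, so stage I–III follow-up is capped at 5 years (configurable);
stage IV accrues until death. Annual streams accrue pro rata over partial
years — this reproduces integer-year worked examples exactly (e.g. stage I
+ 3 survival years = 6968 + 3×404) while avoiding a zero-cost artefact for
sub-year survivors.

QALYs are discounted life-years lived from 2009, minus 0.0055 per
colonoscopy (two days of life, 365-day year, 4-decimal rounding), 0.0384 per
complication (two weeks), and annual utility losses per life-year with
cancer care (surrogate defaults 0.05/0.08/0.12/0.30 by stage; the published
stage-specific values are not reproduced in the available text, so these are
configurable inputs). Life-year fractions are discounted by the factor of
the calendar year containing them; a mid-year convention was considered and
left off for testability.

## Calibration

The objective is a weighted Pearson deviance: prevalence residuals are
scaled by binomial standard errors at the target proportion and sample size,
incidence-rate residuals by Poisson standard errors of the rate (0.5-event
floor for empty cells; cells with no observable population are skipped).
Every objective evaluation simulates a cohort with the *same* seed, making
the surface deterministic so simplex methods can act on it. Two or more free
parameters use Nelder–Mead with three random restarts; a single free
parameter uses bounded golden-section search (`stats::optimize`), which is
more reliable than a 1-D simplex. Parameters are fitted on the log scale to
stay positive, within a ±log 6 window by default. Sexes are calibrated
independently. The self-consistency gate — regenerate targets from known
parameters, free the onset multiplier, recover it within 10% at 50,000
individuals per evaluation — runs in the acceptance suite.

## Problem sizes and what the tests show

The acceptance runs use 200,000 simulated individuals representing the 2.23
million population (scale factor ≈ 11.15), the package's desk-scale default:
large enough that the directional contrasts (screened vs unscreened
incidence, mortality, QALYs, dominance; base vs low-prevalence colonoscopy
demand; correlated vs independent FIT positivity) are far outside Monte-Carlo
noise, yet a full paired scenario completes in about a minute on one CPU.
Unit-level oracles run at n = 10,000 with 3-standard-error tolerances.

The synthetic-data generator emulates the statistical *structure* of the
inputs (age-increasing high adenoma prevalence, registry-like stage-specific
incidence, Gompertz-type mortality, a baby-boom pyramid) with known
parameters. It does not emulate secular trends, migration, birth cohorts
after 2008, geographic roll-out order, serrated-pathway lesions, adenoma
regression, or real participation behaviour. Passing tests therefore
demonstrate internal correctness and directionally faithful programme
behaviour, not quantitative agreement with any specific population; the
shipped defaults are surrogates wherever the original fitted values live in
unavailable supplementary material (test characteristics, participation by
age, stage-specific disutilities, calibrated natural-history parameters).

## Known limitations

* One FIT operating point (20 µg/g) via class-wise sensitivities; no
  quantitative haemoglobin model, so cut-off sweeps require re-specifying
  sensitivities.
* Location (colon/rectum) is a label for calibration tabulation only; the
  dynamics are location-blind.
* No probabilistic sensitivity analysis layer; uncertainty exploration is by
  scenario configuration.
* Complications are costed and disutility-weighted but never fatal, and only
  occur with polypectomy.
* A person exits organised screening at the first cancer diagnosis;
  post-treatment surveillance of cancer survivors is not modelled beyond the
  flat follow-up costs.

```{r example, eval = FALSE}
# a small end-to-end run
sc <- run_scenario(scenario_config(seed = 7,
                                   population = list(n_simulated = 25000L)))
sc$cea
sc$bia
```
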