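---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscreen)
```

# The decision problem

`dmscreen` evaluates population screening for type 2 diabetes mellitus
(T2DM) delivered opportunistically at two primary-care tiers of a
Vietnam-like health system: commune health stations (CHS) and district
health centers (DHC). Screening strategies differ by delivery setting,
starting age (30/35/40/45 in the reference grid) and interval (one-off,
annual, 3-yearly), and are compared with no screening from a societal
perspective (medical plus direct non-medical costs) and a provider
perspective (medical costs only). Outcomes are lifetime discounted
costs, life years (LY) and quality-adjusted life years (QALY), combined
into incremental cost-effectiveness ratios (ICER), net monetary benefit
(NMB) at a willingness-to-pay of one GDP per capita (2,715.3 USD/QALY),
and an efficiency frontier.

# The screening cascade

At CHS the cascade is: FINDRISC risk questionnaire, then fasting
capillary glucose (FCG) for questionnaire-positives, then referral to
the district level — subject to an adherence proportion — for one
confirmatory fasting plasma glucose (FPG) test. At DHC it is FINDRISC,
then FPG, then an immediate second FPG at the same visit. Detection of
a truly diseased participant therefore chains the test sensitivities,

$$
p^{CHS}_{detect} = sn_{FINDRISC}\, sn_{FCG}\, a\, sn_{FPG}, \qquad
p^{DHC}_{detect} = sn_{FINDRISC}\, sn^2_{FPG},
$$

with repeated tests treated as conditionally independent given true
status (single-test operating characteristics are all that is
available). Healthy participants who run the full false-positive
cascade are returned to the disease-free state untreated: they incur
the cascade's cost but no downstream consequence. Expected round costs
sum branch probability times branch cost over the tree; under the
societal perspective the setting's per-visit non-medical cost (0.6 USD
at CHS, 1.96 USD at DHC) is added once for the initial visit and, at
CHS, once more for the referral trip. The adherence proportion applies
only to the CHS referral leg; its value is not reported for the
reference setting, so it defaults to 1.0 and is exposed as an ordinary
parameter. Missed referrals still incur the FCG cost but not the
referral-leg costs.

# The cohort model

Five states: normal glucose tolerance (NGT), undiagnosed T2DM (UNDX),
diagnosed T2DM (DX), T2DM with complication (COMP) and absorbing DEAD.
Cycles are one year; the cohort enters at the starting age with the
age-specific prevalence in UNDX and the rest in NGT (already-diagnosed
people are excluded from screening), and the horizon closes at age 100,
where the life table's death probability is forced to 1.

Annual transition probabilities: NGT to UNDX and NGT to DX each 0.0067,
UNDX to DX 0.0352 (clinical detection), UNDX to COMP 0.0231, DX to COMP
0.0140. Background mortality $q_x$ comes from the life table; diabetic
states scale it by relative risks applied on the *rate scale*,

$$ p' = 1 - (1 - p)^{RR}, $$

i.e. the annual probability is converted to a constant hazard, the
hazard multiplied, and converted back. This transformation — not plain
multiplication — reproduces the derived UNDX-to-COMP entry exactly:
$1-(1-0.0140)^{1.40^{1.5}} = 0.0231$ after rounding, whereas
$0.0140 \times 1.40^{1.5}$ rounds to 0.0232.

Mortality risk ratios: DX carries the overall T2DM ratio 1.89; UNDX and
COMP compound it with the per-1%-HbA1c mortality multiplier 1.38 raised
to their HbA1c excess over the diagnosed level (8.5, 9.1 and 7.0 %
respectively), so $RR_{UNDX} = 1.89 \cdot 1.38^{1.5}$ and
$RR_{COMP} = 1.89 \cdot 1.38^{2.1}$. The 1.89 ratio is anchored at the
diagnosed HbA1c of 7.0% — the anchor is not stated by the sources of
these estimates, and this is the only choice under which the diagnosed
state carries exactly the headline ratio.

Within a cycle, death competes first; the surviving mass is allocated to
disease transitions and the residual remains in state (the ordering is
a modelling choice; no ordering is stated for the reference analysis).
In a screening cycle, screening detection and clinical detection of
UNDX combine as independent events,
$p_{UNDX \to DX} = 1-(1-0.0352)(1-p_{detect})$, rather than adding.
Participants detected by screening enter DX without complications.
Both printed NGT incidence rows (to UNDX and to DX) are applied as
separate destination probabilities, as tabulated; if they were meant as
a split of a single incidence this doubles NGT incidence, but the
printed reading is implemented.

# Accumulation, discounting, within-cycle correction

Continuous flows — treatment cost, LY, QALY — are evaluated at the
cycle points, weighted by composite Simpson 1/3 weights
$(1,4,2,\dots,4,1)/3$ (an odd interval count is closed with the 3/8
rule over the final three intervals; weights always sum to the interval
count, and the quadrature is exact for cubics), and discounted at 3%
per year with cycle 0 undiscounted. Screening costs are point-in-time
events: they are discounted with the cycle in which the round occurs
but carry no Simpson weight, since the within-cycle correction
approximates the integral of a continuous flow and a screening round
is not one. Undiagnosed patients accrue the "assumed" undiagnosed
treatment costs (17.9 medical + 99.6 non-medical USD/yr) every cycle
spent undiagnosed.

# Parameters and probabilistic machinery

Every input is a (mean, SE, distribution) triple: beta for
probabilities and utilities, gamma for costs, lognormal for risk
ratios, normal for HbA1c levels, all fitted by method of moments —
the only parameterisation the two printed columns support. Parameters
are drawn independently in the PSA (no correlation structure is
reported; this is a known limitation), with one joint draw shared by
all strategies per iteration (common random parameters, a standard
variance-reduction device).

Two numerical guards apply at the model-facing sampling layer only:
normal HbA1c draws are floored at 4% (values below are not
physiological) and any probability or utility draw leaving $[0,1]$ is
clipped; both events are counted and exposed. The raw distribution
machinery is left untruncated so that fitted moments remain exact —
the floor shifts the sampled UNDX HbA1c mean up by about 0.036 (about
3.6% of draws are affected), which is a deliberate physicality/bias
trade-off confined to the PSA layer.

The dispersion entries of the four primary-data cost rows (e.g. 76,945
beside a 66.0 USD mean) are dimensionally implausible as SEs of a mean;
they are interpreted by default as patient-level variances (USD²) and
converted to SEs of the mean via the collection sample sizes (1631 cost
records, 218 surveys). `param_specs(cost_se_mode = "se")` switches to
the verbatim reading.

One-way DSA bounds follow the stated rules: ±20% for transition
probabilities, prevalence and costs; ±1.96 SE for clinical data and
utilities, clipped to each parameter's domain. Note that the HbA1c SEs
(1.5–2.5 percentage points) are patient-level spreads, so their 95%
intervals are very wide: at the lower bound of the undiagnosed HbA1c
(4.0%) the undiagnosed state becomes *healthier* than the treated one
and the incremental NMB of screening turns negative. The tornado
machinery reports this honestly rather than constraining the bounds.

# Synthetic stand-ins

Two inputs of the reference analysis are not publicly available and are
replaced by explicitly synthetic, clearly labelled generators:

* **Life table.** A single-age period table from the Gompertz–Makeham
  hazard $\mu(x) = c + a e^{bx}$ (defaults $b = 0.095$, $c = 5\times
  10^{-4}$), with $a$ calibrated by root search so that life expectancy
  at birth hits a target — 73.6 years by default, a Vietnam-like value.
  It reproduces the *level* of adult mortality, not the age-profile
  quirks of any national table, so absolute LY/QALY totals carry a
  corresponding systematic uncertainty.
* **Cost / EQ-5D-5L microdata.** Gamma-distributed annual costs (right
  skewed, nonnegative — the same family the cost parameters use; CV
  defaults to 1.5, a typical value for hospital cost data) and survey
  responses drawn per dimension with level weights $\propto s^{L-1}$
  for severity $s$, valued by an additive-decrement tariff stub that
  maps the all-ones profile to exactly 1. The severity reproducing the
  complication-state utility (0.63) is $s = 0.88$, obtained
  analytically from the stub's expected decrement, not by fitting to
  test output. Fidelity to any published national value set is
  explicitly not claimed.

A green test against these stand-ins establishes that the *pipeline* —
aggregation, calibration, estimation, propagation — is correct, not
that the absolute cost/QALY levels match any particular country's
surveillance data.

# What the model does and does not reproduce

With the shipped parameters, adherence 1.0 and the e0 = 73.6 life
table, the model reproduces the qualitative decision structure of the
reference setting: annual screening at CHS is the best-ranked strategy
by incremental NMB at 2,715.3 USD/QALY (followed by the 3-yearly and
annual alternatives), one-off screening buys QALYs at a positive ICER
below the threshold at age 40, and screening never reduces life years.

It does **not** make annual screening cost-saving. Under the shipped
cost structure this is arithmetically impossible: earlier diagnosis
moves person-years from the undiagnosed state (117.5 USD/yr societal)
to the diagnosed state (294.1 USD/yr), a 176.6 USD/yr increase, while
the complication-rate differential it buys (0.0231 vs 0.0140 per year)
avoids far too few complication-years (487.2 USD/yr) to offset it —
roughly 40 USD of complication cost is avoided per 400 USD of added
diagnosis cost in the base case. Reported settings in which annual
screening dominates therefore require a different cost configuration
(e.g. much higher complication costs or progression rates, or lower
diagnosed-treatment costs) than the one tabulated here; the acceptance
test asserting dominance is left failing rather than tuned.

# Numerical and degenerate-input choices

* Zero-SE parameters are point masses; the degenerate PSA (all SEs 0)
  reproduces the deterministic base case to 1e-9.
* `adjust_probability` rejects p = 1 (the hazard is undefined); the
  life-table closure row is handled upstream by forcing death.
* Competing exits exceeding probability 1 among survivors are rescaled
  proportionally with a warning (unreachable at default parameters).
* NMB ranking breaks exact ties by lower cost, then identifier, and
  flags them; the frontier drops strong dominance first, then extended
  dominance until stepwise ICERs strictly increase.
* CEAC ties (equal maximal NMB in a draw) split probability mass
  equally, keeping the curves a partition of unity.
* Starting ages between the tabulated prevalence ages interpolate
  linearly; outside the range the nearest value is used.
* All randomness flows through a single integer seed per entry point.

# Known limitations

No prediabetes state, no tunnel states for complication duration, no
sex stratification, independent PSA draws, a single exchange-rate
constant, and a mortality stand-in calibrated to one summary statistic.
These mirror the scope of the reference decision problem; the
generator defaults are stated above and are not adjusted to test
outcomes.
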