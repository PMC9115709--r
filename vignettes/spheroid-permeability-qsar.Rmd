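---
title: "Methods: spheroid permeability values and descriptor-based QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spheroid permeability values and descriptor-based QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidperm)
```

## The measurement model

A drug screened against three spheroid types — the stroma/cancer co-culture
(`multicellular_AM`) and the two monocultures (`mono_ASC`, `mono_MDA`) — gives
one luminescence pair per spheroid: a treated signal and the matched untreated
control of the *same* composition (each spheroid type scales luminescence
differently, so controls are never shared across compositions). Viability is
the treated/control ratio and efficacy its complement:

$$\text{efficacy} = 1 - \frac{\text{signal}_{treated}}{\text{signal}_{control}}.$$

Both are stored as fractions throughout; percent formatting is left to
reports. Efficacies below zero (treated wells brighter than control, i.e.
growth under treatment) are retained with a warning rather than clipped:
clipping would truncate the low tail of the response and bias the regression.

The permeability value contrasts the co-culture with the monoculture mean:

$$PV = \mathrm{Eff}_{A:M} - \tfrac12\,(\mathrm{Eff}_{ASC} + \mathrm{Eff}_{MDA}).$$

A low PV means the multicellular spheroid blocked a drug that works on either
cell type alone. With the default replicate-level aggregation each (drug,
replicate) triple of efficacies yields one PV, so the 16-drug, 3-replicate
design gives 48 records; this replicate-level reading of the 48-record design
is flagged in pipeline metadata whenever the regression runs, and a per-drug
mean aggregation is available.

## Drug-likeness and permeability annotations

PVs are stratified by boolean per-drug labels and compared with an unpaired
two-sample t-test (equal-variance by default, Welch available). Two
degenerate situations are reported rather than refused: identical group
values give $t = 0$, $p = 1$; zero within-group variance with distinct means
is flagged `degenerate` with $p = 0$.

* **Rule of Five** counts violations of MW > 500 Da, logP > 5, HBD > 5,
  HBA > 10 (strict inequalities, so boundary values do not violate). The
  default allowance is zero violations — "satisfying the rule" is read
  strictly — with `max_violations = 1` available for the common one-violation
  reading.
* **Ghose filter** (160 ≤ MW ≤ 480, −0.4 ≤ logP ≤ 5.6, 40 ≤ MR ≤ 130,
  20 ≤ heavy atoms ≤ 70) and **Veber's rule** (ROTB ≤ 10, PSA ≤ 140 Å²) use
  inclusive bounds, matching their original phrasings.
* **Unweighted QED** maps eight descriptors through the published
  asymmetric-double-sigmoid desirability functions (parameters shipped
  verbatim as package constants, each normalised by its tabulated maximum)
  and combines them as an equal-weight geometric mean. A compliance cutoff
  is not part of the QED definition; the package defaults to 0.5 and records
  the choice in run metadata. QED requires all eight inputs — there is no
  silent subset QED.
* **PAMPA** permeability is the linear model
  $0.42\,\log P - 0.26\,|pK_a - pH| - 1.11\,SA_{HA} - 1.01\,SA_{HD} - 4.93$
  with the strict cutoff −6.14 separating low from high permeability. Two
  conventions are configuration, not constants of nature: the working pH
  (default 7.4, physiological) and the surface-area convention. $SA_{HA}$ and
  $SA_{HD}$ enter as *fractions* of total molecular surface area in [0, 1];
  with absolute areas (tens to hundreds of Å²) the −1.11/−1.01 coefficients
  would drive predictions to absurd magnitudes. For multiprotic drugs the
  single `pka` field should hold the tabulated value closest to the working
  pH, since the model takes one $|pK_a - pH|$ term.
* **Caco-2** classes are ingested labels (`permeable`/`impermeable`), never
  computed or imputed; unmatched drugs are `unknown`. This keeps the pipeline
  free of any web dependency on ADMET databases.

## The QSAR regression

The response is the replicate-level PV; the candidates are the nine tabulated
descriptors (MW, logP, logS, HBA, HBD, PSA, rotatable bonds, molar
refractivity, polarizability), entering untransformed. Descriptors are
primarily *ingested* from tables rather than computed: computed logP/PSA
differ across toolkits and would silently change the regression, so the
structure-based path (`descriptors_from_structure()`, Open Babel backend) is
optional and every value it fills is flagged with `computed` provenance.

`qsar_fit()` is ordinary least squares via `stats::lm`, with per-coefficient
t/p values, the overall F-test, $R^2 = 1 - SS_{res}/SS_{tot}$ and
$RMSE = \sqrt{SS_{res}/n}$. The $1/n$ convention (not $1/(n-p)$) makes RMSE a
plain root-mean-square residual, pairing naturally with $R^2$;
`rmse_df_adjust = TRUE` switches to the degrees-of-freedom version. A
rank-deficient design is a hard error naming the dependent columns rather
than a silently dropped term.

`qsar_forward_stepwise()` starts from the intercept-only model and at each
step admits the candidate with the smallest entering-coefficient p-value,
strictly below `p_enter` (default 0.05); ties are broken by the first minimum
in candidate order, and an AIC criterion is available. The threshold is
strict, so `p_enter = 0` returns the intercept-only model and `p_enter = 1`
admits every candidate, which makes the "retain all nine" configuration — the
behaviour the published screen's stepwise run evidently produced, since its
final equation keeps all nine descriptors — an explicit, reproducible
setting rather than a side effect of an unstated software default.

Validation follows two routes:

* `split_pareto()` — one random 80/20 split with validation size
  $\lfloor 0.2n \rfloor$ (48 → 39/9).
* `qsar_cross_validate()` — k disjoint folds (sizes differing by at most one;
  48 records and $k = 5$ give folds of 10,10,10,9,9 and training complements
  of 38 or 39), fit on each complement, evaluated on both partitions.
  Per-fold validation $R^2$ is computed about the held-out fold's own mean,
  and aggregates are unweighted fold means. Because the $R^2$ of a 9–10
  record fold is extremely unstable, `pooled = TRUE` additionally evaluates
  all held-out predictions together; the pooled value is what the package's
  own acceptance checks summarise. With $k = n$ the procedure reduces to
  leave-one-out (per-fold $R^2$ is then undefined and reported `NA`; pooled
  metrics cover that case).

All split and fold randomness flows from explicit integer seeds, and the
pipeline fans one top-level seed out into fixed per-stage sub-seeds.

## What the synthetic screen emulates

`sim_config()` fixes the study conditions: 16 drugs × 3 replicates, 5%
multiplicative (lognormal, unit-mean) luminescence noise, monoculture
efficacies uniform in [0.3, 0.7], control wells lognormal around 10⁵ counts,
and the published nine-coefficient set as the generative truth for PV.

One construction deserves emphasis. Applied to *independently* sampled
drug-plausible descriptors, the ground-truth coefficients produce PVs
spanning roughly ±2 — the MW term alone contributes 0.5–3 across 150–900 Da —
while real screens put PVs on a fractional ~0–0.15 scale. Real descriptor
tables resolve this through strong collinearity: molecular weight,
refractivity and polarizability rise together, and their opposite-signed
partial coefficients cancel along that size axis. The generator reproduces
the cancellation constructively: eight descriptors are drawn uniformly within
their windows, a latent permeability deviation $t \sim N(0, 0.052^2)$ is
drawn, and polarizability is *derived* so that the linear model evaluated on
the finished row returns exactly $0.075 + t$. Draws pushing polarizability
outside (2, 300) Å³ are rejected and redrawn. The signal scale 0.052 and
centre 0.075 follow from the published fit quality (RMSE 0.0347 at
$R^2 = 0.69$ implies a between-drug signal SD of
$0.0347\sqrt{0.69/0.31} \approx 0.052$).

The replicate noise default `pv_noise_sd = 0.0375` was calibrated once by
bisection so that the *expected* training $R^2$ of the nine-descriptor fit on
a default 48-record screen is 0.69 (400 simulated screens per bisection
step), then frozen. Half the drugs are drawn from deliberately rule-violating
windows (always breaching the MW threshold, often others) so that every
rule-compliance stratification has both groups populated; `violation_fraction = 0` yields a
fully Rule-of-Five-compliant table.

What the generator does **not** emulate — and therefore what passing tests do
not certify about real screens: the true covariance structure of drug
descriptors beyond the engineered size collinearity (so the *count* of
significant descriptors in a synthetic fit need not match a real screen's
five of nine, even though the five strong drivers are recovered); plate
position effects, edge evaporation or batch drift in luminescence;
dose–response behaviour (each drug is screened at one fixed concentration);
and any mechanistic ECM transport. Synthetic masks are clean disks and
ellipses with analytic ground truth, not segmented microscopy.

## Morphometrics

From area and perimeter: circularity $4\pi A / P^2$, sphericity index
$\sqrt{\text{circularity}}$, equivalent diameter $2\sqrt{A/\pi}$. Circularity
and its square root are both reported side by side because the two are easy
to conflate and published shape panels rarely say which was plotted; values
marginally above 1 from digitization are reported as-is with a warning, never
clamped.

Mask measurement: the largest 8-connected component is kept (others counted
and messaged), area is the pixel count, and the perimeter uses a chain-code
estimator — axial steps weight 1, diagonal steps $\sqrt 2$ — scaled by the
analytic correction $\pi / (8(\sqrt 2 - 1)) \approx 0.9481$. The raw
$(1, \sqrt 2)$ chain length overestimates a smooth contour's perimeter by
about 5.5% on average over orientations, which alone would push a digitized
disk's sphericity index down to ~0.95; the corrected estimator restores the
circle fixed point to within digitization error (the package's acceptance
check bounds the disk SI within 2% of 1 at radius 100 px). Roundness is
$4A/(\pi \cdot \text{major axis}^2)$ with the major axis from second-order
pixel moments, the standard image-analysis definition. Degenerate masks:
an all-background mask is a `no_object` error; a single-pixel component falls
back to the circle-equivalent perimeter.

## Numerical and interface conventions

* Errors are classed conditions (`spq_error_schema`, `spq_error_missing_data`,
  `spq_error_pairing`, `spq_error_collinearity`, `spq_error_feasibility`, ...)
  so callers can distinguish failure modes; soft screens (descriptor
  plausibility ranges) warn without rejecting.
* Missing optional descriptor columns stay absent — never coerced to zero —
  and unknown columns pass through as metadata (rejected under
  `schema_policy = "strict"`).
* Text artifacts are written with 6 significant digits; JSON artifacts keep
  full precision; no output carries a timestamp, so identical configurations
  produce byte-identical runs.
* Problem sizes in the test and acceptance suites (48-record screens; 50-seed
  cross-validation summaries; 200-replication coverage and round-trip checks;
  radius-100 masks) were chosen as the smallest sizes at which the targeted
  expectations are stable.

## Known limitations

* The package ships no per-drug experimental dataset: the original screen's
  per-drug descriptor and PV data are not publicly deposited, so all
  end-to-end numbers are computed on the synthetic emulation anchored to the
  published coefficients. Loading a real descriptor/PV table through
  `read_descriptor_table()` / `read_viability_table()` reproduces the full
  analysis unchanged.
* `alerts_count` (structural alerts) is an input column; SMARTS-based alert
  matching, pKa prediction, 3D surface areas and conformer generation are out
  of scope.
* The stepwise entry criterion of the original screen's software is unknown;
  both the p-to-enter and AIC criteria are provided and the configuration is
  echoed in every artifact.
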