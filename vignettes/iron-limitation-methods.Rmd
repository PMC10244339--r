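---
title: "Methods: iron speciation and kelp physiology in ion-buffered media"
author: "kelpfe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: iron speciation and kelp physiology in ion-buffered media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpfe)
```

kelpfe analyses iron-limitation experiments on kelp cultured in EDTA
ion-buffered seawater. This vignette documents the models the package
implements, their assumptions, the tunable parameters, the numerical
choices, and the design decisions made where the design was genuinely
open.

## The Fe–EDTA ion buffer model

Culture experiments cannot dose inorganic iron directly: at seawater pH,
Fe(III) hydrolyses and precipitates. The standard workaround is an ion
buffer — a large excess of the synthetic chelator EDTA that holds the
free (inorganic) iron concentration, written Fe′, at a small, stable
fraction of the total dissolved iron. Fe′, the sum of dissolved
inorganic Fe(III) species, is the accepted proxy for bioavailable iron.

The conditional dissociation of FeEDTA chelates has a thermal and a
photochemical component:

$$K'(\mathrm{light}) = K_d'(\mathrm{dark}) + K_{h\nu} \cdot I_{h\nu}$$

where $I_{h\nu} \in [0,1]$ is a dimensionless irradiance factor folding
in light level and photoperiod. The defaults
($K_d'(\mathrm{dark}) = 4.98\times10^{-8}$,
$K_{h\nu} = 8.01\times10^{-7}$, $I_{h\nu} = 0.163$) describe an
Aquil-type medium at 13 °C, pH 8.05, under 150 µmol photons m⁻² s⁻¹ on
a 14:10 light:dark cycle, and give
$K'(\mathrm{light}) = 1.804\times10^{-7}$. $I_{h\nu}$ is an input
constant: its derivation from irradiance and photoperiod is not
reproduced here, because only the value, not the formula, is available
for these conditions.

With essentially all iron chelated (1:1 Fe:EDTA), the free chelator is
$\mathrm{EDTA_T} - \mathrm{Fe_T}$ and

$$\mathrm{Fe'} = K'(\mathrm{light})\,
  \frac{\mathrm{Fe_T}}{\mathrm{EDTA_T} - \mathrm{Fe_T}}$$

The Fe′:Fe(tot) ratio rises with the iron addition because free
chelator is consumed: from $1.80\times10^{-3}$ at the background-only
medium to $3.01\times10^{-3}$ at the 40 µM addition in the standard
design (100 µM EDTA, 7.25 nM background dFe). Other Aquil trace metals
(~0.6 µM combined) are ignored in the chelator balance; their effect on
free EDTA is below 1%.

### Accuracy of the closed form

`fe_prime_mass_balance()` solves the complete two-balance system
($\mathrm{Fe_T} = \mathrm{Fe'} + \mathrm{FeEDTA}$,
$\mathrm{EDTA_T} = \mathrm{EDTA_{free}} + \mathrm{FeEDTA}$) by fixed-point
iteration to a $10^{-12}$ relative tolerance. The closed form neglects
Fe′ in both balances, so it overstates the reference Fe′ by
approximately $\mathrm{Fe'}/\mathrm{Fe_T} + \mathrm{Fe'}/\mathrm{EDTA_{free}}$
— i.e. by the ratio itself, 0.18% at the lowest and 0.50% at the
highest treatment. This is an intrinsic property of the approximation,
not a numerical artefact: no tolerance below the Fe′:Fe(tot) ratio
(~$2$–$3\times10^{-3}$) can be met by the closed form. Since treatments
are *labelled* by closed-form Fe′ (the field convention), the package
uses the closed form throughout and keeps the iterative solver as a
reference for validation.

### Solubility partition

Above ~700 pM, Fe′ exceeds its solubility and iron oxyhydroxide
colloids form. All but the background-only treatment in the standard
design cross this limit. Because colloids may still be utilised by
kelp, the nominal Fe′ is retained as the treatment label, and the
result also reports the effective (capped) dissolved pool and the
colloidal remainder — a reporting partition, not a change of label.

### Design mode and its guard

`invert_fe_total()` is the exact algebraic inverse,
$\mathrm{Fe_T} = \mathrm{Fe'_{target}} \cdot \mathrm{EDTA_T} /
(K' + \mathrm{Fe'_{target}})$, so forward/inverse round trips hold to
machine precision. Because this expression approaches but never reaches
$\mathrm{EDTA_T}$, a naive bound on $\mathrm{Fe_T}$ alone can never
fire; the buffer-exhaustion guard therefore requires chelated *plus*
inorganic iron to stay below total EDTA
($\mathrm{Fe_T} + \mathrm{Fe'_{target}} < \mathrm{EDTA_T}$), which also
rejects targets far outside the buffer's validity.

### Open-ocean Fe′

Natural seawater has no EDTA; its inorganic fraction is set by natural
organic ligands. `ocean_dfe_to_fe_prime()` is a documented
approximation: a power law through the two anchor values typical of
Southern Ocean surface waters (0.1 nM dFe → 0.11 pM Fe′; 0.6 nM →
1.49 pM), interpolated in log–log space and extrapolated on the same
line, with results flagged `approximate` and a warning beyond 1 nM dFe.
It should not be used as a ligand model.

### A note on one printed ratio

For these constants the model gives a low-end Fe′:Fe(tot) ratio of
$\approx 1.80\times10^{-3}$; a value of $1.18\times10^{-3}$ is
sometimes quoted for the same conditions. The two are irreconcilable
given $K'(\mathrm{light})/\mathrm{EDTA_T} = 1.8\times10^{-3}$ as the
dilute limit; the quoted value is plausibly a digit transposition of
1.81. The package's validation therefore anchors on the high-end ratio
($2.99\times10^{-3}$) and the treatment Fe′ values, all of which the
model reproduces within 1%.

## Physiological rates

All rate calculations are two-endpoint differences — initial and final
bottles, matching how the assays are sampled — normalised by flask
volume, elapsed time and biomass:

* growth: $(SA_F - SA_I)/d$ in cm² d⁻¹ over the 14-day run; negative
  values are meaningful tissue loss;
* DOC flux: $(C_F - C_I) \cdot V / (m_{DW} \cdot t)$ in
  µmol C gDW⁻¹ h⁻¹; positive = release, negative = net uptake;
* O₂ fluxes: same normalisation per gram wet weight; the light phase
  reports production, the dark phase consumption as a positive
  respiration (O₂ fluxes are normalised identically to DOC; the flask
  volume enters both);
* Fv/Fm $= (F_m - F_o)/F_m \in [0,1]$;
* soluble nitrate: $(N_1 + N_2) \cdot V_{extract} / WW$ over two
  sequential boiling-water extractions (default 0.02 L tubes);
* C:N on atomic weights fixed at C = 12.011, N = 14.007;
* chlorophyll a + c from extract absorbances via configurable linear
  coefficient sets (`seely_coefficients()` ships the standard
  brown-algal DMSO/90%-acetone calibration); the estimate is linear in
  the absorbances and normalised to the extracted tissue's wet mass.

Flask volume defaults to 0.25 L (250 mL bottles) but is a per-record
field; the volume displaced by the disc is ignored. Missing raw fields
propagate as `NA` in the affected metric only — never as silent zeros.

## Dose–response fit

Growth against Fe′ is fitted with the rectangular hyperbola
$V = V_{max} S / (K_m + S)$ by bounded Levenberg–Marquardt least
squares ($V_{max}, K_m \ge 0$; up to $10^4$ function evaluations;
convergence tolerance $10^{-10}$), pinned so that results are
reproducible rather than dependent on an interactive fitter.
Initialisation is deterministic: $V_{max,0} = \max(v)$ and $K_{m,0}$
the substrate level at half of $V_{max,0}$ by linear interpolation of
the mean response profile (median substrate level when the profile
never crosses half-max). $R^2 = 1 - SSE/SST$, adjusted with the Wherry
form $1 - (1 - R^2)(n-1)/(n-p-1)$, $p = 2$ — stated explicitly because
"adjusted R²" is otherwise ambiguous. Non-convergence sets a flag and
warns; it is never silent. The default fits per-replicate points
(n = 42 in the standard design); `means = TRUE` collapses to treatment
means first, since either convention is defensible and published fits
do not always say which was used.

## Treatment statistics

`fe_anova()` chains the stages used for every response: normalizing
transform where needed, one-way ANOVA, Tukey HSD when the global test
is significant, and a compact letter display.

**Transform selection.** Candidates are identity, log, square root,
Box–Cox (λ profiled on a 0.05 grid over [-2, 2] via `MASS::boxcox`)
and an ordered-quantile (rank-to-normal, Blom offsets) map. Each is
scored by the Shapiro–Wilk W of the residuals of a one-way fit on the
transformed scale; largest W wins, identity preferred on numerical
ties. Log-family candidates are skipped (never auto-shifted) when
values are non-positive. The ordered-quantile map would trivially win
any such contest — it sends *any* continuous sample to near-perfect
normal scores — so it is held back as a fallback, entering only when
every parametric candidate leaves a significant Shapiro–Wilk departure
(p < 0.05). Because the choice of transform can move the F statistic,
the untransformed ANOVA is always reported alongside the transformed
one, and the selection is deterministic and logged in the result.

**Letters.** The compact letter display uses the insert-and-absorb
algorithm: a single letter covering all treatments is split by each
significant pair and redundant letters are absorbed. Two treatments
share a letter iff they are not significantly different at α (default
0.05). The test suite checks both this consistency property and
minimality of the letter count against an exhaustive enumeration on
small instances.

Degrees of freedom are reported as (between, within); for the
seven-treatment design the between-groups df is 6.

## Synthetic experiments

`generate_replicates()` emulates the study design — seven Fe′ levels ×
six replicate discs plus four no-seaweed controls (split between the
lowest and highest level) — with the assumed statistical structure:

* growth means follow $V_{max} S/(K_m + S)$ with mean-preserving
  multiplicative lognormal noise (CV default 0.2); defaults
  $V_{max} = 0.5$ cm² d⁻¹ and $K_m = 5$ nM put saturation just above
  the 9.56 nM level. These are synthetic choices, not estimates from
  any particular experiment;
* DOC flux has a threshold structure: uniform in [0.43, 1.56]
  µmol C gDW⁻¹ h⁻¹ (release) at levels at or below the 30 nM
  limitation threshold, uniform in [−0.4, −0.05] (net uptake) above
  it. Fragmenting replicates (probability 0.25 at limited levels) draw
  from the upper half of the release band, mimicking enhanced release
  from disintegrating tissue;
* photosynthesis, respiration, chlorophyll, Fv/Fm, C:N and soluble
  nitrate have treatment-dependent means, elevated above the
  threshold; the default photosynthesis (0.05 vs 2.9 µmol O₂ gWW⁻¹
  h⁻¹) and respiration (1.0 vs 2.95) means reproduce ~5700% and ~195%
  replete-vs-limited contrasts;
* raw endpoint columns are constructed by inverting the rate
  equations, so `replicate_rates()` recovers the drawn rates exactly;
  noise models are multiplicative lognormal for strictly positive
  quantities (keeping masses and areas positive without truncation)
  and bounded/truncated draws for sign-constrained ones.

Everything is reproducible from the seed; generation saves and
restores the caller's RNG state. Configurations round-trip losslessly
through JSON (17 significant digits — full double precision).

What the generator does **not** emulate: within-run dynamics (all
quantities are endpoints), bacterial DOC consumption as a process
(only its net sign), covariance between assays beyond the shared
limited/replete split, instrument error structure, and any carry-over
between the three-day medium refreshes. Passing tests on synthetic
data therefore validate the computational chain and its statistical
behaviour, not biological effect sizes.

`recover_parameters()` closes the loop: generate → rates → refit,
summarising bias and spread of $\hat V_{max}, \hat K_m$. With zero
noise the recovery is exact; at CV = 0.2 the median $\hat K_m$ over
200 simulated experiments stays within ±50% of truth, and doubling the
replication does not widen the interquartile range. The validation
suite uses 200 simulations and 220×220 grid-search oracles — sizes
chosen to make the checks sharp while keeping the whole suite quick to
run.

## Gradient context

`load_gradient()` validates a compilation of surface dFe against
distance offshore and classifies records by a 50 km cutoff — the band
where offshore transect data take over from coastal site surveys. The
bundled table (`kelpfe_example_gradient()`) is an illustrative
synthetic stand-in spanning the published extremes (573 nM in a
river-fed bay at the coast down to < 0.33 nM in Southern Ocean surface
water); it is labelled synthetic in its filename and should be replaced
with a real compilation for substantive use. `fold_limitation()` is
the dimensionless quotient required/available; with the oceanic Fe′
window 0.11–1.49 pM and a 45.2 nM requirement the shortfall is
3.0×10⁴- to 4.1×10⁵-fold — three orders of magnitude beyond parity.

## Known limitations

* Single-metal, single-ligand chemistry: no Zn/Cu/Mn/Co speciation, no
  re-derivation of conditional constants for other temperatures or pH.
* The open-ocean Fe′ conversion is an anchored interpolation, not a
  ligand model.
* The statistics stage offers no mixed models, repeated measures or
  nonparametric fallbacks; it reproduces the fixed one-way design.
* Pigment coefficients are shipped as defaults but are configuration
  data; calibrations differ between laboratories.
* Exact replication of published F statistics from raw data can hinge
  on which normalizing transform was applied; reporting both
  transformed and untransformed F makes any such mismatch auditable
  rather than hidden.
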