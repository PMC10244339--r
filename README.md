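# kelpfe

Iron speciation and physiology of kelp in EDTA ion-buffered culture
media.

Dissolved iron (dFe) limits primary production across much of the open
ocean, and proposals to grow nearshore kelps offshore at scale (ocean
macroalgal afforestation) collide with that scarcity. Quantifying a
kelp's iron requirement takes a chain of computations: designing
ion-buffered media that clamp inorganic iron (Fe′) at chosen levels,
converting raw incubation measurements into physiological rates,
fitting the saturation curve of growth against Fe′, comparing
treatments statistically, and placing the requirement against the
coastal-to-ocean dFe gradient. kelpfe implements that chain as a
tested R package for experimentalists and modellers working on
trace-metal limitation of macroalgae.

## The models at the core

**Fe–EDTA buffer.** In a medium with total chelator
EDTA<sub>T</sub> in large excess, inorganic iron follows

    K'(light) = Kd'(dark) + Khv · Ihv
    Fe' = K'(light) · FeT / (EDTA_T − FeT)

with conditional constants for the seawater matrix, temperature, pH and
light regime. Defaults (Kd′(dark) = 4.98×10⁻⁸, Khv = 8.01×10⁻⁷,
I<sub>hv</sub> = 0.163, 100 µM EDTA, 7.25 nM background dFe) describe
an Aquil-type medium at 13 °C and pH 8.05 under a 14:10 photoperiod.
Fe′ above the ~700 pM solubility limit is partitioned into an
effective dissolved pool and an oxyhydroxide colloid remainder. The
model inverts exactly for medium design, and a full mass-balance
fixed-point solver is included as a reference.

**Dose–response.** Growth versus Fe′ is fitted with the
Michaelis–Menten rectangular hyperbola V = V<sub>max</sub>·S/(K<sub>m</sub>+S)
by bounded nonlinear least squares with a documented, deterministic
initialisation.

**Treatment statistics.** Normalizing-transform selection (identity /
log / √ / Box–Cox / ordered-quantile, scored on residual normality),
one-way ANOVA, Tukey HSD and a compact letter display in which
treatments sharing a letter are not significantly different.

**Synthetic experiments.** A seeded generator reproduces the
7-treatment × 6-replicate (+ 4 control) design with Michaelis–Menten
growth means and a threshold DOC structure, so the whole pipeline runs
and validates without external data.

## Worked example

```r
library(kelpfe)

# medium chemistry for the seven standard iron additions
treatment_speciation()
#> Fe-EDTA buffer speciation (7 media)
#>  fe_total fe_prime   ratio colloidal
#>   7.25 nM  13.1 pM 0.00180         -
#>   1.01 uM  1.84 nM 0.00182   1.14 nM
#>   2.51 uM  4.64 nM 0.00185   3.94 nM
#>   5.01 uM  9.51 nM 0.00190   8.81 nM
#>     10 uM  20.1 nM 0.00200   19.4 nM
#>     20 uM  45.1 nM 0.00225   44.4 nM
#>     40 uM   120 nM 0.00301    120 nM

# a synthetic experiment through the full analysis
reps <- generate_replicates(synthetic_config(seed = 42))
report <- run_pipeline(reps, gradient = kelpfe_example_gradient())
report
#> kelpfe analysis report
#>   replicates: 46 rows ( 4 controls )
#>   treatments: 13.1 pM, 1.84 nM, 4.64 nM, 9.51 nM, 20.1 nM, 45.1 nM, 120 nM
#>   growth fit: Vmax = 0.46, Km = 4.2 nM, adj R2 = 0.819
#>   doc_flux: F(6, 35) = 26.948, p = 9.465e-12 [identity]
#>   ...
#>   offshore limitation: 73342- to 1126116-fold
```

The speciation table shows each addition's total iron, the inorganic
fraction it buffers to (rising from ~0.0018 to ~0.0030 as free EDTA is
consumed), and the colloidal excess over the solubility limit. The
report then carries the growth saturation fit (here recovering the
generator's V<sub>max</sub> = 0.5 cm² d⁻¹, K<sub>m</sub> = 5 nM within
noise), the per-response ANOVA F values with df = 6 between the seven
treatments, and the fold by which offshore Fe′ falls short of the
45.2 nM requirement — over a thousandfold everywhere beyond the shelf.

The `analysis/` directory holds the same workflow as numbered
narrative scripts (`01_speciation.R` … `06_gradient.R`), each writing
its tables under `results/`.

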