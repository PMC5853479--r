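---
title: "Methods: comparing membrane-transport physiology of bundle-sheath and mesophyll protoplasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing membrane-transport physiology of bundle-sheath and mesophyll protoplasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protophys)
```

`protophys` compares two leaf cell types — bundle-sheath cells (BSCs), the
layer wrapping the vasculature and gating xylem-to-mesophyll transport, and
mesophyll cells (MCs) — along three experimental axes: whole-cell
voltage-clamp analysis of their K⁺ channel gating, two-group expression
filtering, and ratiometric membrane-potential imaging. This vignette is the
package's account of the underlying models, the synthetic-data generators
that close the testing loop, and the numerical and design choices made
where more than one reasonable option existed.

## 1. The gating model

Whole-cell membrane conductance is modelled as a voltage-invariant basal
component plus a single homogeneous population of voltage-gated channels
with two-state Boltzmann statistics:

$$G'(E_M) = G'_b + \frac{G'_{max} - G'_b}{1 + \exp\!\big(z F (E_M - E_{1/2}) / RT\big)},
\qquad
P_O(E_M) = \frac{1}{1 + \exp\!\big(z F (E_M - E_{1/2}) / RT\big)}.$$

* `G'` — specific conductance, mS·cm⁻² (whole-cell conductance divided by
  the spherical membrane area $\pi d^2$).
* `E_1/2` — half-activation voltage, mV; $P_O(E_{1/2}) = 0.5$ exactly.
* `z` — effective gating charge, dimensionless; with $z > 0$ the channels
  open on hyperpolarization (inward rectification), so $G'$ and $P_O$ fall
  monotonically with depolarization.
* `G'_max_net = G'_max − G'_b` — the gated part of the conductance.

The convenience constructors `bsc_params()` and `mc_params()` carry the
group-mean parameter sets used throughout the package as ground truth for
simulation: BSC `G'_b` 0.8, `G'_max` 1.75 mS·cm⁻², `E_1/2` +14.5 mV,
`z` 1.46, diameter 27.4 µm; MC 0.43, 1.15 mS·cm⁻², −6.5 mV, 1.03, 43.5 µm;
reversal potential −31 mV in the low-K (5 mM) bath. The 21 mV separation in
`E_1/2` is the physiologically interesting difference: at the same membrane
potential a larger fraction of BSC channels is open, and combined with a
more hyperpolarized BSC membrane (section 4) it can drive simultaneous,
oppositely directed K⁺ fluxes in the two cell types —
`predict_flux_direction()` reports the sign of
$-\,[G'_b + G'_{max,net}P_O(E_M)]\,(E_M - E_K)$ for exactly this argument.

### Temperature and thermal voltage

The default temperature is 295.15 K (22 °C, the bottom of the 22–24 °C room
range the protocols assume), giving $RT/F = 25.43$ mV. All gating functions
also accept an explicit `thermal_voltage_mV`; with the commonly quoted
round value 25.7 mV (≈ 25 °C) the group-mean fits give whole-percent open
fractions of 89% (BSC) and 66% (MC) at −23 mV, and either choice rounds to
the same whole percents. Temperature is configurable everywhere it enters.

### Liquid junction potentials

Command voltages are nominal amplifier values; true membrane potentials are
obtained by adding the bath-specific liquid junction potential (LJP):
−23 mV for the low-K bath, −14 mV for the 30 mM K⁺ bath. The LJP is an
*input* per bath (`correct_ljp()` refuses to guess): a Henderson-equation
calculator would drag in ion-mobility tables without improving anything the
package tests. Whether to correct is never optional — a missing LJP is a
hard error, because a 23 mV systematic offset is larger than every effect
of interest.

## 2. The recording simulator

`simulate_recording()` emulates the standard sweep family: 1 s square
pulses stepping +120 → −160 mV (nominal) in −20 mV increments, each
followed by a 30 ms conductance-testing ramp from +70 to −70 mV, sampled at
2 kHz, holding at a nominal 0 mV. The open fraction relaxes first-order
toward the Boltzmann steady state at the pulse potential and is **frozen**
during the ramp; total current is
`area × [G'_b + (G'_max − G'_b)p] × (E − E_rev)` plus Gaussian noise
(default SD 5 pA, a realistic filtered whole-cell noise floor).

Deliberate simplifications, chosen once:

* **Kinetics.** No activation/deactivation time constants are established
  for these currents; the only constraint is that a 30 ms ramp does not
  change the number of open channels. A voltage-independent τ = 100 ms
  satisfies that with a 3.3× margin while letting a 1 s pulse settle to
  within $e^{-10}$ of steady state. τ is a free simulation parameter; if a
  protocol violates the frozen-gate margin (ramp ≥ τ) the simulator sets a
  warning flag rather than silently producing curved ramps.
* **One channel population per cell.** Real currents may superpose
  differently modified channel pools; a mixture would only blur `E_1/2`
  without changing anything the pipeline estimates, so the default is a
  single population.
* **No capacitive transients or series-resistance error.** Experimental
  recordings compensate both; simulating and then removing them would test
  the simulator, not the analysis.
* **Independent sweeps.** The 20–30 s inter-sweep interval re-equilibrates
  the gate at holding, so sweeps are generated independently.

Recordings serialize to a plain-text dialect (a YAML metadata document plus
a TSV of `time_ms`, `command_mV_nominal`, `current_pA`, `sweep_index`) via
`write_recording()` / `read_recording()`.

## 3. The electrophysiology analysis chain

`extract_gv_curve()` fits each sweep's trimmed ramp by OLS in the
current–voltage plane; the slope is the whole-cell conductance set by the
preceding pulse, and division by $\pi d^2$ gives `G'`, keyed by the
corrected pulse potential. Numerical choices:

* **Ramp trimming**: the first and last 2 ms of each 30 ms ramp are
  discarded (settling), configurable.
* **Linearity gate**: points with ramp $R^2 < 0.99$ are flagged and
  excluded from fitting — on a linear fit this catches both noise
  catastrophes and frozen-gate violations.
* **Degenerate ramps**: a constant trace is an exact zero-slope line
  ($R^2$ defined as 1), not a division-by-zero.

`fit_boltzmann()` runs bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) in the parameterization
(`G'_b`, `G'_max_net`, `E_1/2`, `z`) with box bounds `G'_b ≥ 0`,
`G'_max_net ≥ 0`, `0 < z ≤ 5`, so `G'_max ≥ G'_b` is structural and the
reported `G'_max_net` equals `G'_max − G'_b` exactly. Initialization:
`G'_b` = min, `G'_max_net` = range, `E_1/2` = voltage of the point nearest
mid-conductance, `z = 1`. Fewer than six usable points, a flat curve, or
LM failure yield a `converged = FALSE` object with a message — never a
crash or a silent `NaN` — and such fits are dropped (with a message) from
group averaging.

`estimate_reversal()` exploits the geometry that all ramp lines cross at
$(E_{rev}, 0)$: it fits a line per ramp, forms all pairwise intersection
voltages among ramps whose slopes differ by more than 5% of the largest
absolute slope (near-parallel pairs produce wild intersections), and takes
the **median**, reporting the dispersion. No estimator is canonical here;
the median over floor-filtered pairs is robust to a single bad ramp and
reduces to the exact answer in noiseless constructions.

`compare_groups()` averages per-cell best-fit parameters within cell type
(fit-then-average — averaging curves first would bias `z` downward) and
applies a two-sided **Welch** t-test per parameter. The unequal-variance
form was chosen over the pooled form because group sizes and variances
differ; for the expression module, where the classical two-group ANOVA is
the reference procedure, the pooled form is used instead (section 5).

## 4. The imaging track

A dual-excitation potentiometric dye (di-8-ANEPPS class) stains the plasma
membrane; the ratio of emission under 438 nm and 531 nm excitation reports
membrane potential, with hyperpolarization lowering the ratio when 438 nm
is the numerator. `simulate_ratio_images()` renders each protoplast as a
fluorescent ring whose 531 nm amplitude is fixed and whose 438 nm amplitude
is `ratio × amplitude`, with the true ratio following a **linear** map
`intercept + slope × potential` (slope > 0). The linear map is a
literature-consistent small-signal approximation; the package never claims
a millivolt calibration, only ordering and differences, which is also all
the analysis reports. The default field has four BSC-like protoplasts at
−130 ± 5 mV and four MC-like at −90 ± 5 mV — potentials in the plausible
resting range for energized plant cells, separated by the hypothesized
pump-driven hyperpolarization of BSCs — plus uniform background (500
counts), Gaussian noise (50 counts) and 16-bit quantization. Setting both
population means equal (e.g. −60 mV) emulates the depolarizing
vanadate/nitrate control in which the group difference must vanish. Not
emulated: chloroplast autofluorescence, dye internalization, flat-field
inhomogeneity — so passing tests demonstrate the correctness of the ratio
arithmetic and segmentation, not robustness to every optical artifact.

`segment_protoplasts()` thresholds the 531 nm image (Otsu), labels
connected components (`EBImage`), fits each as a circle (centroid + mean
pixel distance) and measures a 3 px annulus centred on the rim;
edge-truncated rings are flagged and excluded by default, and the
background is the dimmest 20% of pixels outside all components.
`compute_ratio()` divides the **ROI-mean** background-subtracted
intensities rather than averaging per-pixel ratios: the ratio of means is
far stabler at low signal (a per-pixel ratio has heavy tails when the
denominator pixel is near background) and is invariant to a common gain on
both channels. Saturated pixels are excluded; a non-positive numerator or
denominator marks the result invalid rather than returning a number.

## 5. The expression track

The pipeline starts at a normalized genes × samples log2 expression matrix
(log2(NREL)) with ≥ 2 replicates per cell type; array preprocessing is out
of scope. The filtering rules, with their cutoff conventions pinned:

* **Expressed** in a type: mean log2 over that type's replicates **≥ 2**
  (inclusive). The per-type mean was chosen as the summary; a
  per-replicate rule is not what a per-type Venn implies.
* **Differential**: per-gene pooled-variance t-test (identical to the
  classical two-group one-way ANOVA) on log2 values, with signed linear
  fold change from the anti-logged difference of group means
  (FC = ratio if ≥ 1 else −1/ratio). The DE flag requires **|FC| ≥ 1.5**
  (inclusive, evaluated on the log2 scale with a 10⁻⁹ epsilon so boundary
  genes are not lost to rounding) **and P < 0.05** (strict). The
  transporter re-analysis uses **P ≤ 0.05 with no fold-change
  restriction**. Raw P-values are used throughout — deliberately mirroring
  the reference filtering procedure; `add_bh = TRUE` exposes a
  Benjamini–Hochberg column for users but never feeds the flags.
  Zero-variance genes get a flagged fallback P (1 if means equal, else 0)
  instead of `NaN`.
* **Highly expressed transporters**: mean log2 **≥ 3.5**; crossing the
  high-expression sets with the P-only differential set yields the
  disjoint groups A (high in MC only), B (high in BSC only) and C (high in
  both).
* **Enrichment**: one-tailed hypergeometric over-representation per flat
  category label against the background universe, enriched at P < 0.05,
  with a direction split (higher/lower in BSC) from the DE signs. This is
  an explicit stand-in for web-tool enrichment engines (modified
  Fisher/EASE scores, GO DAG traversal), and is labelled as such; on small
  instances it is verified against exhaustive subset enumeration.

`simulate_expression_matrix()` generates per-gene Gaussian baselines
(default mean 2 — the median-level threshold — SD 1.5 across genes),
replicate noise SD 0.2, three replicates per type, and spikes 5% of genes
by ±1.5 log2 units in the BSC group, recording the truth table. It emulates
the statistical structure the tests assume (Gaussian log2 values, shared
within-group variance, independent genes); it does not emulate
probe-level effects, correlated gene blocks, or amplification-induced
variance inflation, so sensitivity/specificity results on it are
best-case bounds, not array benchmarks.

## 6. Pipeline, determinism, problem sizes

`run_pipeline()` drives all three assays from one validated `run_config`
(thresholds, LJP table, temperature, seed) and writes per-stage TSVs, a
combined `summary.json` and a `manifest.json` sufficient to reproduce any
table. Every random draw flows from the config seed through private RNG
streams (`simulate_*` restore the caller's `.Random.seed`), so one seed
gives byte-identical tables.

Default problem sizes — 8 BSC + 4 MC simulated cells (the study's group
sizes), 15 sweeps × 2 kHz × 1.03 s per cell, a 1000-gene × 6-sample matrix
with 50 spiked genes, and 8-protoplast image fields — were chosen as the
smallest sizes at which every estimator operates in its intended regime;
the full pipeline completes in a few seconds on one CPU, and the test
suite's property checks (20-seed parameter recovery, 1000-replicate
type-I-error simulation, exhaustive enrichment enumeration) in well under a
minute.

## 7. Known limitations

* Kinetics (τ) are not estimated, only assumed brief-ramp-compatible;
  channel identity (AKT2 vs KAT1 mixtures) is out of scope.
* The reversal estimator needs genuinely different pre-pulse conductances;
  a cell whose gate barely moves across the protocol has no crossover and
  errors out by design.
* Printed K⁺ equilibrium potentials in the motivating experimental system
  cannot be reproduced exactly without knowing the effective intracellular
  activity the authors assumed; the package therefore computes Nernst
  potentials from explicit compositions and treats them as inputs, not
  targets.
* The enrichment test assumes flat, non-overlapping category labels per
  gene; real GO annotation is a DAG with multiple membership.
* Segmentation assumes bright, approximately circular, non-overlapping
  membrane rings; confluent or burst protoplasts are not handled.
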