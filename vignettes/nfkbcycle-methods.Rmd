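---
title: "Models and methods: coupled NF-kB / E2F dynamics across the cell cycle"
author: "nfkbcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: coupled NF-kB / E2F dynamics across the cell cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`nfkbcycle` simulates and analyses the interplay between TNF-alpha-driven
NF-kB (RelA) signalling and cell-cycle position in single cells. It provides

* a family of three nested ODE models of the NF-kB oscillator and its
  couplings to E2F-1 and E2F-4 (`nfkb_model()`, `simulate_nfkb()`),
* a cell-cycle layer (duration statistics, phase boundaries, E2F synthesis
  drive profiles, FUCCI crossing detection),
* a seeded synthetic-data generator producing single-cell imaging traces and
  FCS/FCCS measurement sets with known ground truth,
* virtual synchronization (phase assignment from mitosis timing or from the
  E2F-1 reporter peak), per-cell trace features, and the group statistics and
  spectroscopy quantifications used to summarize such experiments,
* six packaged scenario pipelines (`run_scenario()`) that run the stages end
  to end under one seed.

# The reaction network

All variants share one master network, integrated with a stiff-capable
solver (`lsoda`, relative tolerance 1e-8, absolute tolerance 1e-10 nM,
compiled right-hand side). Time is in minutes, concentrations in nM. Total
RelA (free plus all complexes, both compartments) is conserved exactly:
there are no RelA synthesis or degradation terms, and every reaction moves
RelA between pools.

**Base oscillator.** TNF-alpha activates IKK (neutral -> active), active IKK
is inactivated along an A20-assisted route and recycled; active IKK degrades
IkBa both free and in the RelA:IkBa complex; liberated RelA enters the
nucleus, where it drives IkBa and A20 transcription through a Hill function;
newly made IkBa enters the nucleus, captures RelA, and the nuclear complex
is exported — the classic delayed negative feedback that produces damped
nuclear-cytoplasmic RelA oscillations.

**E2F-1 extension (`e2f1`).** Nuclear E2F-1 binds free nuclear RelA
reversibly (competing with IkBa for free RelA; it does not act on the
RelA:IkBa complex), represses NF-kB-driven IkBa transcription by a
multiplicative factor $1/(1 + [\mathrm{E2F1}]/K_{rep})$, is itself
synthesized under a cycle-gated drive repressed by nuclear RelA, and turns
over by first-order degradation (also while RelA-bound, releasing RelA).

**Revised model (`revised`).** E2F-4 is synthesized from E2F-1 (and/or a
direct cycle-gated drive) and binds the *cytoplasmic* RelA:IkBa complex,
forming a ternary complex whose IkBa is not a substrate for IKK-driven
degradation — a stabilized, stimulus-resistant reservoir. E2F-4 keeps
turning over inside the ternary complex, releasing the RelA:IkBa complex;
without this turnover the ternary pool would sequester E2F-4 indefinitely
and stimulation could never resume. E2F-4 does not bind free RelA (whether
it also competes with IkBa for RelA binding is left open by the data and is
not modelled).

The variants are strict supersets: zeroing the E2F-4 couplings of `revised`
reproduces `e2f1` exactly, and zeroing the E2F-1 couplings of `e2f1`
reproduces `base` exactly, because all variants share one right-hand side.

## Parameterization

The kinetic defaults (`nfkb_default_params()`) are the package's own
calibration of this network, chosen once to reproduce the qualitative
single-cell behaviours reported for these cell systems and then frozen:

* predominantly cytoplasmic RelA at rest (N:C ratio ~ 0.02) with a stable
  unstimulated steady state;
* under sustained saturating TNF-alpha, a first nuclear peak ~30 min after
  stimulation and subsequent peaks every ~80–140 min; the stimulated fixed
  point is unstable (Hill coefficient 3 on the NF-kB-driven promoters), so
  oscillations persist rather than spiralling into a steady state — this is
  essential for the refractory-period experiment, where oscillations must
  *resume* after E2F-mediated suppression decays;
* a RelA:E2F-1 dissociation constant of 12 nM (`kdNE/kaNE`), the value
  measured for the nuclear complex by fluorescence cross-correlation
  spectroscopy;
* E2F-1 and E2F-4 half-lives of ~2.7 h and ~1.6 h, placing the
  co-expression refractory period (below) at ~4 times the base inter-peak
  interval.

Every parameter can be overridden per call (`nfkb_model(overrides=)`) or
through the YAML model configuration (`read_model_config()`), so a
transcribed published parameter set can be substituted wholesale.

Two *contexts* of this network appear in the package, reflecting two
experimental systems:

1. **Transient co-expression** (refractory-period scenario): the model
   defaults above. Cells are initialized at the co-expression equilibrium of
   the `e2f1` variant with constitutive E2F-1 synthesis, synthesis is
   switched off at stimulation, and E2F-4 is produced transiently from the
   decaying E2F-1 pool.
2. **Cycling reporter line** (population generator): the generator's
   `kinetic_overrides` adapt the same network to cycling cells —
   cycle-gated E2F-1 synthesis (`kE1syn = 0.5`, weaker transcriptional
   couplings `KrepE = 2`, `KrepN = 100`) and a direct cycle-gated E2F-4
   drive (`kE4drv = 4`, `kaE4 = 0.05`, `kdegE4 = 0.02`, `kE4syn = 0` since
   the drive already encodes the cycle dependence). This calibration
   produces the phase-dependent first-response pattern: strongest at G1/S,
   suppressed in S, restored in G1/G2.

# Cell-cycle layer

A `cycle_program()` fixes the duration distribution (log-normal; default
mean 20 h, SD 1.45 h between cells) and phase boundaries as fractions of
the realized duration: G1 `[0, 0.40)`, a late-G1 "G1/S" window
`[0.40, 0.50)`, S `[0.50, 0.85)`, G2 `[0.85, 1)`. These fractions are
package defaults (the calibrating crossing-point measurements are not
published as numbers); they honour the usual thymidine-block anchors — a
release point inside the G1/S window and release + 4 h in mid S phase — and
are fully configurable.

E2F drive profiles are smooth log-normal-shaped bumps in cycle fraction:
E2F-1 peaking at 0.45 (late G1), E2F-4 lagged by 0.17 (peaking early-to-mid
S). Both fall below 5% of peak at mitosis. Because protein accumulates
against first-order turnover, the E2F-1 *protein* peak lags the synthesis
drive by roughly the turnover time — with the default kinetics it sits near
cycle fraction 0.55; the E2F-1-peak alignment method accounts for this via
its `peak_position_frac` default.

`fucci_crossing()` marks G1/S as the earliest positive-to-negative sign
change of (red − green), linearly interpolated between samples, after an
optional centered moving average; a tie at a sample resolves to that
sample's time. The generator places the true crossing at cycle fraction
0.45 (the G1/S window midpoint).

# Synthetic populations

`generate_population()` realizes one virtual imaging experiment from a
`population_config()`:

* each cell draws successive log-normal cycle durations; its age at the
  start of the recording is uniform over the first cycle (asynchronous
  culture), or fixed via `initial_age_frac` to force the phase at
  treatment;
* the `revised` model, driven by the cell's cycle clock through the E2F
  drive profiles, produces the RelA and E2F-1 reporter channels; per-cell
  heterogeneity enters as log-normal multipliers (default CV 10–15%) on the
  TNF->IKK rate, the IkBa transcription rate and the E2F drive amplitudes;
* reporter intensities are `scale * (concentration + background)` with
  multiplicative log-normal measurement noise (default SD 5% — the study
  does not quantify imaging noise; this is a package default) and a
  background of 10 nM RelA-equivalents on both compartment channels, so
  measured N:C ratios are finite and bounded away from zero. Intensities
  halve at each division (the simplest division model; all extracted
  features are ratio-based and unaffected);
* ground truth (phase at treatment, realized durations, lengthening,
  multipliers) is kept in a JSON sidecar next to the trace CSV
  (`write_traces()` / `read_traces()`), so analyses can run blind on the
  CSV while tests compare against the sidecar.

## The TNF-alpha cycle-timing effect

Treated cells pause their cycle clock at the position reached at treatment
for a phase-dependent time: 9 h when stimulated inside the G1/S window,
1.8 h in G1 or G2, 0 h in S. The pause model is deliberately
phenomenological (the mechanism of the lengthening is not established).
These values are calibrated in *measured* space: mitosis-timing phase
assignment has limited purity (~2/3 of cells labelled G1/S are truly
G1/S), so the blind pipeline's subset means are diluted relative to ground
truth. With this block and an untreated SD of 1.45 h the full pipeline —
generate, assign phases from mitosis timing, extract spanning-cycle
durations, summarize — recovers a treated-minus-untreated mean difference
of ~1.9 h (~10%), a treated/untreated SD ratio of ~2 (the phase-structured
lengthening alone accounts for the variance inflation; the calibrated
extra jitter term is zero), and a G1/S-subset lengthening of ~1/3 of the
untreated mean, with no S-phase effect. Treated durations are measured on
the cycle spanning the fixed treatment time, which over-samples long
cycles slightly; this length bias is inherent to the measurement design
and is reproduced, not corrected.

# Feature extraction and statistics

* `first_response()`: maximum N:C ratio within a window (default 120 min)
  after treatment divided by the N:C ratio at treatment. An amplitude of 1
  (no rise) is reported with a censoring flag. All censoring in the package
  is explicit; group statistics receive only uncensored values, with counts.
* `detect_peaks()`: local maxima filtered by topographic prominence
  (default 0.2 in normalized N:C units) and minimum separation (default
  40 min, below the inter-peak scale and above noise); the less prominent
  of two conflicting peaks is discarded.
* `refractory_delay()`: time from treatment to the second detected peak of
  the treatment-normalized N:C series; censored when fewer than two peaks.
* `half_times()`: nuclear-occupancy half-time (fall halfway from the
  initial value to the final plateau, taken as the median of the last 10%
  of samples — robust to end noise) and E2F decay half-time (fall to half
  the initial value), both linearly interpolated.
* `kruskal_dunn()`: Kruskal–Wallis H with tie correction plus Dunn's
  pairwise z tests on mean ranks, Bonferroni-adjusted by default (the
  conventional "Dunn correction"; the adjustment method is configurable).
* `levene_test()`: one-way F on absolute deviations from the group mean
  (median optional). The treated/untreated variability comparison is
  reported on the SD scale (ratio of standard deviations); the scale is a
  documented choice.
* `theil_sen_slope()` / `estimate_kd()`: the median of all pairwise slopes
  with a rank-based confidence interval from the order statistics of the
  pairwise slopes (normal approximation to the Kendall score variance).
  Because free-A x free-B = Kd x complex at equilibrium, regressing the
  product of free concentrations on the complex concentration gives Kd as
  the slope; the Theil–Sen estimator makes this robust to outlying
  measurements.
* `molecules_per_cell()`: whole-cell counts from confocal particle numbers,
  `n_nuc V_nuc/V_conf + n_cyt V_cyt/V_conf`, with the measured volumes
  (0.59 fL confocal, 1420 fL nuclear, 6110 fL cytoplasmic) as defaults in
  the FCS generator.

# Virtual synchronization

`assign_phase_from_mitosis()` maps the mitosis-to-treatment time onto the
phase bands using the program's mean duration (default) or the cell's
realized duration; assignments within 2% of the cycle duration of a band
boundary are flagged boundary-adjacent and excluded from grouping by
default. On noiseless synthetic data, realized-duration assignment agrees
with ground truth for >= 95% of non-flagged cells.

`align_to_e2f1_peak()` implements the faster alternative used for the
dual-reporter line: each cell's E2F-1 channel is smoothed (moving average,
5 samples; ties resolve to the earliest time), its maximum located within
the cycle containing treatment, treatment times re-expressed relative to
the peak, levels normalized to the peak, and a cubic smoothing spline
(default 8 df) fitted over the pooled population. Phase bands are placed on
relative time through the reporter-peak position (default cycle fraction
0.55, the measured protein-peak position under the default kinetics).
Cells whose maximum sits on the window boundary are excluded and counted.
In treated populations the cycle-lengthening pause delays the reporter
peak of G1/S-stimulated cells, so the relative-time axis under-populates
the region just before the peak; as in the original analysis of the
dual-reporter line, the per-phase amplitude comparison is most informative
for G1 vs S and G2 vs S.

# Scenario pipelines and reproducibility

`run_scenario(name, config, seed)` runs one of six end-to-end analyses;
every random draw descends from the single seed, and identical
configuration and seed reproduce the report exactly. Problem sizes follow
the study designs: 200 cells per arm for the cycle-timing effects, 237
cells for the phase-response population, 20 cells per cohort for the
refractory comparison, 128 cells for the alignment population, 46 FCCS
triplets, and 20 FCS replicates per species.

The `fig6_refractory` scenario initializes `revised`-model cells at the
E2F-1 co-expression equilibrium and stimulates with sustained TNF-alpha;
the refractory delay (treatment to second peak, detected at prominence
0.05 on the normalized series) is compared with the base-model cohort's
first-to-second peak interval, giving a cohort-mean ratio near 4. The
restart time is bimodal in the E2F-1 degradation rate — below a threshold
the model skips a full oscillation — so the cohort heterogeneity CV is set
to 0.05, representing clone-to-clone variability within the unimodal
regime; larger CVs inflate the cohort mean through occasional
skipped-cycle cells.

# What the generator does and does not emulate

The generator reproduces the statistical structure the analyses assume:
asynchronous phase at treatment, damped heterogeneous oscillations,
phase-dependent first-response modulation via the E2F couplings,
phase-dependent cycle lengthening, mitosis events with intensity halving,
and multiplicative measurement noise. It does not emulate image
segmentation errors, photobleaching, focus drift, cell death or lineage
correlations beyond one division's parameter inheritance, and its noise is
stationary and log-normal. Passing tests therefore validate the pipeline's
statistical machinery and the model's qualitative predictions under these
idealized conditions — not the imaging layer of a real experiment.

# Numerical choices and degenerate inputs

* Integration restarts exactly at stimulus onset/offset (no discontinuity
  inside a solver span); halving the solver tolerances changes the N:C
  series by well under 0.1%.
* Negative solver round-off beyond −1e-9 nM is an error; smaller
  excursions are tolerated and zeroed only at explicit state hand-offs.
* `fucci_crossing` distinguishes "no crossing" (NA) from the degenerate
  all-zero difference (error).
* Theil–Sen with fewer than two distinct x values is an error; pairs with
  equal x are skipped.
* The N:C ratio is undefined where the cytoplasmic RelA total is zero;
  such samples are dropped from half-time computations (can occur only in
  synthetic initial conditions, not in background-bearing traces).

# Known limitations

* The kinetic defaults are a qualitative calibration, not a fitted
  parameter set; quantities that depend on absolute rates (peak widths,
  absolute amplitudes) should not be read as predictions.
* Phase assignment purity near band boundaries is limited by duration
  variability; the boundary flag mitigates but does not remove this.
* The SD-ratio estimate from the spanning-cycle design carries a small
  (~5%) upward length bias, reproduced deliberately.
* No stochastic (molecular-noise) simulation; heterogeneity is purely
  parametric.
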