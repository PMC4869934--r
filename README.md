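# nfkbcycle

Single-cell analysis of how NF-κB signalling and the cell cycle are
prioritised against each other. In cycling cells, the response of the
transcription factor NF-κB (RelA) to the inflammatory cytokine TNF-α
depends on when in the division cycle the signal arrives: stimulation at
the G1/S boundary produces a strong nuclear translocation and lengthens the
cycle, while stimulation in S phase produces a damped, delayed response and
leaves cycle timing untouched. The mechanism runs through two cell-cycle
transcription factors that bind RelA directly: E2F-1 (peaking in late G1,
competing with IκBα for free RelA) and its target E2F-4 (peaking in S
phase, stabilising the cytoplasmic RelA:IκBα complex against IKK-driven
IκBα degradation).

`nfkbcycle` implements this system as a tested, reusable R package:

* **ODE models** — three nested variants of the TNF-α → IKK → IκBα/A20
  negative-feedback oscillator in compiled C, integrated with `deSolve`:

  `base`: d[IKKa]/dt = ka·TR·IKKn − (k3 + k2·TR·A20)·IKKa, IKK-driven IκBα
  degradation, nuclear import of free RelA, NF-κB-driven IκBα/A20
  transcription (Hill), IκBα-mediated export — damped N:C RelA
  oscillations with total RelA conserved;
  `e2f1`: + reversible nuclear RelA·E2F-1 binding (K_d = 12 nM),
  transcriptional cross-repression between E2F-1 and the IκBα promoter;
  `revised`: + E2F-1-driven E2F-4 synthesis and a ternary
  RelA:IκBα:E2F-4 complex whose IκBα is protected from degradation.

* **Virtual synchronization** — assigning each cell's cycle phase at
  stimulation from mitosis timings, from the E2F-1 reporter peak, or from
  the FUCCI red/green crossing, then grouping per-cell response features
  by phase.

* **Trace features & statistics** — normalized first-peak amplitude,
  refractory delay (time to the second nuclear peak), nuclear-occupancy
  and E2F decay half-times; Kruskal–Wallis with Dunn post-hoc z tests,
  Levene's variance test, bootstrap effect summaries.

* **Spectroscopy quantification** — whole-cell molecule counts from FCS
  particle numbers (count = n·V_compartment/V_confocal) and dissociation
  constants from FCCS triplets via the Theil–Sen estimator
  (K_d = median pairwise slope of freeA·freeB against complex).

* **Synthetic data** — a seeded generator producing single-cell imaging
  traces (driven by the `revised` model on a per-cell cycle clock, with
  heterogeneity, background, noise and division events) and FCS/FCCS
  measurement sets with known ground truth, so the whole pipeline is
  testable end to end without any external data.

## Worked example

Simulate the base oscillator and measure its response:

```r
library(nfkbcycle)

m  <- nfkb_model("base")
eq <- equilibrate(m, horizon = 40000, tol = 1e-6)
nc_ratio(eq)
#> [1] 0.0246          # resting RelA is predominantly cytoplasmic

traj <- simulate_nfkb(m, state0 = eq,
                      protocol = stimulus_protocol(0, Inf, 1),  # sustained saturating TNF-α
                      times = seq(0, 600, by = 2))
detect_peaks(traj$time, traj$nc_ratio / traj$nc_ratio[1],
             min_prominence = 1, min_separation = 40)$time
#> [1]  30 168 266 356 444 530   # nuclear peaks, ~90-140 min apart
```

Estimate a dissociation constant from synthetic FCCS triplets (true
K_d = 12 nM, 10% measurement noise, n = 46):

```r
tri <- generate_fccs_set(true_kd_nM = 12, n = 46, noise_sd = 0.1, seed = 1)
estimate_kd(tri)
#> Kd = 11.7 nM  [95% CI 10.5, 13.4]  (n = 46)
```

Run the cycle-timing pipeline (two 200-cell arms, blind phase assignment,
bootstrap CIs):

```r
run_scenario("fig3_cycle_effects", seed = 1)
#> scenario report: fig3_cycle_effects (seed 1 )
#>   mean_diff_h: 1.8019          # TNF-treated cycles ~1.9 h longer
#>   mean_diff_ci: 1.3874, 2.2562
#>   sd_ratio: 2.1337             # ~2-fold more variable
#>   g1s_frac_longer: 0.3279      # G1/S-treated subset ~1/3 longer
#>   s_frac_longer: 0.0075063     # no S-phase effect
#>   levene_p: 7.1173e-10
#>   n_untreated: 200
#>   n_treated: 200
```

The mean difference says TNF-α-treated cells take about 1.9 h longer from
mitosis to mitosis than untreated cells; the SD ratio says the treated
population is about twice as variable; the G1/S subset estimate says cells
caught in the late-G1 window are about a third slower than the untreated
average — all recovered by the blind pipeline from generated traces.

Other scenarios: `fig2_phase_response` (phase-grouped first-response
amplitudes with Dunn contrasts), `fig6_refractory` (the ~4-fold refractory
period under E2F-1 co-expression), `fig8_alignment` (E2F-1-peak alignment
with a population spline), `fcs_counting` (whole-cell molecule counts).

## Package layout

| Area | Files |
|------|-------|
| ODE models & simulation | `R/model.R`, `src/nfkb_ode.c` |
| Cell-cycle programs & FUCCI | `R/cellcycle.R` |
| Synthetic data | `R/synthetic.R` |
| Trace features | `R/features.R` |
| Virtual synchronization | `R/vsync.R` |
| Statistics & FCS/FCCS | `R/stats.R` |
| Scenario pipelines | `R/pipeline.R`, `R/io.R` |

The methods vignette (`vignettes/nfkbcycle-methods.Rmd`) documents the
model equations, the calibration choices, the generator's assumptions and
the package's known limitations.
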