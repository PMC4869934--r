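Package: nfkbcycle
Title: Coupled NF-kB / E2F Dynamics, Virtual Synchronization and
    Single-Cell Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of the coupling between NF-kB
    (RelA) signalling dynamics and the cell cycle in single cells.
    Provides a family of ordinary differential equation models of the
    TNF-alpha-driven NF-kB/IkBa/A20 oscillator, extended with E2F-1
    competition for RelA binding and an E2F-4-mediated stabilization of
    the cytoplasmic RelA:IkBa complex; a virtual-synchronization
    pipeline that assigns a cell-cycle phase at stimulation from
    mitosis timings, E2F-1 reporter peaks or FUCCI channel crossings;
    per-cell trace feature extraction (normalized first-peak amplitude,
    refractory delay, half-times); group statistics (Kruskal-Wallis
    with Dunn post-hoc comparisons, Levene's variance test, bootstrap
    effect summaries); and fluorescence (cross-)correlation
    spectroscopy quantification (whole-cell molecule counts, Theil-Sen
    dissociation-constant estimation). A seeded synthetic-data module
    generates single-cell imaging traces and FCS/FCCS measurement sets
    with known ground truth so every stage of the pipeline can be
    exercised and validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
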