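# Seeded synthetic single-cell imaging traces and FCS/FCCS measurement
# sets with known ground truth.

#' Configuration for a synthetic single-cell population
#'
#' Describes one virtual imaging experiment: asynchronous cells with
#' log-normal cycle durations are recorded at a fixed cadence, treated
#' with TNF-alpha at a fixed wall-clock time, and their RelA and E2F
#' reporter channels are produced by the `revised` ODE model driven by
#' each cell's cycle clock. Cell-to-cell heterogeneity enters as
#' log-normal multipliers on a documented kinetic parameter subset;
#' measurement noise is multiplicative.
#'
#' The `cycle_effect` block encodes the TNF-alpha effect on cycle
#' timing as a phase-dependent pause of the cycle clock at treatment:
#' `g1s_lengthening_h` for cells hit in the G1/S window,
#' `s_lengthening_h` in S phase, `other_lengthening_h` in G1/G2, plus
#' a per-cell jitter calibrated so the treated/untreated duration SD
#' ratio matches `sd_ratio_target` in expectation (zero jitter when
#' the phase mixture alone already reaches the target).
#'
#' @param n_cells Number of cells.
#' @param program A [cycle_program()].
#' @param treatment_time_h Treatment time (h into the recording).
#' @param dose_scale TNF-alpha dose scale in `[0, 1]` (0 = untreated).
#' @param record_h Recording length (h).
#' @param sampling_interval_min Imaging cadence (min).
#' @param heterogeneity_cv Named CVs of log-normal multipliers on
#'   kinetic parameters.
#' @param noise_sd Multiplicative measurement noise SD (fraction of
#'   signal).
#' @param cycle_effect List with `g1s_lengthening_h`,
#'   `other_lengthening_h`, `s_lengthening_h`, `sd_ratio_target`.
#' @param kinetic_overrides Named kinetic parameter overrides applied
#'   to the `revised` model before heterogeneity (the cycling-cell
#'   calibration).
#' @param background_nM Background fluorescence in RelA-equivalent nM
#'   added to both compartment channels before ratioing.
#' @param intensity_scale Arbitrary intensity units per nM.
#' @param expression_cv CV of the per-cell expression/scale factor.
#' @param fucci Logical; generate FUCCI red/green channels.
#' @param simulate_traces Logical; when `FALSE`, skip the ODE reporter
#'   channels (mitosis times, ground truth and FUCCI are still
#'   generated) — a fast path for duration-only analyses.
#' @param initial_age_frac Either `NULL` (each cell's age at the start
#'   of the recording is uniform over its first cycle — an
#'   asynchronous culture) or a fraction in `[0, 1)` fixing the age
#'   deterministically (used to force the phase at treatment).
#' @param seed Integer seed; identical config and seed give identical
#'   output.
#' @return Object of class `population_config`.
#' @export
population_config <- function(n_cells = 200,
                              program = cycle_program(),
                              treatment_time_h = 30,
                              dose_scale = 1,
                              record_h = 64,
                              sampling_interval_min = 5,
                              heterogeneity_cv = c(ka = 0.1, ktI = 0.1,
                                                   kE1syn = 0.15,
                                                   kE4drv = 0.15),
                              noise_sd = 0.05,
                              cycle_effect = list(
                                g1s_lengthening_h = 9,
                                other_lengthening_h = 1.8,
                                s_lengthening_h = 0,
                                sd_ratio_target = 2),
                              kinetic_overrides = c(kE1syn = 0.5,
                                                    KrepE = 2,
                                                    KrepN = 100,
                                                    kE4syn = 0,
                                                    kE4drv = 4,
                                                    kaE4 = 0.05,
                                                    kdegE4 = 0.02),
                              background_nM = 10,
                              intensity_scale = 100,
                              expression_cv = 0.3,
                              fucci = TRUE,
                              simulate_traces = TRUE,
                              initial_age_frac = NULL,
                              seed = 1) {
  stopifnot(n_cells >= 0, inherits(program, "cycle_program"),
            dose_scale >= 0, dose_scale <= 1,
            sampling_interval_min > 0, record_h > 0,
            all(heterogeneity_cv >= 0), noise_sd >= 0,
            background_nM >= 0, expression_cv >= 0)
  structure(list(n_cells = as.integer(n_cells), program = program,
                 treatment_time_h = treatment_time_h,
                 dose_scale = dose_scale, record_h = record_h,
                 sampling_interval_min = sampling_interval_min,
                 heterogeneity_cv = heterogeneity_cv,
                 noise_sd = noise_sd, cycle_effect = cycle_effect,
                 kinetic_overrides = kinetic_overrides,
                 background_nM = background_nM,
                 intensity_scale = intensity_scale,
                 expression_cv = expression_cv, fucci = fucci,
                 simulate_traces = simulate_traces,
                 initial_age_frac = initial_age_frac,
                 seed = as.integer(seed)),
            class = "population_config")
}

# per-cell lengthening jitter SD (h) so that the treated/untreated
# duration SD ratio matches the target in expectation
.lengthening_jitter_sd <- function(config) {
  ce <- config$cycle_effect
  pr <- config$program
  p <- c(G1 = pr$g1s_start, `G1/S` = pr$s_start - pr$g1s_start,
         S = pr$g2_start - pr$s_start, G2 = 1 - pr$g2_start)
  L <- c(G1 = ce$other_lengthening_h, `G1/S` = ce$g1s_lengthening_h,
         S = ce$s_lengthening_h, G2 = ce$other_lengthening_h)
  mix_var <- sum(p * L^2) - sum(p * L)^2
  target_var <- (ce$sd_ratio_target * pr$sd_duration_h)^2
  extra <- target_var - pr$sd_duration_h^2 - mix_var
  sqrt(max(0, extra))
}

.lnorm_pars <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# deterministic rolling hash of a deparsed object
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Generate a synthetic single-cell population
#'
#' Realizes the experiment described by a [population_config()]: each
#' cell receives log-normal cycle durations and mitosis times tiling
#' the recording, a ground-truth phase at treatment, perturbed kinetic
#' parameters, an N:C RelA trajectory from the `revised` model with
#' E2F synthesis gated by the cell's cycle clock, reporter intensities
#' with background and multiplicative noise (halving at each
#' division), and — for treated cells — a phase-dependent cycle
#' lengthening applied as a clock pause at treatment.
#'
#' @param config A [population_config()].
#' @return Object of class `cell_population`: list with `traces` (a
#'   list of `cell_trace` objects) and the `config`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  set.seed(config$seed)
  pr <- config$program
  t_treat <- config$treatment_time_h * 60
  t_end <- config$record_h * 60
  grid <- seq(0, t_end, by = config$sampling_interval_min)
  treated <- config$dose_scale > 0 && t_treat <= t_end
  jitter_sd <- .lengthening_jitter_sd(config)

  model <- nfkb_model("revised", overrides = config$kinetic_overrides)
  state0 <- NULL
  if (config$simulate_traces) {
    # common resting state: cytoplasmic RelA, no E2F drive
    m0 <- model
    m0$params[c("kE1syn", "kE4drv")] <- 0
    eq <- simulate_nfkb(m0, protocol = NULL,
                        times = seq(0, 40000, by = 500))
    state0 <- eq$state[nrow(eq$state), ]
    state0[state0 < 0] <- 0
  }

  dl <- .lnorm_pars(pr$mean_duration_h, max(pr$sd_duration_h, 1e-6))
  traces <- vector("list", config$n_cells)
  for (ci in seq_len(config$n_cells)) {
    durations <- 60 * stats::rlnorm(12, dl["meanlog"], dl["sdlog"])
    age0 <- if (is.null(config$initial_age_frac))
      stats::runif(1, 0, durations[1]) else
      config$initial_age_frac * durations[1]
    births <- cumsum(c(-age0, durations))[seq_along(durations)]

    # phase at treatment from the cycle containing it
    phase_at_treat <- NA_character_
    lengthening <- 0
    k_treat <- NA_integer_
    if (treated) {
      k_treat <- findInterval(t_treat, births)
      Dk <- durations[k_treat]
      tsm <- (t_treat - births[k_treat])
      phase_at_treat <- as.character(
        phase_label(min(tsm, Dk - 1e-9) / 60, pr, Dk / 60))
      ce <- config$cycle_effect
      base_len <- switch(phase_at_treat,
                         "G1/S" = ce$g1s_lengthening_h,
                         "S" = ce$s_lengthening_h,
                         ce$other_lengthening_h)
      lengthening <- max(0, base_len + stats::rnorm(1, 0, jitter_sd))
    }

    # effective time-in-cycle at each sample: the clock pauses at the
    # treatment position for `lengthening` hours in the treated cycle
    Lmin <- lengthening * 60
    births_obs <- births
    if (treated && Lmin > 0)
      births_obs[seq_along(births) > k_treat] <-
        births[seq_along(births) > k_treat] + Lmin
    cyc <- findInterval(grid, births_obs)
    e_min <- grid - births_obs[cyc]
    if (treated && Lmin > 0) {
      in_k <- cyc == k_treat
      e_min[in_k] <- pmin(grid[in_k], t_treat) - births[k_treat] +
        pmax(0, grid[in_k] - (t_treat + Lmin))
    }
    e_min <- pmax(0, pmin(e_min, durations[cyc] - 1e-9))
    dur_cyc <- durations[cyc]

    dr <- e2f_drive(e_min / 60, pr, dur_cyc / 60)
    drives <- list(e2f1 = cbind(grid, dr$e2f1_rate),
                   e2f4 = cbind(grid, dr$e2f4_rate))

    # heterogeneity multipliers
    mult <- stats::setNames(rep(1, length(config$heterogeneity_cv)),
                            names(config$heterogeneity_cv))
    for (pn in names(config$heterogeneity_cv)) {
      cv <- config$heterogeneity_cv[[pn]]
      if (cv > 0) {
        lp <- .lnorm_pars(1, cv)
        mult[pn] <- stats::rlnorm(1, lp["meanlog"], lp["sdlog"])
      }
    }
    mcell <- model
    mcell$params[names(mult)] <- mcell$params[names(mult)] * mult

    if (config$simulate_traces) {
      protocol <- if (treated)
        stimulus_protocol(t_treat, Inf, config$dose_scale) else NULL
      traj <- simulate_nfkb(mcell, state0 = state0,
                            protocol = protocol,
                            times = grid, drives = drives)
      st <- traj$state
      rela_nuc <- rowSums(st[, c("NFkB_n", "NFkB.IkBa_n",
                                 "NFkB.E2F1_n"), drop = FALSE])
      rela_cyt <- rowSums(st[, c("NFkB_c", "NFkB.IkBa_c",
                                 "NFkB.IkBa.E2F4_c"), drop = FALSE])
      e2f1_tot <- rowSums(st[, c("E2F1_n", "NFkB.E2F1_n"),
                             drop = FALSE])
    } else {
      rela_nuc <- rela_cyt <- e2f1_tot <- rep(NA_real_, length(grid))
    }

    mitoses_obs <- births_obs[births_obs > 0 & births_obs <= t_end]
    lp <- .lnorm_pars(1, max(config$expression_cv, 1e-9))
    scale_cell <- config$intensity_scale *
      stats::rlnorm(1, lp["meanlog"], lp["sdlog"])
    halving <- 0.5^findInterval(grid, mitoses_obs)
    noise <- function(n) {
      if (config$noise_sd <= 0) return(rep(1, n))
      np <- .lnorm_pars(1, config$noise_sd)
      stats::rlnorm(n, np["meanlog"], np["sdlog"])
    }
    ng <- length(grid)
    bg <- config$background_nM
    nuc_mean <- scale_cell * halving * (rela_nuc + bg) * noise(ng)
    cyt_mean <- scale_cell * halving * (rela_cyt + bg) * noise(ng)
    e2f1_ch <- scale_cell * halving * (e2f1_tot + 0.1 * bg) * noise(ng)
    if (config$fucci) {
      xfrac <- e_min / dur_cyc
      xc <- (pr$g1s_start + pr$s_start) / 2
      red <- 1 / (1 + exp((xfrac - xc) / 0.03)) * noise(ng)
      green <- 1 / (1 + exp(-(xfrac - xc) / 0.03)) * noise(ng)
    } else {
      red <- green <- rep(NA_real_, ng)
    }

    traces[[ci]] <- structure(list(
      cell_id = sprintf("cell_%04d", ci),
      time_min = grid,
      nuc_mean = nuc_mean, cyt_mean = cyt_mean, e2f1 = e2f1_ch,
      fucci_red = red, fucci_green = green,
      mitosis_times_min = mitoses_obs,
      treatment_time_min = if (treated) t_treat else NA_real_,
      dose_scale = config$dose_scale,
      ground_truth = list(
        phase_at_treatment = phase_at_treat,
        base_durations_h = durations / 60,
        lengthening_h = lengthening,
        age_at_start_h = age0 / 60,
        multipliers = as.list(mult))),
      class = "cell_trace")
  }
  structure(list(traces = traces, config = config,
                 config_hash = .config_hash(unclass(config))),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat("synthetic cell population:", length(x$traces), "cells, dose",
      x$config$dose_scale, ", seed", x$config$seed, "\n")
  invisible(x)
}

#' @export
print.cell_trace <- function(x, ...) {
  cat("cell_trace", x$cell_id, ":", length(x$time_min), "samples,",
      length(x$mitosis_times_min), "mitoses",
      if (!is.na(x$treatment_time_min))
        paste(", treated at", x$treatment_time_min, "min") else
        ", untreated", "\n")
  invisible(x)
}

#' Generate FCCS concentration triplets with known Kd
#'
#' Constructs per-measurement (free A, free B, complex) triplets that
#' satisfy `freeA * freeB = Kd * complex` exactly before noise, then
#' applies independent multiplicative log-normal noise per channel.
#'
#' @param true_kd_nM Ground-truth dissociation constant (nM).
#' @param n Number of measurements (>= 2).
#' @param complex_range_nM Range of complex concentrations sampled
#'   uniformly.
#' @param noise_sd Multiplicative noise SD per channel.
#' @param seed Integer seed.
#' @return Data frame (`fccs_set`) with `measurement_id`, `freeA_nM`,
#'   `freeB_nM`, `complex_nM`; the truth is stored in attributes
#'   `true_kd_nM` and `noise_sd`.
#' @export
generate_fccs_set <- function(true_kd_nM = 12, n = 46,
                              complex_range_nM = c(2, 100),
                              noise_sd = 0.1, seed = 1) {
  stopifnot(true_kd_nM > 0, n >= 2, all(complex_range_nM > 0))
  set.seed(seed)
  cx <- stats::runif(n, complex_range_nM[1], complex_range_nM[2])
  prod <- true_kd_nM * cx
  asym <- exp(stats::runif(n, -log(2), log(2)))
  fa <- sqrt(prod * asym)
  fb <- sqrt(prod / asym)
  if (noise_sd > 0) {
    np <- .lnorm_pars(1, noise_sd)
    fa <- fa * stats::rlnorm(n, np["meanlog"], np["sdlog"])
    fb <- fb * stats::rlnorm(n, np["meanlog"], np["sdlog"])
    cx <- cx * stats::rlnorm(n, np["meanlog"], np["sdlog"])
  }
  out <- data.frame(measurement_id = seq_len(n), freeA_nM = fa,
                    freeB_nM = fb, complex_nM = cx)
  attr(out, "true_kd_nM") <- true_kd_nM
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("fccs_set", "data.frame")
  out
}

#' Generate an FCS particle-number input with known total count
#'
#' Sets the per-compartment mean particle numbers in the confocal
#' volume so that [molecules_per_cell()] returns
#' `target_total_molecules` exactly in the absence of noise; optional
#' Poisson noise perturbs the particle numbers.
#'
#' @param target_total_molecules Ground-truth whole-cell count.
#' @param nuclear_fraction Fraction of molecules in the nucleus.
#' @param v_conf_fL,v_nuc_fL,v_cyt_fL Confocal, nuclear and
#'   cytoplasmic volumes (fL).
#' @param poisson_noise Logical; draw observed particle numbers from a
#'   Poisson law around their means. Uses the current RNG state.
#' @return Object of class `fcs_input`: list with `n_nuc`, `n_cyt`,
#'   the three volumes and the ground-truth total.
#' @export
generate_fcs_input <- function(target_total_molecules,
                               nuclear_fraction = 0.5,
                               v_conf_fL = 0.59, v_nuc_fL = 1420,
                               v_cyt_fL = 6110,
                               poisson_noise = FALSE) {
  stopifnot(target_total_molecules >= 0,
            nuclear_fraction >= 0, nuclear_fraction <= 1,
            v_conf_fL > 0, v_nuc_fL > 0, v_cyt_fL > 0)
  n_nuc <- target_total_molecules * nuclear_fraction *
    v_conf_fL / v_nuc_fL
  n_cyt <- target_total_molecules * (1 - nuclear_fraction) *
    v_conf_fL / v_cyt_fL
  if (poisson_noise) {
    # Poisson draws at a 10-run acquisition resolution
    runs <- 10
    n_nuc <- stats::rpois(1, n_nuc * runs) / runs
    n_cyt <- stats::rpois(1, n_cyt * runs) / runs
  }
  structure(list(n_nuc = n_nuc, n_cyt = n_cyt, v_conf_fL = v_conf_fL,
                 v_nuc_fL = v_nuc_fL, v_cyt_fL = v_cyt_fL,
                 true_total = target_total_molecules),
            class = "fcs_input")
}

.TRACE_COLUMNS <- c("cell_id", "time_min", "nuc_mean", "cyt_mean",
                    "e2f1", "fucci_red", "fucci_green", "mitosis_flag")

#' Write traces to CSV with a JSON metadata sidecar
#'
#' The CSV holds the observable channels (one row per cell and time
#' point, `mitosis_flag` marking the sample at each division); exact
#' mitosis/treatment times and the generator's ground-truth block go
#' to a `_meta.json` sidecar so analyses can be run blind on the CSV.
#'
#' @param population A `cell_population` or list of `cell_trace`.
#' @param path CSV file path (sidecar derives from it).
#' @return `path`, invisibly.
#' @export
write_traces <- function(population, path) {
  traces <- if (inherits(population, "cell_population"))
    population$traces else population
  rows <- lapply(traces, function(tr) {
    flag <- rep(0L, length(tr$time_min))
    idx <- findInterval(tr$mitosis_times_min, tr$time_min)
    flag[idx[idx > 0]] <- 1L
    data.frame(cell_id = tr$cell_id, time_min = tr$time_min,
               nuc_mean = tr$nuc_mean, cyt_mean = tr$cyt_mean,
               e2f1 = tr$e2f1, fucci_red = tr$fucci_red,
               fucci_green = tr$fucci_green, mitosis_flag = flag)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(
    treatment_time_min = traces[[1]]$treatment_time_min,
    dose_scale = traces[[1]]$dose_scale,
    seed = if (inherits(population, "cell_population"))
      population$config$seed else NA,
    config_hash = if (inherits(population, "cell_population"))
      population$config_hash else NA,
    cells = lapply(traces, function(tr) list(
      cell_id = tr$cell_id,
      mitosis_times_min = tr$mitosis_times_min,
      treatment_time_min = tr$treatment_time_min,
      ground_truth = tr$ground_truth)))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

.sidecar_path <- function(path) sub("\\.csv$", "", path) |>
  paste0("_meta.json")

#' Read traces written by [write_traces()]
#'
#' @param path CSV path; the `_meta.json` sidecar is used when present
#'   (exact mitosis times and ground truth), otherwise mitosis times
#'   are reconstructed from `mitosis_flag`.
#' @return List of `cell_trace` objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(.TRACE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("malformed trace CSV: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  meta <- NULL
  if (file.exists(.sidecar_path(path)))
    meta <- jsonlite::read_json(.sidecar_path(path),
                                simplifyVector = FALSE)
  meta_ids <- if (!is.null(meta))
    vapply(meta$cells, function(cc) cc$cell_id, character(1)) else
    character(0)
  ids <- unique(df$cell_id)
  traces <- lapply(ids, function(id) {
    d <- df[df$cell_id == id, ]
    d <- d[order(d$time_min), ]
    mt <- d$time_min[d$mitosis_flag == 1]
    tt <- NA_real_; gt <- NULL
    i <- match(id, meta_ids)
    if (!is.na(i)) {
      cc <- meta$cells[[i]]
      if (!is.null(cc$mitosis_times_min))
        mt <- as.numeric(unlist(cc$mitosis_times_min))
      tt <- if (is.null(cc$treatment_time_min)) NA_real_ else
        as.numeric(cc$treatment_time_min)
      gt <- cc$ground_truth
      if (!is.null(gt)) {
        gt$base_durations_h <- as.numeric(unlist(gt$base_durations_h))
        gt$multipliers <- lapply(gt$multipliers, as.numeric)
      }
    }
    structure(list(cell_id = id, time_min = d$time_min,
                   nuc_mean = d$nuc_mean, cyt_mean = d$cyt_mean,
                   e2f1 = d$e2f1, fucci_red = d$fucci_red,
                   fucci_green = d$fucci_green,
                   mitosis_times_min = mt,
                   treatment_time_min = tt,
                   dose_scale = if (!is.null(meta))
                     meta$dose_scale else NA_real_,
                   ground_truth = gt),
              class = "cell_trace")
  })
  traces
}
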