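# Per-cell response descriptors extracted from N:C RelA ratio and E2F
# reporter channels.

# Internal: N:C ratio series and treatment time from a cell_trace or
# nfkb_trajectory.
.nc_series <- function(x, t_treat = NULL) {
  if (inherits(x, "cell_trace")) {
    list(time = x$time_min, nc = x$nuc_mean / x$cyt_mean,
         t_treat = if (is.null(t_treat)) x$treatment_time_min else t_treat)
  } else if (inherits(x, "nfkb_trajectory")) {
    list(time = x$time, nc = x$nc_ratio, t_treat = t_treat)
  } else if (is.list(x) && !is.null(x$time) && !is.null(x$nc)) {
    list(time = x$time, nc = x$nc, t_treat = t_treat)
  } else stop("expected a cell_trace, nfkb_trajectory, or list(time, nc)")
}

#' Detect peaks in a time series
#'
#' Local maxima filtered by topographic prominence (height above the
#' higher of the two flanking saddle minima) and by a minimum pairwise
#' time separation. When two candidate peaks are closer than
#' `min_separation`, the less prominent one is discarded.
#'
#' @param time Sampling times (strictly increasing).
#' @param x Series values (length >= 3).
#' @param min_prominence Minimum prominence, in the units of `x`.
#' @param min_separation Minimum time separation between reported
#'   peaks, in the units of `time`.
#' @return Data frame with columns `time`, `value`, `prominence`,
#'   ordered in time; zero rows when no peak qualifies.
#' @export
detect_peaks <- function(time, x, min_prominence = 0.2,
                         min_separation = 40) {
  n <- length(x)
  stopifnot(length(time) == n, n >= 3)
  cand <- which(diff(sign(diff(x))) < 0) + 1
  # plateau maxima: first sample of any flat top that later descends
  if (!length(cand) && length(unique(x)) > 1) {
    d <- diff(x)
    up <- which(d > 0); down <- which(d < 0)
    if (length(up) && length(down) && min(up) < max(down))
      cand <- min(down[down > min(up)])
  }
  if (!length(cand)) {
    return(data.frame(time = numeric(0), value = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(cand, function(i) {
    left <- if (any(x[seq_len(i - 1)] > x[i])) {
      j <- max(which(x[seq_len(i - 1)] > x[i]))
      min(x[j:i])
    } else min(x[1:i])
    right <- if (any(x[seq(i + 1, n)] > x[i])) {
      j <- i + min(which(x[seq(i + 1, n)] > x[i]))
      min(x[i:j])
    } else min(x[i:n])
    x[i] - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) > 1 && min_separation > 0) {
    ord <- order(prom, x[cand], decreasing = TRUE)
    sel <- logical(length(cand))
    for (k in ord) {
      if (!any(sel & abs(time[cand] - time[cand[k]]) < min_separation))
        sel[k] <- TRUE
    }
    cand <- cand[sel]; prom <- prom[sel]
  }
  o <- order(time[cand])
  data.frame(time = time[cand][o], value = x[cand][o],
             prominence = prom[o])
}

#' Normalized first-peak response after treatment
#'
#' The per-cell response amplitude as reported for virtually
#' synchronized populations: the maximum N:C RelA ratio within
#' `window` minutes after treatment, divided by the N:C ratio at the
#' moment of treatment (so an amplitude of 1 means no rise).
#'
#' @param x A `cell_trace`, [simulate_nfkb()] trajectory, or
#'   `list(time, nc)`.
#' @param window Response window after treatment (min).
#' @param t_treat Treatment time (min); taken from the trace when
#'   absent.
#' @return List with `amplitude` (dimensionless), `time_to_peak_min`
#'   (`NA` and `censored = TRUE` when the series never rises above its
#'   treatment value), and `nc_at_treatment`.
#' @export
first_response <- function(x, window = 120, t_treat = NULL) {
  s <- .nc_series(x, t_treat)
  stopifnot(!is.null(s$t_treat), window > 0)
  if (s$t_treat < min(s$time) || s$t_treat > max(s$time))
    stop("treatment time outside the recorded grid")
  nc0 <- stats::approx(s$time, s$nc, xout = s$t_treat)$y
  if (!is.finite(nc0) || nc0 == 0)
    stop("degenerate N:C ratio at treatment")
  win <- s$time > s$t_treat & s$time <= s$t_treat + window
  if (!any(win))
    stop("no samples inside the response window")
  amp <- max(s$nc[win]) / nc0
  if (amp <= 1) {
    return(list(amplitude = max(amp, 1), time_to_peak_min = NA_real_,
                censored = TRUE, nc_at_treatment = nc0))
  }
  tp <- s$time[win][which.max(s$nc[win])] - s$t_treat
  list(amplitude = amp, time_to_peak_min = tp, censored = FALSE,
       nc_at_treatment = nc0)
}

#' Refractory delay: treatment to the second nuclear RelA peak
#'
#' Peaks are detected on the treatment-normalized N:C series (divided
#' by the N:C value at treatment) restricted to post-treatment times.
#'
#' @inheritParams first_response
#' @param min_prominence,min_separation Peak-detector settings on the
#'   normalized series (see [detect_peaks()]).
#' @return List with `delay_min` (time from treatment to the second
#'   detected peak; `NA` with `censored = TRUE` when fewer than two
#'   peaks are found), `n_peaks`, and the detected `peaks` table.
#' @export
refractory_delay <- function(x, t_treat = NULL, min_prominence = 0.2,
                             min_separation = 40) {
  s <- .nc_series(x, t_treat)
  stopifnot(!is.null(s$t_treat))
  nc0 <- stats::approx(s$time, s$nc, xout = s$t_treat)$y
  post <- s$time >= s$t_treat
  pk <- detect_peaks(s$time[post], s$nc[post] / nc0,
                     min_prominence, min_separation)
  pk <- pk[pk$time > s$t_treat, , drop = FALSE]
  if (nrow(pk) < 2) {
    return(list(delay_min = NA_real_, censored = TRUE,
                n_peaks = nrow(pk), peaks = pk))
  }
  list(delay_min = pk$time[2] - s$t_treat, censored = FALSE,
       n_peaks = nrow(pk), peaks = pk)
}

#' Half-times of nuclear occupancy and E2F decay
#'
#' Nuclear-occupancy half-time: the time at which the N:C ratio first
#' falls halfway from its initial value to its final plateau (median
#' of the last 10 percent of samples), by linear interpolation. E2F
#' decay half-time: the time at which the E2F channel first falls to
#' half its initial value.
#'
#' @param x A `cell_trace` (uses `nuc_mean`/`cyt_mean` and `e2f1`), an
#'   [simulate_nfkb()] trajectory (uses the N:C series and total
#'   nuclear E2F-1), or `list(time, nc, e2f)`.
#' @return List with `t_half_occupancy_min`, `t_half_e2f_min`, and
#'   censoring flags (`TRUE` when the corresponding half level is
#'   never reached, in which case the time is `NA`).
#' @export
half_times <- function(x) {
  if (inherits(x, "cell_trace")) {
    time <- x$time_min; nc <- x$nuc_mean / x$cyt_mean; e2f <- x$e2f1
  } else if (inherits(x, "nfkb_trajectory")) {
    time <- x$time; nc <- x$nc_ratio
    e2f <- rowSums(x$state[, intersect(c("E2F1_n", "NFkB.E2F1_n"),
                                       colnames(x$state)), drop = FALSE])
  } else {
    time <- x$time; nc <- x$nc; e2f <- x$e2f
  }
  ok <- is.finite(nc)
  tocc <- NA_real_; cocc <- TRUE
  if (any(ok)) {
    tnc <- time[ok]; v <- nc[ok]
    plateau <- stats::median(v[seq(ceiling(0.9 * length(v)), length(v))])
    if (v[1] > plateau) {
      half <- plateau + (v[1] - plateau) / 2
      tocc <- .cross_down(tnc, v, half)
      cocc <- is.na(tocc)
    }
  }
  te2f <- NA_real_; ce2f <- TRUE
  if (!is.null(e2f) && length(e2f) && e2f[1] > 0) {
    te2f <- .cross_down(time, e2f, e2f[1] / 2)
    ce2f <- is.na(te2f)
  }
  list(t_half_occupancy_min = tocc, occupancy_censored = cocc,
       t_half_e2f_min = te2f, e2f_censored = ce2f)
}

#' Mitosis-to-mitosis cycle durations
#'
#' @param traces A list of `cell_trace` objects (or a
#'   `cell_population`).
#' @param spanning_time_min When given, only the single cycle that
#'   spans this time contributes per cell (used for treated-cell
#'   analyses); otherwise every pair of successive recorded mitoses
#'   contributes one duration.
#' @return Data frame with `cell_id` and `duration_h`; attribute
#'   `n_excluded` counts cells without a qualifying mitosis pair.
#' @export
cycle_durations <- function(traces, spanning_time_min = NULL) {
  if (inherits(traces, "cell_population")) traces <- traces$traces
  rows <- list(); excluded <- 0L
  for (tr in traces) {
    m <- tr$mitosis_times_min
    if (length(m) < 2) { excluded <- excluded + 1L; next }
    if (!is.null(spanning_time_min)) {
      k <- which(m[-length(m)] <= spanning_time_min &
                 m[-1] > spanning_time_min)
      if (!length(k)) { excluded <- excluded + 1L; next }
      d <- (m[k + 1] - m[k]) / 60
    } else {
      d <- diff(m) / 60
    }
    rows[[length(rows) + 1L]] <-
      data.frame(cell_id = tr$cell_id, duration_h = d)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), duration_h = numeric(0))
  attr(out, "n_excluded") <- excluded
  out
}

#' Feature table for a population of traces
#'
#' Applies [first_response()], [refractory_delay()] and [half_times()]
#' to each trace and assembles one row per cell with explicit
#' censoring flags.
#'
#' @param traces List of `cell_trace` objects or a `cell_population`.
#' @param window Response window for [first_response()] (min).
#' @param min_prominence,min_separation Peak-detector settings.
#' @return Data frame, one row per cell.
#' @export
trace_features <- function(traces, window = 120, min_prominence = 0.2,
                           min_separation = 40) {
  if (inherits(traces, "cell_population")) traces <- traces$traces
  rows <- lapply(traces, function(tr) {
    fr <- first_response(tr, window = window)
    rd <- refractory_delay(tr, min_prominence = min_prominence,
                           min_separation = min_separation)
    ht <- half_times(tr)
    p1p2 <- if (rd$n_peaks >= 2) diff(rd$peaks$time[1:2]) else NA_real_
    data.frame(cell_id = tr$cell_id,
               amplitude = fr$amplitude,
               time_to_peak_min = fr$time_to_peak_min,
               amplitude_censored = fr$censored,
               refractory_delay_min = rd$delay_min,
               refractory_censored = rd$censored,
               peak1_peak2_min = p1p2,
               t_half_occupancy_min = ht$t_half_occupancy_min,
               t_half_e2f_min = ht$t_half_e2f_min)
  })
  do.call(rbind, rows)
}
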