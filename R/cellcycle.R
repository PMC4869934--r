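# Cell-cycle programs: duration statistics, phase boundaries, E2F drive
# profiles, and FUCCI-based G1/S detection.

#' Define a cell-cycle program
#'
#' A cycle program describes the statistical and regulatory structure of
#' a cell line's division cycle: the mitosis-to-mitosis duration
#' distribution, the fractions of the cycle at which the G1/S window,
#' S phase and G2 begin, and smooth unimodal synthesis-drive profiles
#' for E2F-1 (peaking in late G1) and E2F-4 (peaking in S phase, i.e.
#' delayed by `e2f4_lag_frac` relative to E2F-1).
#'
#' Default boundary fractions (0.40, 0.50, 0.85) of a 20 h cycle give
#' G1 about 8 h, a 2 h late-G1 (G1/S) window, about 7 h of S phase and
#' 3 h of G2 — consistent with a double-thymidine release sitting at
#' the G1/S transition and release + 4 h in mid S phase.
#'
#' @param mean_duration_h Mean mitosis-to-mitosis duration (h).
#' @param sd_duration_h Between-cell SD of the duration (h).
#' @param g1s_start,s_start,g2_start Phase boundary fractions in (0,1),
#'   strictly increasing: G1 is `[0, g1s_start)`, the G1/S window
#'   `[g1s_start, s_start)`, S `[s_start, g2_start)`, G2 `[g2_start, 1)`.
#' @param e2f1_peak_frac Cycle fraction of peak E2F-1 drive; must lie
#'   within the G1/S window.
#' @param e2f1_width Log-scale width of the E2F-1 drive profile.
#' @param e2f1_amplitude Peak E2F-1 synthesis-rate multiplier.
#' @param e2f4_lag_frac Lag of the E2F-4 drive peak after the E2F-1
#'   peak, as a fraction of the cycle (> 0).
#' @param e2f4_width,e2f4_amplitude Width and peak multiplier of the
#'   E2F-4 drive profile.
#' @return An object of class `cycle_program`.
#' @export
cycle_program <- function(mean_duration_h = 20, sd_duration_h = 1.45,
                          g1s_start = 0.40, s_start = 0.50,
                          g2_start = 0.85,
                          e2f1_peak_frac = 0.45, e2f1_width = 0.18,
                          e2f1_amplitude = 1,
                          e2f4_lag_frac = 0.17, e2f4_width = 0.10,
                          e2f4_amplitude = 1) {
  stopifnot(mean_duration_h > 0, sd_duration_h >= 0,
            0 < g1s_start, g1s_start < s_start, s_start < g2_start,
            g2_start < 1,
            e2f1_peak_frac >= g1s_start, e2f1_peak_frac <= s_start,
            e2f4_lag_frac > 0, e2f1_width > 0, e2f4_width > 0,
            e2f1_amplitude >= 0, e2f4_amplitude >= 0)
  structure(list(mean_duration_h = mean_duration_h,
                 sd_duration_h = sd_duration_h,
                 g1s_start = g1s_start, s_start = s_start,
                 g2_start = g2_start,
                 e2f1_peak_frac = e2f1_peak_frac,
                 e2f1_width = e2f1_width,
                 e2f1_amplitude = e2f1_amplitude,
                 e2f4_lag_frac = e2f4_lag_frac,
                 e2f4_width = e2f4_width,
                 e2f4_amplitude = e2f4_amplitude),
            class = "cycle_program")
}

#' @export
print.cycle_program <- function(x, ...) {
  cat("cell-cycle program: T =", x$mean_duration_h, "+/-",
      x$sd_duration_h, "h\n")
  cat("  boundaries (fractions): G1/S", x$g1s_start, "| S", x$s_start,
      "| G2", x$g2_start, "\n")
  cat("  E2F-1 drive peak at", x$e2f1_peak_frac, "of T; E2F-4 lag",
      x$e2f4_lag_frac, "\n")
  invisible(x)
}

.PHASE_LEVELS <- c("G1", "G1/S", "S", "G2")

#' Cell-cycle phase at a time since mitosis
#'
#' Piecewise-constant phase assignment by boundary fractions of the
#' realized duration.
#'
#' @param t_since_mitosis_h Hours since the last mitosis, in
#'   `[0, duration_h)`. Vectorized.
#' @param program A [cycle_program()].
#' @param duration_h Realized cycle duration (h); defaults to the
#'   program mean.
#' @return Factor with levels `G1`, `G1/S`, `S`, `G2`.
#' @export
phase_label <- function(t_since_mitosis_h, program,
                        duration_h = program$mean_duration_h) {
  stopifnot(inherits(program, "cycle_program"))
  if (any(t_since_mitosis_h < 0 | t_since_mitosis_h >= duration_h))
    stop("t_since_mitosis_h must lie in [0, duration_h)")
  x <- t_since_mitosis_h / duration_h
  idx <- findInterval(x, c(0, program$g1s_start, program$s_start,
                           program$g2_start))
  factor(.PHASE_LEVELS[idx], levels = .PHASE_LEVELS)
}

# log-normal-shaped unimodal bump in cycle fraction, peak value 1 at xp
.lnorm_bump <- function(x, xp, width) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- exp(-(log(x[pos] / xp))^2 / (2 * width^2))
  out
}

#' E2F synthesis-drive multipliers along the cycle
#'
#' Smooth log-normal-shaped profiles for the cycle-gated synthesis of
#' E2F-1 (late-G1 peak) and E2F-4 (S-phase peak, lagged by the
#' program's `e2f4_lag_frac`). Both profiles fall below 5 percent of
#' their peak at mitosis (t = 0 and t = duration).
#'
#' @param t_since_mitosis_h Hours since mitosis (vectorized), in
#'   `[0, duration_h]`.
#' @inheritParams phase_label
#' @return List with numeric vectors `e2f1_rate` and `e2f4_rate`.
#' @export
e2f_drive <- function(t_since_mitosis_h, program,
                      duration_h = program$mean_duration_h) {
  stopifnot(inherits(program, "cycle_program"))
  if (any(t_since_mitosis_h < 0 | t_since_mitosis_h > duration_h))
    stop("t_since_mitosis_h must lie in [0, duration_h]")
  x <- t_since_mitosis_h / duration_h
  list(e2f1_rate = program$e2f1_amplitude *
         .lnorm_bump(x, program$e2f1_peak_frac, program$e2f1_width),
       e2f4_rate = program$e2f4_amplitude *
         .lnorm_bump(x, program$e2f1_peak_frac + program$e2f4_lag_frac,
                     program$e2f4_width))
}

#' G1/S transition time from FUCCI reporter crossing
#'
#' The crossing point of the two cell-cycle ubiquitin-ligase reporter
#' channels marks the G1/S transition: the earliest time at which
#' `red - green` changes sign from positive to negative, located by
#' linear interpolation between the bracketing samples. A tie (exact
#' zero) at a sample resolves to that sample's time.
#'
#' @param time Sampling times (shared grid, strictly increasing).
#' @param red,green Reporter intensity series on `time`.
#' @param smooth_window Optional centered moving-average window
#'   (odd number of samples; 1 = no smoothing).
#' @return The crossing time, or `NA` if the difference never crosses
#'   from positive to negative.
#' @export
fucci_crossing <- function(time, red, green, smooth_window = 1) {
  if (length(red) != length(green) || length(red) != length(time))
    stop("time, red and green must have equal length")
  if (smooth_window > 1) {
    w <- smooth_window
    if (w %% 2 == 0) stop("smooth_window must be odd")
    sm <- function(x) {
      f <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
      f[is.na(f)] <- x[is.na(f)]  # keep raw values at the edges
      f
    }
    red <- sm(red); green <- sm(green)
  }
  d <- red - green
  if (all(d == 0))
    stop("degenerate input: red - green is constant at zero")
  for (i in seq_len(length(d) - 1)) {
    if (d[i] == 0 && (i == 1 || d[i - 1] > 0)) return(time[i])
    if (d[i] > 0 && d[i + 1] < 0)
      return(time[i] + (time[i + 1] - time[i]) * d[i] / (d[i] - d[i + 1]))
    if (d[i] > 0 && d[i + 1] == 0) return(time[i + 1])
  }
  NA_real_
}
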