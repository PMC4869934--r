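# ODE model family: base NF-kB/IkBa/A20 oscillator, E2F-1 competition
# extension, and the revised E2F-4 / IkBa-stabilization variant.

.NFKB_SPECIES <- c("IKKn", "IKKa", "IKKi",
                   "NFkB_c", "NFkB_n",
                   "IkBa_c", "IkBa_n",
                   "NFkB.IkBa_c", "NFkB.IkBa_n",
                   "tIkBa", "tA20", "A20",
                   "E2F1_n", "NFkB.E2F1_n",
                   "E2F4_c", "NFkB.IkBa.E2F4_c")

.NFKB_COMPARTMENT <- c(IKKn = "cytoplasmic", IKKa = "cytoplasmic",
                       IKKi = "cytoplasmic",
                       NFkB_c = "cytoplasmic", NFkB_n = "nuclear",
                       IkBa_c = "cytoplasmic", IkBa_n = "nuclear",
                       "NFkB.IkBa_c" = "cytoplasmic",
                       "NFkB.IkBa_n" = "nuclear",
                       tIkBa = "cytoplasmic", tA20 = "cytoplasmic",
                       A20 = "cytoplasmic",
                       E2F1_n = "nuclear", "NFkB.E2F1_n" = "nuclear",
                       E2F4_c = "cytoplasmic",
                       "NFkB.IkBa.E2F4_c" = "cytoplasmic")

# RelA-containing species by compartment (fluorescent-reporter read-out)
.RELA_NUC <- c("NFkB_n", "NFkB.IkBa_n", "NFkB.E2F1_n")
.RELA_CYT <- c("NFkB_c", "NFkB.IkBa_c", "NFkB.IkBa.E2F4_c")

# Parameter order must match src/nfkb_ode.c
.NFKB_PARAM_NAMES <- c(
  "ka", "kp", "k3", "k2",
  "kaNI", "kdNI", "kc1", "kc2", "kdegI", "kdegIc",
  "kNin", "kNIex", "kIin", "kIex",
  "ktI", "ktI0", "KN", "hN", "kdeg_tI", "ktrI",
  "ktA", "ktA0", "kdeg_tA", "ktrA", "kdegA",
  "kE1syn", "KrepN", "kdegE1", "kaNE", "kdNE", "KrepE",
  "kE4syn", "kE4drv", "kdegE4", "kaE4", "kdE4",
  "TR")

#' Default kinetic parameters of the coupled NF-kB / E2F network
#'
#' Rates are per minute, bimolecular rates per nM per minute,
#' concentrations and half-max constants in nM. The IKK / IkBa / A20
#' core is parameterized to give damped nuclear RelA oscillations with
#' an inter-peak interval of roughly 100 min under sustained saturating
#' TNF-alpha and a predominantly cytoplasmic resting distribution; the
#' RelA:E2F-1 dissociation constant `kdNE/kaNE` defaults to 12 nM, the
#' value measured for the nuclear complex by cross-correlation
#' spectroscopy.
#'
#' @return Named numeric vector of all kinetic parameters.
#' @export
nfkb_default_params <- function() {
  c(ka      = 0.05,   kp     = 0.03,  k3      = 0.02,  k2     = 0.002,
    kaNI    = 0.5,    kdNI   = 0.05,  kc1     = 0.005, kc2    = 0.005,
    kdegI   = 0.01,   kdegIc = 2e-4,
    kNin    = 2,      kNIex  = 0.5,   kIin    = 0.03,  kIex   = 0.01,
    ktI     = 1,      ktI0   = 0.01,  KN      = 10,    hN     = 3,
    kdeg_tI = 0.02,   ktrI   = 0.5,
    ktA     = 0.1,    ktA0   = 0.001, kdeg_tA = 0.03,  ktrA   = 0.5,
    kdegA   = 0.02,
    kE1syn  = 0.5,    KrepN  = 10,    kdegE1  = 0.0043,
    kaNE    = 0.01,   kdNE   = 0.12,  KrepE   = 5,
    kE4syn  = 0.01,   kE4drv = 0,     kdegE4  = 0.007,
    kaE4    = 0.01,   kdE4   = 0.05,
    TR      = 0)
}

# parameters zeroed per variant (nested reductions are exact)
.VARIANT_ZERO <- list(
  base    = c("kE1syn", "kaNE", "kE4syn", "kE4drv", "kaE4"),
  e2f1    = c("kE4syn", "kE4drv", "kaE4"),
  revised = character(0))

.VARIANT_SPECIES <- list(
  base    = .NFKB_SPECIES[1:12],
  e2f1    = .NFKB_SPECIES[1:14],
  revised = .NFKB_SPECIES)

#' Build an NF-kB / E2F reaction-network model
#'
#' Constructs one of three nested ODE model variants:
#' \describe{
#'   \item{`base`}{the TNF-alpha-driven NF-kB oscillator: IKK
#'     activation with A20-mediated inactivation, IKK-driven IkBa
#'     degradation (free and complexed), nuclear import of free RelA,
#'     NF-kB-driven IkBa and A20 transcription, and IkBa-mediated
#'     nuclear export.}
#'   \item{`e2f1`}{adds reversible nuclear RelA:E2F-1 binding
#'     (competing with IkBa for free RelA), multiplicative repression
#'     of NF-kB-driven IkBa transcription by E2F-1, repression of
#'     E2F-1 synthesis by nuclear RelA, and first-order E2F-1
#'     turnover.}
#'   \item{`revised`}{adds E2F-1-driven E2F-4 synthesis and reversible
#'     E2F-4 binding to the cytoplasmic RelA:IkBa complex; the IkBa in
#'     this ternary complex is protected from IKK-driven degradation.}
#' }
#' The variants are strict supersets: zeroing the E2F-4 couplings of
#' `revised` recovers `e2f1`, and zeroing the E2F-1 couplings of
#' `e2f1` recovers `base` exactly. Total RelA (free plus all
#' complexes, both compartments) is conserved in every variant.
#'
#' @param variant One of `"base"`, `"e2f1"`, `"revised"`.
#' @param overrides Named numeric vector or list of parameter
#'   overrides; names must exist in [nfkb_default_params()]. Rate
#'   parameters must be non-negative; half-max constants strictly
#'   positive; the Hill coefficient `hN` at least 1.
#' @return An object of class `nfkb_model`: a list with `variant`,
#'   `species` (the variant's species names), `compartment`, `params`,
#'   and `stimulus_coupling` (the TNF-activated step, `"ka"`).
#' @examples
#' m <- nfkb_model("base")
#' m$species
#' @export
nfkb_model <- function(variant = c("base", "e2f1", "revised"),
                       overrides = NULL) {
  variant <- match.arg(variant)
  params <- nfkb_default_params()
  if (length(overrides)) {
    overrides <- unlist(overrides)
    unknown <- setdiff(names(overrides), names(params))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    if (any(!is.finite(overrides)) || any(overrides < 0))
      stop("parameter overrides must be finite and non-negative")
    params[names(overrides)] <- overrides
  }
  if (params[["hN"]] < 1)
    stop("Hill coefficient 'hN' must be >= 1")
  strictly_pos <- c("KN", "KrepN", "KrepE")
  if (any(params[strictly_pos] <= 0))
    stop("half-max constants (KN, KrepN, KrepE) must be strictly positive")
  params[.VARIANT_ZERO[[variant]]] <- 0
  structure(list(variant = variant,
                 species = .VARIANT_SPECIES[[variant]],
                 compartment = .NFKB_COMPARTMENT[.VARIANT_SPECIES[[variant]]],
                 params = params,
                 stimulus_coupling = "ka"),
            class = "nfkb_model")
}

#' @export
print.nfkb_model <- function(x, ...) {
  cat("NF-kB / E2F ODE model, variant '", x$variant, "'\n", sep = "")
  cat("  species (", length(x$species), "): ",
      paste(x$species, collapse = ", "), "\n", sep = "")
  cat("  stimulus coupling: TNF-alpha scales '", x$stimulus_coupling,
      "'\n", sep = "")
  invisible(x)
}

#' Default initial state for a model
#'
#' All RelA starts in the cytoplasmic RelA:IkBa complex and all IKK in
#' the neutral pool; every other species starts at zero.
#'
#' @param model An [nfkb_model()].
#' @param total_rela,total_ikk Total RelA and IKK pools (nM).
#' @return Named non-negative state vector over the full network.
#' @export
nfkb_initial_state <- function(model, total_rela = 100, total_ikk = 100) {
  y <- stats::setNames(numeric(length(.NFKB_SPECIES)), .NFKB_SPECIES)
  y["IKKn"] <- total_ikk
  y["NFkB.IkBa_c"] <- total_rela
  y
}

#' TNF-alpha stimulus protocol
#'
#' @param onset_min,offset_min Stimulus window in minutes;
#'   `offset_min` may be `Inf` for sustained stimulation.
#' @param dose_scale Dose in `[0, 1]`; 1 corresponds to a saturating
#'   10 ng/ml TNF-alpha dose.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(onset_min = 0, offset_min = Inf,
                              dose_scale = 1) {
  stopifnot(is.finite(onset_min), onset_min < offset_min,
            dose_scale >= 0, dose_scale <= 1)
  structure(list(onset_min = onset_min, offset_min = offset_min,
                 dose_scale = dose_scale),
            class = "stimulus_protocol")
}

.full_state <- function(state) {
  y <- stats::setNames(numeric(length(.NFKB_SPECIES)), .NFKB_SPECIES)
  if (is.null(names(state))) {
    stopifnot(length(state) == length(y))
    y[] <- state
  } else {
    unknown <- setdiff(names(state), .NFKB_SPECIES)
    if (length(unknown))
      stop("unknown species: ", paste(unknown, collapse = ", "))
    y[names(state)] <- state
  }
  y[y < 0 & y > -1e-9] <- 0  # tolerate solver-level round-off only
  if (any(y < 0)) stop("state must be non-negative")
  y
}

.constant_forcings <- function(t0, t1, drives = NULL) {
  span <- c(t0 - 1, t1 + 1)
  if (is.null(drives))
    return(list(cbind(span, c(1, 1)), cbind(span, c(1, 1))))
  as_forc <- function(f) {
    if (is.null(f)) return(cbind(span, c(1, 1)))
    stopifnot(is.matrix(f) || is.data.frame(f), ncol(f) == 2)
    f <- as.matrix(f)
    rbind(c(span[1], f[1, 2]), f, c(span[2], f[nrow(f), 2]))
  }
  list(as_forc(drives$e2f1), as_forc(drives$e2f4))
}

.ode_segment <- function(y, times, params, forcings, rtol, atol) {
  out <- deSolve::ode(y = y, times = times, func = "nfkb_derivs",
                      parms = unname(params[.NFKB_PARAM_NAMES]),
                      dllname = "nfkbcycle",
                      initfunc = "nfkb_initmod",
                      initforc = "nfkb_initforc",
                      forcings = forcings,
                      fcontrol = list(method = "linear", rule = 2),
                      nout = 1, outnames = "nc_ratio",
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failure near t = ",
         signif(out[nrow(out), "time"], 6), " min")
  out
}

#' Simulate a single cell's trajectory
#'
#' Integrates the model with a stiff-capable solver (`lsoda`, relative
#' tolerance 1e-8, absolute tolerance 1e-10 nM) over a strictly
#' increasing time grid, applying the TNF-alpha protocol piecewise so
#' stimulus onset and offset are handled as exact solver restarts.
#'
#' @param model An [nfkb_model()].
#' @param state0 Initial state: named vector over (a subset of) the
#'   network species, or `NULL` for [nfkb_initial_state()].
#' @param protocol A [stimulus_protocol()]; `NULL` means no stimulus.
#' @param times Strictly increasing time grid (min).
#' @param drives Optional list with elements `e2f1` and/or `e2f4`:
#'   two-column matrices (time, multiplier) gating the E2F synthesis
#'   rates, linearly interpolated; absent drives are constant 1.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `nfkb_trajectory`: list with `time`,
#'   `state` (matrix, one column per species of the variant),
#'   `nc_ratio` (nuclear over cytoplasmic total RelA), and the
#'   conservation drift of total RelA.
#' @export
simulate_nfkb <- function(model, state0 = NULL, protocol = NULL,
                          times = seq(0, 600, by = 5), drives = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "nfkb_model"))
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  y <- if (is.null(state0)) nfkb_initial_state(model) else .full_state(state0)
  forc <- .constant_forcings(min(times), max(times), drives)

  # split grid at protocol boundaries
  t0 <- min(times); t1 <- max(times)
  cuts <- numeric(0)
  dose <- 0
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "stimulus_protocol"))
    dose <- protocol$dose_scale
    cuts <- c(protocol$onset_min, protocol$offset_min)
    cuts <- cuts[is.finite(cuts) & cuts > t0 & cuts < t1]
  }
  bounds <- sort(unique(c(t0, cuts, t1)))
  tr_at <- function(tm) {
    if (is.null(protocol)) return(0)
    if (tm >= protocol$onset_min && tm < protocol$offset_min) dose else 0
  }

  rows <- list()
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    seg_times <- sort(unique(c(a, times[times > a & times < b], b)))
    p <- model$params
    p["TR"] <- tr_at((a + b) / 2)
    out <- .ode_segment(y, seg_times, p, forc, rtol, atol)
    y <- out[nrow(out), 1 + seq_along(.NFKB_SPECIES)]
    names(y) <- .NFKB_SPECIES
    keep <- out[, "time"] %in% times
    if (i > 1) keep[1] <- FALSE  # boundary row already emitted
    rows[[i]] <- out[keep, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  state <- out[, 1 + seq_along(.NFKB_SPECIES), drop = FALSE]
  colnames(state) <- .NFKB_SPECIES
  if (min(state) < -1e-9)
    stop("negative species value beyond tolerance: ", min(state))
  state[state < 0] <- state[state < 0]  # no clipping; kept as computed

  total <- rowSums(state[, c(.RELA_NUC, .RELA_CYT), drop = FALSE])
  drift <- max(abs(total - total[1])) / total[1]
  structure(list(time = out[, "time"],
                 state = state[, model$species, drop = FALSE],
                 nc_ratio = out[, "nc_ratio"],
                 rela_drift = drift,
                 variant = model$variant),
            class = "nfkb_trajectory")
}

#' @export
print.nfkb_trajectory <- function(x, ...) {
  cat("nfkb_trajectory (variant '", x$variant, "'): ",
      length(x$time), " time points over [",
      min(x$time), ", ", max(x$time), "] min\n", sep = "")
  cat("  N:C RelA range: ", signif(min(x$nc_ratio), 4), " - ",
      signif(max(x$nc_ratio), 4),
      "; total-RelA drift ", format(x$rela_drift, digits = 3), "\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.nfkb_trajectory <- function(x, ...) {
  data.frame(time_min = rep(x$time, ncol(x$state)),
             species = rep(colnames(x$state), each = length(x$time)),
             compartment = rep(unname(
               .NFKB_COMPARTMENT[colnames(x$state)]), each = length(x$time)),
             value_nM = as.vector(x$state))
}

#' @export
plot.nfkb_trajectory <- function(x, ...) {
  graphics::plot(x$time, x$nc_ratio, type = "l",
                 xlab = "time (min)", ylab = "N:C RelA ratio", ...)
  invisible(x)
}

.nfkb_derivative <- function(params, state) {
  f <- deSolve::DLLfunc(y = state, times = 0, func = "nfkb_derivs",
                        parms = unname(params[.NFKB_PARAM_NAMES]),
                        dllname = "nfkbcycle",
                        initfunc = "nfkb_initmod",
                        initforc = "nfkb_initforc",
                        forcings = list(cbind(c(-1, 1), 1),
                                        cbind(c(-1, 1), 1)),
                        nout = 1)
  f$dy
}

#' Relax a model to its unstimulated steady state
#'
#' Integrates without stimulus until the state stops changing, then
#' verifies that the maximum absolute time-derivative is below `tol`.
#'
#' @param model An [nfkb_model()].
#' @param init Initial state (default [nfkb_initial_state()]).
#' @param horizon Integration horizon (min).
#' @param tol Residual tolerance on the max absolute derivative
#'   (nM/min).
#' @return The equilibrated named state vector, with attribute
#'   `"residual"` (max absolute derivative).
#' @export
equilibrate <- function(model, init = NULL, horizon = 20000, tol = 1e-8) {
  stopifnot(horizon > 0, tol > 0)
  y <- if (is.null(init)) nfkb_initial_state(model) else .full_state(init)
  p <- model$params
  p["TR"] <- 0
  forc <- .constant_forcings(0, horizon)
  out <- .ode_segment(y, c(0, horizon / 2, horizon), p, forc,
                      rtol = 1e-10, atol = 1e-12)
  y <- out[nrow(out), 1 + seq_along(.NFKB_SPECIES)]
  names(y) <- .NFKB_SPECIES
  y[y < 0 & y > -1e-12] <- 0
  res <- max(abs(.nfkb_derivative(p, y)))
  if (res > tol)
    stop("equilibration failed: residual ", format(res, digits = 3),
         " > tol ", tol, " after ", horizon, " min")
  attr(y, "residual") <- res
  y
}

#' Nuclear:cytoplasmic RelA ratio of a state
#'
#' @param state Named state vector (full network).
#' @return Nuclear over cytoplasmic total RelA.
#' @export
nc_ratio <- function(state) {
  s <- .full_state(state)
  sum(s[.RELA_NUC]) / sum(s[.RELA_CYT])
}

#' Nuclear-occupancy half-time under E2F-1 co-expression decay
#'
#' Emulates the co-transfection experiment in which RelA starts
#' nuclear, bound to E2F-1, and relocalizes to the cytoplasm as E2F-1
#' decays: the model is initialized with the whole RelA pool in the
#' nuclear RelA:E2F-1 complex, E2F-1 synthesis switched off, and the
#' E2F-1 degradation rate set from `e2f1_half_life`. Returns the time
#' for the N:C RelA ratio to fall halfway from its initial value to
#' its post-decay plateau.
#'
#' @param model An [nfkb_model()] of variant `e2f1` or `revised`.
#' @param e2f1_half_life E2F-1 protein half-life (min).
#' @param e2f1_syn Constitutive E2F-1 synthesis rate (nM/min) used to
#'   establish the nuclear-RelA co-expression equilibrium before the
#'   synthesis switch-off.
#' @param horizon Simulation horizon (min); extended automatically for
#'   long half-lives.
#' @return Half-occupancy time `T_half_NO` in minutes, or `NA` with
#'   attribute `censored = TRUE` when the N:C ratio never declines to
#'   the half level.
#' @export
coexpression_half_time <- function(model, e2f1_half_life,
                                   e2f1_syn = 2, horizon = NULL) {
  stopifnot(inherits(model, "nfkb_model"),
            model$variant %in% c("e2f1", "revised"),
            e2f1_half_life > 0)
  m0 <- model
  m0$params["kE1syn"] <- e2f1_syn
  pre <- simulate_nfkb(m0, protocol = NULL,
                       times = seq(0, 60000, by = 500))
  y <- pre$state[nrow(pre$state), ]
  y[y < 0] <- 0
  m <- model
  m$params["kdegE1"] <- log(2) / e2f1_half_life
  m$params["kE1syn"] <- 0
  if (is.null(horizon)) horizon <- max(1200, 12 * e2f1_half_life)
  traj <- simulate_nfkb(m, state0 = y, protocol = NULL,
                        times = seq(0, horizon, by = 2))
  ok <- is.finite(traj$nc_ratio)  # N:C undefined while cytoplasm holds no RelA
  nc <- traj$nc_ratio[ok]
  traj$time <- traj$time[ok]
  plateau <- stats::median(nc[seq(ceiling(0.9 * length(nc)), length(nc))])
  half <- plateau + (nc[1] - plateau) / 2
  if (nc[1] <= plateau || all(nc > half)) {
    out <- NA_real_
    attr(out, "censored") <- TRUE
    return(out)
  }
  .cross_down(traj$time, nc, half)
}

# first downward crossing of `level`, linearly interpolated
.cross_down <- function(t, x, level) {
  below <- which(x <= level)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(t[1])
  t[i - 1] + (t[i] - t[i - 1]) * (x[i - 1] - level) / (x[i - 1] - x[i])
}
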