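# YAML model/scenario configuration and tidy trajectory output.

#' Read a model configuration from YAML
#'
#' The file may contain blocks `variant`, `params` (overrides),
#' `protocol` (`onset_min`, `offset_min`, `dose_scale`) and `grid`
#' (`t_end_min`, `dt_min`).
#'
#' @param path YAML file path.
#' @return List with `model` ([nfkb_model()]), `protocol`
#'   ([stimulus_protocol()] or `NULL`) and `times` (numeric grid).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  variant <- if (is.null(cfg$variant)) "base" else cfg$variant
  model <- nfkb_model(variant, overrides = unlist(cfg$params))
  protocol <- NULL
  if (!is.null(cfg$protocol)) {
    off <- cfg$protocol$offset_min
    protocol <- stimulus_protocol(
      onset_min = cfg$protocol$onset_min %||% 0,
      offset_min = if (is.null(off) || identical(off, "inf")) Inf
                   else off,
      dose_scale = cfg$protocol$dose_scale %||% 1)
  }
  times <- if (!is.null(cfg$grid))
    seq(0, cfg$grid$t_end_min, by = cfg$grid$dt_min %||% 5) else
    seq(0, 600, by = 5)
  list(model = model, protocol = protocol, times = times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory as tidy CSV
#'
#' One row per time point and species (`time_min, species,
#' compartment, value_nM`), plus a companion `<path>_nc.csv` with the
#' derived N:C RelA ratio series.
#'
#' @param traj An [simulate_nfkb()] trajectory.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "nfkb_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  utils::write.csv(data.frame(time_min = traj$time,
                              nc_ratio = traj$nc_ratio),
                   paste0(sub("\\.csv$", "", path), "_nc.csv"),
                   row.names = FALSE)
  invisible(path)
}
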