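#' Read and write the package's CSV schemas
#'
#' Plain-UTF-8 CSV with '.' decimal separator and ISO years. The schemas:
#' observations (`year, ch4_ppb, ch4_sigma, d13c_permil, d13c_sigma`),
#' inventories (`dataset, sector, year, hemisphere, flux_tg`), gridded
#' rasters (`lat, lon, value[, sigma]`), model trajectories (as produced by
#' [run_forward()]) and ensemble score tables.
#'
#' @param path File path.
#' @return `read_observations()` returns an [observation_record()];
#'   `read_inventory()` a validated inventory data frame; `read_raster()` a
#'   [gridded_field()].
#' @name ch4box-io
NULL

#' @rdname ch4box-io
#' @export
read_observations <- function(path) {
  observation_record(utils::read.csv(path))
}

#' @rdname ch4box-io
#' @param obs An [observation_record()].
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ch4box-io
#' @export
read_inventory <- function(path) {
  inv <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sector", "year", "hemisphere", "flux_tg")
  if (!all(req %in% names(inv))) {
    stop("inventory CSV must have columns ", paste(req, collapse = ", "))
  }
  inv
}

#' @rdname ch4box-io
#' @export
read_raster <- function(path) {
  df <- utils::read.csv(path)
  req <- c("lat", "lon", "value")
  if (!all(req %in% names(df))) {
    stop("raster CSV must have columns ", paste(req, collapse = ", "))
  }
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  idx <- cbind(match(df$lat, lat), match(df$lon, lon))
  val <- matrix(NA_real_, length(lat), length(lon))
  val[idx] <- df$value
  sig <- NULL
  if ("sigma" %in% names(df)) {
    sig <- matrix(NA_real_, length(lat), length(lon))
    sig[idx] <- df$sigma
  }
  if (any(is.na(val))) stop("raster CSV does not cover the full grid")
  gridded_field(lat, lon, val, sig)
}

#' @rdname ch4box-io
#' @param field A [gridded_field()].
#' @export
write_raster <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  df <- expand.grid(lat = field$lat, lon = field$lon)
  df$value <- as.numeric(field$values)
  if (!is.null(field$sigma)) df$sigma <- as.numeric(field$sigma)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Loads (or builds) the configuration bundle shared by the pipeline stages,
#' with every convention constant pinned to its default: interhemispheric
#' exchange time 1 yr, 1000 Monte Carlo draws, first-percentile selection,
#' 0.04 permil observational delta uncertainty, VPDB ratio 1.12372%, and
#' 2.767 Tg per ppb. A YAML file may override any field; unknown fields are
#' rejected.
#'
#' @param path Optional YAML file with overrides.
#' @param ... Named overrides applied after the file.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    n_draws = 1000,
    percentile = 1,
    tau_ex = 1,
    k_minor = 0,
    d13c_obs_sigma = 0.04,
    r_std = 0.0112372,
    tg_per_ppb = 2.767,
    onset_years = 3,
    eps_bracket = c(-12, -1),
    soil_delta = -47.3,
    seed = 1,
    score_years = NULL
  )
  apply_over <- function(cfg, over, src) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0) {
      stop("unknown config field(s) in ", src, ": ",
           paste(bad, collapse = ", "))
    }
    utils::modifyList(cfg, over)
  }
  if (!is.null(path)) cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  over <- list(...)
  if (length(over) > 0) cfg <- apply_over(cfg, over, "arguments")
  stopifnot(cfg$n_draws >= 0, cfg$percentile > 0, cfg$percentile <= 100,
            cfg$tau_ex > 0, cfg$r_std > 0, cfg$tg_per_ppb > 0)
  structure(cfg, class = "run_config")
}

#' Write an ensemble result to disk
#'
#' Writes the score table as CSV and a JSON summary (seed, ensemble size,
#' selection, epsilon distribution) alongside it.
#'
#' @param ens A `ch4_ensemble` from [run_ensemble()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_ensemble <- function(ens, dir) {
  stopifnot(inherits(ens, "ch4_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scores_path <- file.path(dir, "scores.csv")
  utils::write.csv(ens$scores, scores_path, row.names = FALSE)
  summary_path <- file.path(dir, "ensemble_summary.json")
  s <- ens$scores
  jsonlite::write_json(list(
    seed = ens$seed, n_draws = ens$n_draws,
    n_scenarios = nrow(ens$scenarios), n_runs = nrow(s),
    n_feasible = sum(s$feasible), n_selected = sum(s$selected),
    percentile = ens$percentile,
    epsilon_mean = mean(s$epsilon[s$feasible]),
    epsilon_sd = stats::sd(s$epsilon[s$feasible]),
    msd_min = min(s$msd[s$feasible]),
    score_years = range(ens$score_years)
  ), summary_path, auto_unbox = TRUE, digits = NA)
  invisible(c(scores_path, summary_path))
}
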