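#' Score a simulated delta-13C series against observations
#'
#' Computes the statistics used to rank ensemble runs: RMSE, its square the
#' mean squared difference (MSD), Pearson correlation, the standard
#' deviations of both series, and the centered (pattern) RMSE. Standard
#' deviations use the n-denominator so the Taylor identity
#' `crmse^2 = sd_sim^2 + sd_obs^2 - 2*sd_sim*sd_obs*r` holds exactly.
#'
#' @param sim,obs Aligned numeric series (same years, length >= 3).
#' @param run_id Optional identifier carried into the result row.
#' @param mean_source_delta Optional mean source signature before
#'   fractionation (permil) carried into the result row.
#' @return One-row data frame: `run_id`, `rmse`, `msd`, `r`, `sd_sim`,
#'   `sd_obs`, `crmse`, `bias`, `mean_source_delta`.
#' @export
score_run <- function(sim, obs, run_id = NA_character_,
                      mean_source_delta = NA_real_) {
  if (length(sim) != length(obs)) stop("sim and obs lengths differ")
  n <- length(sim)
  if (n < 3) stop("need at least 3 points for a defined correlation")
  if (!all(is.finite(sim)) || !all(is.finite(obs))) {
    stop("non-finite values in scored series")
  }
  d <- sim - obs
  msd <- mean(d^2)
  cs <- sim - mean(sim)
  co <- obs - mean(obs)
  sd_sim <- sqrt(mean(cs^2))
  sd_obs <- sqrt(mean(co^2))
  r <- if (sd_sim == 0 || sd_obs == 0) NA_real_ else {
    mean(cs * co) / (sd_sim * sd_obs)
  }
  data.frame(run_id = run_id, rmse = sqrt(msd), msd = msd, r = r,
             sd_sim = sd_sim, sd_obs = sd_obs,
             crmse = sqrt(mean((cs - co)^2)), bias = mean(d),
             mean_source_delta = mean_source_delta,
             stringsAsFactors = FALSE)
}

#' Select the most likely runs by lowest MSD
#'
#' Sorts the score table ascending by MSD and keeps the lowest
#' `floor(percentile/100 * n)` runs; ties are broken by the stable original
#' row order. Failed runs must be excluded beforehand.
#'
#' @param scores Data frame with at least an `msd` column (one row per run).
#' @param percentile Percentage of runs to keep, in (0, 100].
#' @return The input with a logical `selected` column added; the attribute
#'   `"n_selected"` records the subset size.
#' @export
select_most_likely <- function(scores, percentile = 1) {
  if (!is.data.frame(scores) || nrow(scores) == 0L) {
    stop("scores must be a non-empty data frame")
  }
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 100) {
    stop("percentile must lie in (0, 100]")
  }
  n_keep <- floor(percentile / 100 * nrow(scores))
  ord <- order(scores$msd)  # radix order: stable for ties
  sel <- rep(FALSE, nrow(scores))
  if (n_keep > 0) sel[ord[seq_len(n_keep)]] <- TRUE
  scores$selected <- sel
  attr(scores, "n_selected") <- n_keep
  scores
}
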