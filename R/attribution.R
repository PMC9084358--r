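#' Named analysis periods of the study span
#'
#' The four growth regimes of the atmospheric CH4 record plus the post-2007
#' composite used for the headline attribution: decreased growth 1993-1999,
#' plateau (stabilization) 2000-2006, renewed growth 2007-2012, accelerated
#' growth 2013-2017, and post-2007 (2007-2017, the union of the last two).
#' All attribution deltas are taken relative to the plateau.
#'
#' @return Data frame with columns `period`, `start`, `end`.
#' @export
period_set <- function() {
  data.frame(
    period = c("decline", "plateau", "renewed", "accelerated", "post2007"),
    start = c(1993, 2000, 2007, 2013, 2007),
    end = c(1999, 2006, 2012, 2017, 2017),
    stringsAsFactors = FALSE
  )
}

#' Mean-flux changes of a series relative to the plateau
#'
#' For each period, the mean of the series over the period minus its mean
#' over the reference (plateau) period.
#'
#' @param series Data frame with columns `year` and `value` (or a numeric
#'   vector with `years` supplied).
#' @param periods A [period_set()]-style data frame.
#' @param years Years of `series` when it is a bare numeric vector.
#' @param reference Name of the reference period (default `"plateau"`).
#' @return Data frame `period`, `delta` (same units as the series).
#' @export
period_delta <- function(series, periods = period_set(), years = NULL,
                         reference = "plateau") {
  if (is.data.frame(series)) {
    years <- series$year
    values <- series$value
  } else {
    values <- series
    if (is.null(years)) stop("years must be given for a bare vector")
  }
  if (!reference %in% periods$period) stop("unknown reference period")
  pmean <- function(p) {
    i <- periods$period == p
    yr <- seq(periods$start[i], periods$end[i])
    if (!all(yr %in% years)) stop("series does not cover period ", p)
    mean(values[years %in% yr])
  }
  ref <- pmean(reference)
  data.frame(period = periods$period,
             delta = vapply(periods$period, pmean, numeric(1)) - ref,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent shares of a total emission change across categories
#'
#' Per run, the share of each category is its flux change divided by the sum
#' of changes over the categories in the denominator (the three headline
#' categories IFF, AGW, WET by convention); the ensemble mean and 1-sigma are
#' reported across runs. Runs whose summed change is ~0 are excluded with a
#' count. Runs with mixed-sign changes keep their raw shares, which can fall
#' outside [0, 100]%.
#'
#' @param deltas Matrix or data frame, one row per run, one column per
#'   category (Tg/yr changes).
#' @param zero_tol Absolute threshold on the summed change below which a
#'   run's shares are undefined.
#' @return List: `per_run` (share matrix, %), `summary` (data frame
#'   `category`, `delta_mean`, `delta_sigma`, `share_mean`, `share_sigma`),
#'   `n_excluded`.
#' @export
contribution_shares <- function(deltas, zero_tol = 1e-9) {
  m <- as.matrix(deltas)
  if (is.null(colnames(m))) stop("deltas must have category column names")
  tot <- rowSums(m)
  ok <- abs(tot) > zero_tol
  shares <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  shares[ok, ] <- 100 * m[ok, , drop = FALSE] / tot[ok]
  summ <- data.frame(
    category = colnames(m),
    delta_mean = colMeans(m),
    delta_sigma = apply(m, 2, stats::sd),
    share_mean = colMeans(shares[ok, , drop = FALSE]),
    share_sigma = apply(shares[ok, , drop = FALSE], 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_run = shares, summary = summ, n_excluded = sum(!ok))
}

#' Per-category share of the annual source 13CH4 mass
#'
#' Splits each category's flux into isotopologues at its signature and
#' reports each category's percent share of the total 13CH4 source mass per
#' year, period averages, and the change of the period averages relative to
#' the plateau.
#'
#' @param fluxes Data frame `category`, `year`, `flux_tg` (global totals).
#' @param deltas Named vector of category signatures (permil), or a data
#'   frame `category`, `year`, `delta` for year-varying signatures.
#' @param periods A [period_set()]-style data frame.
#' @param conv A [delta_convention()].
#' @return List: `annual` (data frame `category`, `year`, `share_pct`),
#'   `period_change` (data frame `category`, `period`, `share_pct`,
#'   `change_pct` vs the plateau).
#' @export
c13_mass_share <- function(fluxes, deltas, periods = period_set(),
                           conv = delta_convention()) {
  if (is.data.frame(deltas)) {
    key <- paste(fluxes$category, fluxes$year)
    dv <- deltas$delta[match(key, paste(deltas$category, deltas$year))]
  } else {
    dv <- deltas[fluxes$category]
  }
  if (any(is.na(dv))) stop("missing signature for some category/year")
  s13 <- split_isotopologues(fluxes$flux_tg, as.numeric(dv), conv)$s13
  tot <- tapply(s13, fluxes$year, sum)
  if (any(tot <= 0)) stop("zero total 13CH4 source mass in some year")
  annual <- data.frame(category = fluxes$category, year = fluxes$year,
                       share_pct = 100 * s13 / as.numeric(tot[as.character(fluxes$year)]),
                       stringsAsFactors = FALSE)
  per <- do.call(rbind, lapply(seq_len(nrow(periods)), function(i) {
    yr <- seq(periods$start[i], periods$end[i])
    sub <- annual[annual$year %in% yr, ]
    agg <- tapply(sub$share_pct, sub$category, mean)
    data.frame(category = names(agg), period = periods$period[i],
               share_pct = as.numeric(agg), stringsAsFactors = FALSE)
  }))
  ref <- per[per$period == "plateau", ]
  per$change_pct <- per$share_pct -
    ref$share_pct[match(per$category, ref$category)]
  list(annual = annual, period_change = per)
}

#' Centered moving-average anomaly of an annual series
#'
#' Smooths with a centered moving window (truncated at the series edges) and
#' subtracts the smoothed value at a reference year.
#'
#' @param values Numeric series.
#' @param years Corresponding years.
#' @param window Odd window length in years (default 7).
#' @param ref_year Year whose smoothed value is subtracted (default 2001).
#' @return Data frame `year`, `smoothed`, `anomaly`.
#' @export
moving_anomaly <- function(values, years, window = 7, ref_year = 2001) {
  n <- length(values)
  stopifnot(length(years) == n)
  if (window %% 2 != 1) stop("window must be odd")
  if (window > n) stop("window longer than the series")
  if (!ref_year %in% years) stop("series does not cover the reference year")
  h <- (window - 1) / 2
  sm <- vapply(seq_len(n), function(i) {
    mean(values[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  data.frame(year = years, smoothed = sm,
             anomaly = sm - sm[years == ref_year])
}

#' Least-squares linear trend with significance test
#'
#' Ordinary least-squares slope of a series against year, with the two-sided
#' t-test on the slope and a 95%-confidence significance flag. A constant
#' series returns slope 0 with p = 1 by convention.
#'
#' @param values Numeric series (length >= 3).
#' @param years Corresponding years.
#' @return List: `slope` (units/yr), `p_value`, `significant` (p < 0.05).
#' @export
linear_trend <- function(values, years) {
  n <- length(values)
  stopifnot(length(years) == n)
  if (n < 3) stop("need at least 3 points for a trend")
  if (stats::sd(values) == 0) {
    return(list(slope = 0, p_value = 1, significant = FALSE))
  }
  fit <- stats::lm(values ~ years)
  co <- summary(fit)$coefficients
  p <- co["years", "Pr(>|t|)"]
  list(slope = unname(co["years", "Estimate"]), p_value = unname(p),
       significant = unname(p) < 0.05)
}
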