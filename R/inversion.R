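#' Observation record
#'
#' Validates a data frame of annual global observations: CH4 mixing ratio and
#' delta-13C-CH4, each with a 1-sigma uncertainty. The default delta
#' uncertainty (0.04 permil) reflects station variability and network scale
#' conversions of the global record.
#'
#' @param df Data frame with at least columns `year`, `ch4_ppb`,
#'   `d13c_permil`; `ch4_sigma` and `d13c_sigma` are added with defaults 0 and
#'   0.04 if absent.
#' @return The validated data frame (class `observation_record` prepended).
#' @export
observation_record <- function(df) {
  req <- c("year", "ch4_ppb", "d13c_permil")
  if (!all(req %in% names(df))) {
    stop("observations must have columns ", paste(req, collapse = ", "))
  }
  if (any(diff(df$year) != 1)) stop("observation years must be contiguous")
  if (any(!is.finite(df$ch4_ppb)) || any(df$ch4_ppb <= 0)) {
    stop("CH4 observations must be positive")
  }
  if (is.null(df$ch4_sigma)) df$ch4_sigma <- 0
  if (is.null(df$d13c_sigma)) df$d13c_sigma <- 0.04
  class(df) <- c("observation_record", class(df))
  df
}

#' Invert the box model for the OH removal-rate series
#'
#' For each year, solves the global annual mass balance for the OH rate
#' `k_oh(t)` such that the simulated total CH4 at year end equals the
#' observation exactly. Because interhemispheric exchange conserves the global
#' totals, the balance is linear in `k_oh` given the start-of-year state and
#' sources, so the solve is algebraic:
#' `k_oh = (M(t) + S_tot*dt - M_obs(t+1)) / ((m12 + alpha*m13)*dt) - k_minor`
#' with global isotopologue masses `m12`, `m13`. The state is then stepped
#' forward with that rate, so nested forward runs reproduce the CH4 record to
#' machine precision.
#'
#' @param forcing Net isotopologue source data frame as in [run_forward()].
#' @param obs An [observation_record()] covering the same years.
#' @param epsilon Sink-weighted fractionation (permil).
#' @param init An [isotope_state()] at the first observation year.
#' @param k_minor Constant minor-sink rate (1/yr).
#' @param tau_ex Interhemispheric exchange time (yr).
#' @param units,conv Unit and delta conventions.
#' @return List of class `oh_solution`: `solution` (data frame `year`, `k_oh`,
#'   `lifetime_yr`, `feasible`), `trajectory` (as [run_forward()]), and the
#'   `sink_parameters` actually used. Years with implied `k_oh <= 0` are
#'   flagged infeasible (sources too small against the observed growth) but
#'   the march continues.
#' @export
invert_oh <- function(forcing, obs, epsilon, init, k_minor = 0, tau_ex = 1,
                      units = unit_convention(), conv = delta_convention()) {
  obs <- observation_record(as.data.frame(obs))
  if (init$year != obs$year[1]) stop("init year must be the first obs year")
  n_steps <- nrow(obs) - 1L
  years <- obs$year[seq_len(n_steps)]
  if (!all(years %in% forcing$year)) stop("forcing does not cover obs years")
  alpha <- 1 + epsilon / 1000
  m_obs <- ppb_to_tg(obs$ch4_ppb, units)

  k <- numeric(n_steps)
  states <- vector("list", n_steps + 1)
  states[[1]] <- init
  for (i in seq_len(n_steps)) {
    st <- states[[i]]
    row <- forcing[match(years[i], forcing$year), ]
    m12 <- st$m12_n + st$m12_s
    m13 <- st$m13_n + st$m13_s
    s_tot <- row$s12_n + row$s12_s + row$s13_n + row$s13_s
    k[i] <- (m12 + m13 + s_tot - m_obs[i + 1]) / (m12 + alpha * m13) - k_minor
    sinks_i <- list(k_oh = k[i], k_minor = k_minor, epsilon = epsilon,
                    alpha = alpha, tau_ex = tau_ex)
    class(sinks_i) <- "sink_parameters"
    states[[i + 1]] <- step_forward(
      st, list(s12_n = row$s12_n, s12_s = row$s12_s,
               s13_n = row$s13_n, s13_s = row$s13_s), sinks_i)
  }
  feasible <- k > 0
  sinks <- list(k_oh = stats::setNames(k, years), k_minor = k_minor,
                epsilon = epsilon, alpha = alpha, tau_ex = tau_ex)
  class(sinks) <- "sink_parameters"
  structure(list(
    solution = data.frame(year = years, k_oh = k,
                          lifetime_yr = 1 / (k + k_minor),
                          feasible = feasible),
    trajectory = trajectory_frame(states, sinks, units, conv),
    sinks = sinks
  ), class = "oh_solution")
}

#' Fit the sink-weighted fractionation factor
#'
#' Finds the scalar epsilon such that the simulated global delta-13C-CH4
#' (with the OH inversion nested inside, so the CH4 record is always matched)
#' agrees with the observed delta over the onset window of the study period.
#' The residual is monotone in epsilon on the bracket (a more negative
#' epsilon leaves the simulated atmosphere isotopically heavier), so a
#' bracketed one-dimensional root find suffices.
#'
#' @inheritParams invert_oh
#' @param onset_years Number of initial observation years averaged as the
#'   matching window (default 3, damping single-year noise).
#' @param bracket Search bracket for epsilon (permil).
#' @param tol Absolute tolerance on epsilon (permil).
#' @return List: `epsilon`, the final [invert_oh()] result (`oh`), and the
#'   onset residual at the solution. Errors with the bracket residuals if no
#'   sign change exists.
#' @export
fit_epsilon <- function(forcing, obs, init, onset_years = 3,
                        bracket = c(-12, -1), tol = 1e-4,
                        k_minor = 0, tau_ex = 1,
                        units = unit_convention(), conv = delta_convention()) {
  obs <- observation_record(as.data.frame(obs))
  idx <- seq_len(min(onset_years, nrow(obs)))
  target <- mean(obs$d13c_permil[idx])
  resid <- function(eps) {
    sol <- invert_oh(forcing, obs, eps, init, k_minor, tau_ex, units, conv)
    mean(sol$trajectory$d13c_global[idx]) - target
  }
  r_lo <- resid(bracket[1]); r_hi <- resid(bracket[2])
  if (sign(r_lo) == sign(r_hi)) {
    stop(sprintf(paste0("no sign change for epsilon in [%g, %g]: residuals ",
                        "%.4g and %.4g permil"),
                 bracket[1], bracket[2], r_lo, r_hi))
  }
  root <- stats::uniroot(resid, bracket, f.lower = r_lo, f.upper = r_hi,
                         tol = tol)
  oh <- invert_oh(forcing, obs, root$root, init, k_minor, tau_ex, units, conv)
  list(epsilon = root$root, oh = oh, onset_residual = root$f.root)
}

#' Jointly invert for idealized wetland flux and OH
#'
#' For each year, solves the 2x2 linear system in (wetland flux, `k_oh`)
#' given by the global 12CH4 and 13CH4 annual balances: the wetland flux is
#' split into isotopologues at its signature, and the two unknowns are chosen
#' so the simulated total CH4 and delta-13C both match the observations at
#' year end. The march is forward year by year, which linearizes the problem.
#'
#' @param other_forcing Net isotopologue sources of everything except
#'   wetlands (data frame as in [run_forward()]).
#' @param wet_delta Wetland source signature (permil): a scalar or a vector
#'   named by year.
#' @param obs An [observation_record()] with both tracers.
#' @param epsilon Sink-weighted fractionation (permil).
#' @param init An [isotope_state()] at the first observation year.
#' @param n_frac Fraction of the solved wetland flux placed in the northern
#'   box (default 0.5).
#' @param det_tol Relative tolerance below which the 2x2 system is flagged
#'   near-singular (wetland signature equal to the post-fractionation
#'   atmospheric composition makes the two balances collinear).
#' @inheritParams invert_oh
#' @return List of class `wetland_solution`: `solution` (data frame `year`,
#'   `wet_flux`, `k_oh`, `det`, `singular`, `negative_wet`) and `trajectory`.
#'   Negative wetland fluxes are retained but flagged with a warning.
#' @export
invert_wetland <- function(other_forcing, wet_delta, obs, epsilon, init,
                           n_frac = 0.5, k_minor = 0, tau_ex = 1,
                           det_tol = 1e-10,
                           units = unit_convention(),
                           conv = delta_convention()) {
  obs <- observation_record(as.data.frame(obs))
  if (init$year != obs$year[1]) stop("init year must be the first obs year")
  n_steps <- nrow(obs) - 1L
  years <- obs$year[seq_len(n_steps)]
  if (!all(years %in% other_forcing$year)) {
    stop("forcing does not cover obs years")
  }
  alpha <- 1 + epsilon / 1000
  m_obs <- ppb_to_tg(obs$ch4_ppb, units)
  r_obs <- ratio_from_delta(obs$d13c_permil, conv)
  m13_obs <- m_obs * r_obs / (1 + r_obs)
  m12_obs <- m_obs - m13_obs
  wd <- function(y) {
    if (length(wet_delta) == 1L && is.null(names(wet_delta))) {
      return(unname(wet_delta))
    }
    v <- wet_delta[as.character(y)]
    if (is.na(v)) stop("no wetland signature for year ", y)
    unname(v)
  }

  wet <- k <- det <- numeric(n_steps)
  singular <- logical(n_steps)
  states <- vector("list", n_steps + 1)
  states[[1]] <- init
  for (i in seq_len(n_steps)) {
    st <- states[[i]]
    row <- other_forcing[match(years[i], other_forcing$year), ]
    m12 <- st$m12_n + st$m12_s
    m13 <- st$m13_n + st$m13_s
    q <- q13_fraction(wd(years[i]), conv)  # 13C share of the wetland flux
    a <- 1 - q; b <- q
    # a*W - k*m12 = rhs1 ; b*W - alpha*k*m13 = rhs2  (dt = 1)
    rhs1 <- m12_obs[i + 1] - m12 - (row$s12_n + row$s12_s) + k_minor * m12
    rhs2 <- m13_obs[i + 1] - m13 - (row$s13_n + row$s13_s) +
      alpha * k_minor * m13
    d <- b * m12 - a * alpha * m13
    det[i] <- d
    scale <- max(abs(c(m12, alpha * m13)))
    if (abs(d) < det_tol * scale) {
      # collinear balances: flag the year, march on with the wetland-free
      # CH4-only solve so later years remain defined
      singular[i] <- TRUE
      wet[i] <- 0
      k[i] <- -rhs1 / m12
    } else {
      wet[i] <- (-alpha * m13 * rhs1 + m12 * rhs2) / d
      k[i] <- (-b * rhs1 + a * rhs2) / d
    }
    src <- split_isotopologues(abs(wet[i]), wd(years[i]), conv)
    sgn <- sign(wet[i])
    sinks_i <- list(k_oh = k[i], k_minor = k_minor, epsilon = epsilon,
                    alpha = alpha, tau_ex = tau_ex)
    class(sinks_i) <- "sink_parameters"
    states[[i + 1]] <- step_forward(
      st,
      list(s12_n = row$s12_n + sgn * src$s12 * n_frac,
           s12_s = row$s12_s + sgn * src$s12 * (1 - n_frac),
           s13_n = row$s13_n + sgn * src$s13 * n_frac,
           s13_s = row$s13_s + sgn * src$s13 * (1 - n_frac)),
      sinks_i)
  }
  if (any(wet < 0, na.rm = TRUE)) {
    warning(sum(wet < 0, na.rm = TRUE),
            " year(s) with negative idealized wetland flux; retained")
  }
  sinks <- list(k_oh = stats::setNames(k, years), k_minor = k_minor,
                epsilon = epsilon, alpha = alpha, tau_ex = tau_ex)
  class(sinks) <- "sink_parameters"
  structure(list(
    solution = data.frame(year = years, wet_flux = wet, k_oh = k, det = det,
                          singular = singular,
                          negative_wet = !is.na(wet) & wet < 0),
    trajectory = trajectory_frame(states, sinks, units, conv)
  ), class = "wetland_solution")
}

#' OH anomaly and lifetime summary of an inversion
#'
#' Converts a removal-rate series into a fractional anomaly relative to the
#' mean over a reference period, and scales it to a number-density anomaly
#' against a reference OH concentration of 1e6 molec/cm3 (reported in units
#' of 1e5 molec/cm3).
#'
#' @param sol An `oh_solution` from [invert_oh()], or a data frame with
#'   columns `year` and `k_oh`.
#' @param ref_years Years defining the reference mean (default: all years).
#' @param ref_k Explicit reference rate (1/yr) overriding `ref_years`, e.g.
#'   to compare series against a common baseline.
#' @param oh_ref Reference OH number density (molec/cm3).
#' @param k_minor Constant minor-sink rate used for the lifetime column.
#' @return Data frame: `year`, `k_oh`, `anomaly_frac`, `anomaly_1e5_molec_cm3`,
#'   `lifetime_yr`.
#' @export
summarize_oh <- function(sol, ref_years = NULL, ref_k = NULL, oh_ref = 1e6,
                         k_minor = 0) {
  df <- if (inherits(sol, "oh_solution")) sol$solution else as.data.frame(sol)
  if (is.null(ref_years)) ref_years <- df$year
  ref <- if (is.null(ref_k)) mean(df$k_oh[df$year %in% ref_years]) else ref_k
  if (!is.finite(ref) || ref <= 0) stop("invalid reference period mean")
  frac <- df$k_oh / ref - 1
  data.frame(year = df$year, k_oh = df$k_oh, anomaly_frac = frac,
             anomaly_1e5_molec_cm3 = frac * oh_ref / 1e5,
             lifetime_yr = 1 / (df$k_oh + k_minor))
}
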