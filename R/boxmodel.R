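#' Two-box isotopologue state
#'
#' Masses of the two CH4 isotopologues in each hemispheric box at one point in
#' time. All masses are in Tg.
#'
#' @param year Calendar year of the state.
#' @param m12_n,m12_s Mass of 12CH4 in the northern / southern box (Tg).
#' @param m13_n,m13_s Mass of 13CH4 in the northern / southern box (Tg).
#' @return An object of class `isotope_state`.
#' @export
isotope_state <- function(year, m12_n, m12_s, m13_n, m13_s) {
  v <- c(m12_n, m12_s, m13_n, m13_s)
  if (!all(is.finite(v))) stop("non-finite mass in isotope state")
  if (any(v <= 0)) stop("isotope-state masses must be positive")
  structure(list(year = year, m12_n = m12_n, m12_s = m12_s,
                 m13_n = m13_n, m13_s = m13_s),
            class = "isotope_state")
}

#' Initialize the box model from an observed global mean
#'
#' Builds an [isotope_state()] with both hemispheric boxes at the observed
#' global mixing ratio and delta value (no interhemispheric gradient is
#' imposed at initialization).
#'
#' @param year Calendar year.
#' @param ch4_ppb Observed global mean CH4 mixing ratio (ppb).
#' @param d13c Observed global mean delta-13C-CH4 (permil).
#' @param units A [unit_convention()].
#' @param conv A [delta_convention()].
#' @return An `isotope_state`.
#' @export
state_from_observation <- function(year, ch4_ppb, d13c,
                                   units = unit_convention(),
                                   conv = delta_convention()) {
  m <- ppb_to_tg(ch4_ppb, units)
  r <- ratio_from_delta(d13c, conv)
  m13 <- m * r / (1 + r)
  m12 <- m - m13
  isotope_state(year, m12 / 2, m12 / 2, m13 / 2, m13 / 2)
}

#' Sink parameterization of the box model
#'
#' The CH4 sink is a first-order loss with an OH-driven, possibly year-varying
#' rate `k_oh` plus a constant lumped minor-sink rate `k_minor`. 13CH4 is
#' removed at `alpha * (k_oh + k_minor)` where `alpha = 1 + epsilon/1000` and
#' `epsilon` (permil, negative) is the sink-weighted kinetic fractionation.
#' Interhemispheric mixing is symmetric with exchange time `tau_ex` (yr).
#'
#' @param k_oh Either a single rate (1/yr) or a year-named numeric vector of
#'   rates; all must be positive.
#' @param k_minor Constant lumped rate for non-OH sinks (1/yr, >= 0).
#' @param epsilon Sink-weighted fractionation (permil); the implied
#'   `alpha = 1 + epsilon/1000` must lie in (0.9, 1].
#' @param tau_ex Interhemispheric exchange time (yr, > 0); default 1.
#' @return An object of class `sink_parameters`.
#' @export
sink_parameters <- function(k_oh, k_minor = 0, epsilon = -6.9, tau_ex = 1) {
  if (!all(is.finite(k_oh)) || any(k_oh <= 0)) {
    stop("k_oh must be positive and finite")
  }
  stopifnot(is.finite(k_minor), k_minor >= 0, is.finite(tau_ex), tau_ex > 0)
  alpha <- 1 + epsilon / 1000
  if (!is.finite(alpha) || alpha <= 0.9 || alpha > 1) {
    stop("epsilon implies alpha outside (0.9, 1]")
  }
  structure(list(k_oh = k_oh, k_minor = k_minor, epsilon = epsilon,
                 alpha = alpha, tau_ex = tau_ex),
            class = "sink_parameters")
}

# look up the OH rate applicable to the step starting at `year`
k_oh_at <- function(sinks, year) {
  k <- sinks$k_oh
  if (length(k) == 1L && is.null(names(k))) return(unname(k))
  nm <- names(k)
  if (is.null(nm)) stop("year-varying k_oh must be named by year")
  i <- match(as.character(year), nm)
  if (is.na(i)) stop("no k_oh value for year ", year)
  unname(k[i])
}

#' Advance the two-box isotopologue budget by one step
#'
#' Explicit difference-equation update: each box gains its net source, loses
#' mass at the first-order sink rate (with kinetic fractionation applied to
#' 13CH4), and exchanges mass symmetrically with the other box on timescale
#' `tau_ex`. Sources are net fluxes for the step (any soil uptake already
#' subtracted).
#'
#' @param state An [isotope_state()] at time t.
#' @param src List with components `s12_n`, `s12_s`, `s13_n`, `s13_s`: net
#'   isotopologue source fluxes (Tg/yr) applying over the step.
#' @param sinks A [sink_parameters()]; if `k_oh` is year-named the rate for
#'   `state$year` is used.
#' @param dt Step length in years (> 0); the model is designed for annual
#'   steps.
#' @return The `isotope_state` at t + dt.
#' @export
step_forward <- function(state, src, sinks, dt = 1) {
  stopifnot(inherits(state, "isotope_state"), dt > 0)
  s <- c(src$s12_n, src$s12_s, src$s13_n, src$s13_s)
  if (length(s) != 4L || !all(is.finite(s))) {
    stop("source fluxes must be four finite numbers")
  }
  k12 <- k_oh_at(sinks, state$year) + sinks$k_minor
  k13 <- sinks$alpha * k12
  ex <- 1 / (2 * sinks$tau_ex)

  m12_n <- state$m12_n +
    (src$s12_n - k12 * state$m12_n - ex * state$m12_n + ex * state$m12_s) * dt
  m12_s <- state$m12_s +
    (src$s12_s - k12 * state$m12_s - ex * state$m12_s + ex * state$m12_n) * dt
  m13_n <- state$m13_n +
    (src$s13_n - k13 * state$m13_n - ex * state$m13_n + ex * state$m13_s) * dt
  m13_s <- state$m13_s +
    (src$s13_s - k13 * state$m13_s - ex * state$m13_s + ex * state$m13_n) * dt

  if (any(c(m12_n, m12_s, m13_n, m13_s) <= 0)) {
    stop("step produced a non-positive mass: unphysical forcing or rate")
  }
  isotope_state(state$year + dt, m12_n, m12_s, m13_n, m13_s)
}

#' Delta values of a box-model state
#'
#' The global delta is computed from the summed hemispheric isotopologue
#' masses, not by averaging hemispheric delta values.
#'
#' @param state An [isotope_state()].
#' @param conv A [delta_convention()].
#' @return List with elements `global`, `nh`, `sh` (permil).
#' @export
to_delta <- function(state, conv = delta_convention()) {
  stopifnot(inherits(state, "isotope_state"))
  list(
    global = combine_isotopologues(state$m12_n + state$m12_s,
                                   state$m13_n + state$m13_s, conv),
    nh = combine_isotopologues(state$m12_n, state$m13_n, conv),
    sh = combine_isotopologues(state$m12_s, state$m13_s, conv)
  )
}

#' Run the box model forward over a span of years
#'
#' Integrates the two-box isotopologue budget with annual explicit steps under
#' prescribed net isotopologue sources, and reports mixing ratios and delta
#' values along the trajectory. Deterministic given its inputs.
#'
#' @param forcing Data frame with columns `year`, `s12_n`, `s12_s`, `s13_n`,
#'   `s13_s` (Tg/yr); must contain one row for every step year, i.e. every
#'   year from `init$year` to the last simulated year minus one.
#' @param sinks A [sink_parameters()].
#' @param init An [isotope_state()] at the first year.
#' @param n_years Number of annual steps to take; defaults to `nrow(forcing)`
#'   (the trajectory then has `n_years + 1` rows).
#' @param units A [unit_convention()] for reporting ppb.
#' @param conv A [delta_convention()].
#' @return Data frame with one row per year: `year`, `ch4_ppb_global`,
#'   `ch4_ppb_nh`, `ch4_ppb_sh`, `d13c_global`, `d13c_nh`, `d13c_sh`,
#'   `lifetime_yr` (1 / total removal rate applying to the step starting that
#'   year; `NA` for the final year), and the four isotopologue masses.
#' @export
run_forward <- function(forcing, sinks, init, n_years = nrow(forcing),
                        units = unit_convention(),
                        conv = delta_convention()) {
  req <- c("year", "s12_n", "s12_s", "s13_n", "s13_s")
  if (!all(req %in% names(forcing))) {
    stop("forcing must have columns ", paste(req, collapse = ", "))
  }
  years_needed <- init$year + seq_len(n_years) - 1
  if (!all(years_needed %in% forcing$year)) {
    stop("forcing does not cover all step years ",
         years_needed[1], "-", years_needed[n_years])
  }
  states <- vector("list", n_years + 1)
  states[[1]] <- init
  for (i in seq_len(n_years)) {
    row <- forcing[match(years_needed[i], forcing$year), ]
    states[[i + 1]] <- step_forward(
      states[[i]],
      list(s12_n = row$s12_n, s12_s = row$s12_s,
           s13_n = row$s13_n, s13_s = row$s13_s),
      sinks)
  }
  trajectory_frame(states, sinks, units, conv)
}

trajectory_frame <- function(states, sinks, units, conv) {
  n <- length(states)
  g <- function(f) vapply(states, f, numeric(1))
  m12_n <- g(function(s) s$m12_n); m12_s <- g(function(s) s$m12_s)
  m13_n <- g(function(s) s$m13_n); m13_s <- g(function(s) s$m13_s)
  years <- g(function(s) s$year)
  half <- units$tg_per_ppb / 2
  k12 <- vapply(years, function(y) {
    tryCatch(k_oh_at(sinks, y) + sinks$k_minor, error = function(e) NA_real_)
  }, numeric(1))
  k12[n] <- NA_real_  # no step starts at the final year
  data.frame(
    year = years,
    ch4_ppb_global = tg_to_ppb(m12_n + m12_s + m13_n + m13_s, units),
    ch4_ppb_nh = (m12_n + m13_n) / half,
    ch4_ppb_sh = (m12_s + m13_s) / half,
    d13c_global = combine_isotopologues(m12_n + m12_s, m13_n + m13_s, conv),
    d13c_nh = combine_isotopologues(m12_n, m13_n, conv),
    d13c_sh = combine_isotopologues(m12_s, m13_s, conv),
    lifetime_yr = 1 / k12,
    m12_n = m12_n, m12_s = m12_s, m13_n = m13_n, m13_s = m13_s
  )
}
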