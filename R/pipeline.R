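#' Monte Carlo draws of the emission-weighted sector signatures
#'
#' For every sector, draws `n_draws` realizations of its emission-weighted
#' hemispheric signature: mapped sectors get cell-wise Gaussian map
#' perturbations (via [sample_signature_maps()]) weighted by the sector's
#' flux pattern, scalar sectors get Gaussian scalar draws. Draw 0 (the
#' unperturbed signature) is prepended when `include_unperturbed` is TRUE.
#' Each sector uses its own counter-based substream of the master seed, so
#' draws are reproducible and order-independent.
#'
#' @param world A `ch4_world` from [generate_world()].
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Master seed for the draws.
#' @param include_unperturbed Prepend the unperturbed signature as draw 0.
#' @return A 3-d array `[sector, hemisphere (N,S), draw]` of signatures
#'   (permil), with a `"draw_ids"` attribute (0 marks the unperturbed draw).
#' @export
draw_sector_signatures <- function(world, n_draws = 1000, seed = 1,
                                   include_unperturbed = TRUE) {
  stopifnot(inherits(world, "ch4_world"), n_draws >= 0)
  sectors <- world$sectors
  nm <- names(sectors)
  lat <- world$grid$lat
  out <- array(NA_real_, dim = c(length(nm), 2, n_draws),
               dimnames = list(nm, c("N", "S"), NULL))
  for (i in seq_along(nm)) {
    s <- sectors[[i]]
    sig <- world$signatures[[i]]
    if (n_draws > 0 && inherits(sig, "gridded_field")) {
      maps <- sample_signature_maps(sig, n_draws, seed, stream = i)
      w <- s$pattern$values
      dim(maps) <- c(length(w), n_draws)  # cells (column-major) x draws
      for (h in 1:2) {
        keep <- if (h == 1) lat >= 0 else lat < 0
        cellmask <- rep(keep, times = ncol(w))
        tot <- sum(w[cellmask])
        if (tot <= 0) {
          # sector absent from this hemisphere: carry the mean (zero weight)
          out[i, h, ] <- s$def$sig_mean
        } else {
          out[i, h, ] <- as.numeric(crossprod(
            w[cellmask] / tot, maps[cellmask, , drop = FALSE]))
        }
      }
    } else if (n_draws > 0) {
      d <- scalar_signature(sig$mean, sig$sigma, n_draws, seed, stream = i)
      out[i, 1, ] <- d
      out[i, 2, ] <- d
    }
  }
  if (include_unperturbed) {
    base <- array(rep(vapply(sectors, function(s) s$def$sig_mean,
                             numeric(1)), 2),
                  dim = c(length(nm), 2, 1), dimnames = dimnames(out)[1:3])
    out <- array(c(base, out), dim = dim(out) + c(0, 0, 1),
                 dimnames = list(nm, c("N", "S"), NULL))
    attr(out, "draw_ids") <- 0:n_draws
  } else {
    attr(out, "draw_ids") <- seq_len(n_draws)
  }
  out
}

# per-candidate isotopologue source matrices [year x draw] per hemisphere:
# S13 = sum_s F_s,h(y) * q13(delta_s[draw,h]), S12 the complement
candidate_source_matrices <- function(composition, sectors, sig_draws, conv) {
  draw_n <- dim(sig_draws)[3]
  out <- list()
  for (cat in names(composition)) {
    out[[cat]] <- list()
    for (label in names(composition[[cat]])) {
      comp <- composition[[cat]][[label]]
      ny <- length(comp[[1]])
      S12n <- S12s <- S13n <- S13s <- matrix(0, ny, draw_n)
      for (sec in names(comp)) {
        nfr <- sectors[[sec]]$n_frac
        fn <- comp[[sec]] * nfr
        fs <- comp[[sec]] * (1 - nfr)
        qn <- q13_fraction(sig_draws[sec, "N", ], conv)
        qs <- q13_fraction(sig_draws[sec, "S", ], conv)
        S13n <- S13n + outer(fn, qn)
        S13s <- S13s + outer(fs, qs)
        S12n <- S12n + outer(fn, 1 - qn)
        S12s <- S12s + outer(fs, 1 - qs)
      }
      out[[cat]][[label]] <- list(s12_n = S12n, s12_s = S12s,
                                  s13_n = S13n, s13_s = S13s)
    }
  }
  out
}

# vectorized march of the inverse-OH forward model over all runs at once;
# columns are runs. Returns onset-window mean deltas, or the full delta and
# k_oh matrices.
ensemble_march <- function(S12n, S12s, S13n, S13s, alpha, m_obs_tg, init,
                           tau_ex = 1, k_minor = 0,
                           conv = delta_convention(),
                           collect = c("onset", "full"), onset_idx = 1:3) {
  collect <- match.arg(collect)
  n_yr <- length(m_obs_tg)
  n_run <- length(alpha)
  m12n <- rep(init$m12_n, n_run); m12s <- rep(init$m12_s, n_run)
  m13n <- rep(init$m13_n, n_run); m13s <- rep(init$m13_s, n_run)
  ex <- 1 / (2 * tau_ex)
  d0 <- delta_from_ratio((init$m13_n + init$m13_s) /
                           (init$m12_n + init$m12_s), conv)
  if (collect == "full") {
    delta <- matrix(NA_real_, n_yr, n_run)
    delta[1, ] <- d0
    kmat <- matrix(NA_real_, n_yr - 1, n_run)
  } else {
    acc <- if (1L %in% onset_idx) rep(d0, n_run) else numeric(n_run)
  }
  for (t in seq_len(n_yr - 1)) {
    m12 <- m12n + m12s
    m13 <- m13n + m13s
    s_tot <- S12n[t, ] + S12s[t, ] + S13n[t, ] + S13s[t, ]
    k <- (m12 + m13 + s_tot - m_obs_tg[t + 1]) / (m12 + alpha * m13) - k_minor
    kk <- k + k_minor
    kk13 <- alpha * kk
    n12 <- m12n + S12n[t, ] - kk * m12n - ex * (m12n - m12s)
    s12 <- m12s + S12s[t, ] - kk * m12s - ex * (m12s - m12n)
    n13 <- m13n + S13n[t, ] - kk13 * m13n - ex * (m13n - m13s)
    s13 <- m13s + S13s[t, ] - kk13 * m13s - ex * (m13s - m13n)
    m12n <- n12; m12s <- s12; m13n <- n13; m13s <- s13
    del <- delta_from_ratio((m13n + m13s) / (m12n + m12s), conv)
    if (collect == "full") {
      delta[t + 1, ] <- del
      kmat[t, ] <- k
    } else if ((t + 1L) %in% onset_idx) {
      acc <- acc + del
    }
  }
  if (collect == "full") list(delta = delta, k_oh = kmat)
  else acc / length(onset_idx)
}

#' Run the full scenario x Monte Carlo ensemble
#'
#' For every (scenario, signature draw) pair: fits the sink fractionation
#' epsilon so the simulated delta-13C matches the observed onset window
#' (vectorized bisection, with the per-year OH inversion nested so the CH4
#' record is reproduced exactly), runs the forward model, and scores the
#' simulated global delta-13C against the observations. Runs whose epsilon
#' bracket shows no sign change or whose OH solution has non-positive years
#' are flagged infeasible and excluded from selection.
#'
#' @param world A `ch4_world` from [generate_world()].
#' @param cat_res Result of [make_scenario_catalogue()] (catalogue +
#'   per-candidate sector composition).
#' @param n_draws Monte Carlo draws per scenario (default 1000).
#' @param seed Master seed for the signature draws.
#' @param percentile Selection percentile for the most likely subset.
#' @param include_unperturbed Include the unperturbed signature as draw 0.
#' @param onset_years Years averaged for the epsilon match (default 3).
#' @param eps_bracket Bisection bracket for epsilon (permil).
#' @param bisect_iter Bisection iterations (30 gives ~1e-8 permil).
#' @param score_years Years scored against observations (default: all
#'   observation years).
#' @param k_minor,tau_ex Minor-sink rate and exchange time.
#' @param units,conv Conventions.
#' @return List of class `ch4_ensemble`: `scores` (one row per run with MSD,
#'   RMSE, correlation, Taylor components, epsilon, mean source delta, mean
#'   lifetime, feasibility and selection flags), `scenarios` (the enumerated
#'   factorial), `delta_sim` (years x runs matrix), `k_oh` (years-1 x runs),
#'   `draws` (the signature-draw array), `candidate_sources`, `obs`, and
#'   bookkeeping (`seed`, `n_draws`, `percentile`).
#' @export
run_ensemble <- function(world, cat_res = make_scenario_catalogue(world),
                         n_draws = 1000, seed = 1, percentile = 1,
                         include_unperturbed = FALSE, onset_years = 3,
                         eps_bracket = c(-12, -1), bisect_iter = 30,
                         score_years = NULL, k_minor = 0, tau_ex = 1,
                         units = unit_convention(),
                         conv = delta_convention()) {
  stopifnot(inherits(world, "ch4_world"))
  catalogue <- cat_res$catalogue
  composition <- cat_res$composition
  obs <- world$obs
  years <- obs$year
  n_yr <- length(years)

  sig_draws <- draw_sector_signatures(world, n_draws, seed,
                                      include_unperturbed)
  draw_ids <- attr(sig_draws, "draw_ids")
  n_d <- length(draw_ids)
  cand <- candidate_source_matrices(composition, world$sectors, sig_draws,
                                    conv)

  # constant soil subtraction (per year, same for every draw)
  soil <- catalogue$soil
  soil_n <- split_isotopologues(soil$flux_n, world$cfg$soil_delta, conv)
  soil_s <- split_isotopologues(soil$flux_s, world$cfg$soil_delta, conv)

  scen <- enumerate_scenarios(catalogue)
  n_scen <- nrow(scen)
  n_run <- n_scen * n_d

  S12n <- matrix(0, n_yr, n_run); S12s <- matrix(0, n_yr, n_run)
  S13n <- matrix(0, n_yr, n_run); S13s <- matrix(0, n_yr, n_run)
  for (s in seq_len(n_scen)) {
    cols <- (s - 1L) * n_d + seq_len(n_d)
    pick <- list(IFF = scen$iff_label[s], AGW = scen$agw_label[s],
                 WET = scen$wet_label[s], BB = scen$bb_label[s],
                 GEO = scen$geo_label[s], OTH = "shared")
    a12n <- -soil_n$s12; a12s <- -soil_s$s12
    a13n <- -soil_n$s13; a13s <- -soil_s$s13
    a12n <- matrix(a12n, n_yr, n_d); a12s <- matrix(a12s, n_yr, n_d)
    a13n <- matrix(a13n, n_yr, n_d); a13s <- matrix(a13s, n_yr, n_d)
    for (cat in names(pick)) {
      cm <- cand[[cat]][[pick[[cat]]]]
      a12n <- a12n + cm$s12_n; a12s <- a12s + cm$s12_s
      a13n <- a13n + cm$s13_n; a13s <- a13s + cm$s13_s
    }
    S12n[, cols] <- a12n; S12s[, cols] <- a12s
    S13n[, cols] <- a13n; S13s[, cols] <- a13s
  }

  init <- state_from_observation(years[1], obs$ch4_ppb[1],
                                 obs$d13c_permil[1], units, conv)
  m_obs <- ppb_to_tg(obs$ch4_ppb, units)
  onset_idx <- seq_len(min(onset_years, n_yr))
  target <- mean(obs$d13c_permil[onset_idx])

  resid <- function(eps) {
    ensemble_march(S12n, S12s, S13n, S13s, 1 + eps / 1000, m_obs, init,
                   tau_ex, k_minor, conv, "onset", onset_idx) - target
  }
  lo <- rep(eps_bracket[1], n_run)
  hi <- rep(eps_bracket[2], n_run)
  r_lo <- resid(lo)
  r_hi <- resid(hi)
  bracket_ok <- is.finite(r_lo) & is.finite(r_hi) & (sign(r_lo) != sign(r_hi))
  for (it in seq_len(bisect_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- resid(mid)
    move_lo <- sign(r_mid) == sign(r_lo)
    lo <- ifelse(move_lo, mid, lo)
    r_lo <- ifelse(move_lo, r_mid, r_lo)
    hi <- ifelse(move_lo, hi, mid)
  }
  epsilon <- (lo + hi) / 2

  fin <- ensemble_march(S12n, S12s, S13n, S13s, 1 + epsilon / 1000, m_obs,
                        init, tau_ex, k_minor, conv, "full")
  oh_ok <- colSums(fin$k_oh <= 0 | !is.finite(fin$k_oh)) == 0
  feasible <- bracket_ok & oh_ok

  sc_idx <- if (is.null(score_years)) seq_len(n_yr) else match(score_years, years)
  sim <- fin$delta[sc_idx, , drop = FALSE]
  ob <- obs$d13c_permil[sc_idx]
  n_sc <- length(sc_idx)
  d <- sim - ob
  msd <- colMeans(d^2)
  cs <- sim - matrix(colMeans(sim), n_sc, ncol(sim), byrow = TRUE)
  co <- ob - mean(ob)
  sd_sim <- sqrt(colMeans(cs^2))
  sd_obs <- sqrt(mean(co^2))
  r <- colMeans(cs * co) / (sd_sim * sd_obs)
  crmse <- sqrt(colMeans((cs - co)^2))

  src_delta <- delta_from_ratio((S13n + S13s) / (S12n + S12s), conv)
  mean_src_delta <- colMeans(src_delta)
  mean_lifetime <- colMeans(1 / (fin$k_oh + k_minor))

  scores <- data.frame(
    run_id = paste0(rep(scen$scenario_id, each = n_d), "_d",
                    rep(draw_ids, n_scen)),
    scenario_id = rep(scen$scenario_id, each = n_d),
    scenario_index = rep(seq_len(n_scen), each = n_d),
    draw = rep(draw_ids, n_scen),
    epsilon = epsilon, feasible = feasible,
    rmse = sqrt(msd), msd = msd, r = r, sd_sim = sd_sim, sd_obs = sd_obs,
    crmse = crmse, mean_source_delta = mean_src_delta,
    mean_lifetime_yr = mean_lifetime,
    stringsAsFactors = FALSE)

  scores$selected <- FALSE
  feas <- which(scores$feasible)
  if (length(feas) > 0) {
    sel <- select_most_likely(scores[feas, c("run_id", "msd")], percentile)
    scores$selected[feas] <- sel$selected
  }

  structure(list(scores = scores, scenarios = scen, delta_sim = fin$delta,
                 k_oh = fin$k_oh, draws = sig_draws,
                 candidate_sources = cand, catalogue = catalogue,
                 composition = composition, obs = obs, seed = seed,
                 n_draws = n_draws, percentile = percentile,
                 score_years = years[sc_idx]),
            class = "ch4_ensemble")
}

#' Period-based source attribution over the most likely subset
#'
#' For every selected run, computes each category's mean-flux change in each
#' period relative to the plateau, the percent shares of the headline
#' categories (IFF, AGW, WET) in the total change, and the change in each
#' category's share of the annual source 13CH4 mass. Ensemble means and
#' 1-sigma are taken across the selected runs.
#'
#' @param ens A `ch4_ensemble` from [run_ensemble()].
#' @param periods A [period_set()]-style data frame.
#' @param share_categories Categories forming the share denominator.
#' @return List: `deltas` (per category x period ensemble mean and sigma of
#'   the flux change, Tg/yr), `shares` (per period, [contribution_shares()]
#'   summaries), `c13_change` (per category x period mean and sigma of the
#'   13CH4-mass share change, percentage points), `n_runs`.
#' @export
attribute_ensemble <- function(ens, periods = period_set(),
                               share_categories = c("IFF", "AGW", "WET")) {
  stopifnot(inherits(ens, "ch4_ensemble"))
  sel <- ens$scores[ens$scores$selected, ]
  if (nrow(sel) == 0L) stop("no selected runs to attribute")
  years <- ens$catalogue$years
  cats <- ch4_categories()
  scen <- ens$scenarios

  # per-scenario global category series and period deltas
  label_cols <- c(IFF = "iff_label", AGW = "agw_label", WET = "wet_label",
                  BB = "bb_label", GEO = "geo_label")
  scen_delta <- list()
  for (si in unique(sel$scenario_index)) {
    dl <- matrix(NA_real_, nrow(periods), length(cats),
                 dimnames = list(periods$period, cats))
    for (cat in cats) {
      ser <- if (cat == "OTH") ens$catalogue$oth else {
        ens$catalogue$candidates[[cat]][[scen[[label_cols[cat]]][si]]]
      }
      glob <- ser$flux_n + ser$flux_s
      dl[, cat] <- period_delta(glob, periods, years = years)$delta
    }
    scen_delta[[as.character(si)]] <- dl
  }

  # per-run delta matrices and shares, per period
  n_sel <- nrow(sel)
  deltas_by_period <- lapply(stats::setNames(periods$period, periods$period),
    function(p) {
      m <- t(vapply(seq_len(n_sel), function(i) {
        scen_delta[[as.character(sel$scenario_index[i])]][p, ]
      }, numeric(length(cats))))
      colnames(m) <- cats
      m
    })
  shares <- lapply(deltas_by_period, function(m) {
    contribution_shares(m[, share_categories, drop = FALSE])
  })
  delta_summary <- do.call(rbind, lapply(periods$period, function(p) {
    m <- deltas_by_period[[p]]
    data.frame(period = p, category = cats,
               delta_mean = colMeans(m), delta_sigma = apply(m, 2, stats::sd),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  # 13CH4-mass share change per selected run (depends on scenario and draw)
  draw_pos <- match(sel$draw, attr(ens$draws, "draw_ids"))
  c13 <- array(NA_real_, dim = c(n_sel, length(cats), nrow(periods)),
               dimnames = list(NULL, cats, periods$period))
  for (i in seq_len(n_sel)) {
    si <- sel$scenario_index[i]
    s13 <- vapply(cats, function(cat) {
      lab <- if (cat == "OTH") "shared" else scen[[label_cols[cat]]][si]
      cm <- ens$candidate_sources[[cat]][[lab]]
      cm$s13_n[, draw_pos[i]] + cm$s13_s[, draw_pos[i]]
    }, numeric(length(years)))
    share <- 100 * s13 / rowSums(s13)
    for (p in seq_len(nrow(periods))) {
      yr <- years >= periods$start[p] & years <= periods$end[p]
      c13[i, , p] <- colMeans(share[yr, , drop = FALSE])
    }
  }
  plateau <- c13[, , "plateau", drop = FALSE]
  c13_change <- do.call(rbind, lapply(periods$period, function(p) {
    ch <- c13[, , p] - plateau[, , 1]
    data.frame(period = p, category = cats, change_mean = colMeans(ch),
               change_sigma = apply(ch, 2, stats::sd),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  list(deltas = delta_summary, shares = shares, c13_change = c13_change,
       n_runs = n_sel)
}
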