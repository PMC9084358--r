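#' Configuration of the synthetic truth
#'
#' Defines everything needed to generate a self-consistent synthetic world:
#' per-sector base fluxes, trends, step changes and interannual variability;
#' per-sector signature means and cell-level 1-sigma; the true sink
#' parameters; observation noise; and the master seed. Defaults describe a
#' late-20th-century methane budget: ~550 Tg/yr of sources, an agriculture
#' and fossil-fuel driven rise, a +7.3 Tg/yr tropical-wetland step in 2007, a
#' declining biomass-burning source, and signature means for the mapped
#' sources (coal -45.8, oil & gas -43.8, livestock -65.4, wetlands -59.6
#' overall with tropical -56.7 vs boreal -67.8, biomass burning -23.9 permil).
#'
#' @param years Observation years (contiguous).
#' @param nlat,nlon Grid resolution (cell centers; default 18 x 36, i.e. 10
#'   degrees).
#' @param sectors Data frame of sector definitions; see
#'   [default_truth_sectors()].
#' @param epsilon_true True sink-weighted fractionation (permil).
#' @param k_oh_base Baseline OH removal rate (1/yr).
#' @param k_oh_amp,k_oh_period Amplitude (fractional) and period (yr) of the
#'   sinusoidal OH anomaly.
#' @param soil_delta Effective signature assigned to soil uptake (permil).
#' @param ch4_noise_sigma Gaussian noise added to the pseudo-observed CH4
#'   record (ppb).
#' @param d13c_noise_sigma Gaussian noise added to the pseudo-observed delta
#'   record (permil); the reported observational uncertainty stays 0.04.
#' @param init_ch4_ppb,init_d13c Initial-year global observations.
#' @param seed Master integer seed; fully determines the world.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(years = 1993:2017, nlat = 18, nlon = 36,
                         sectors = default_truth_sectors(),
                         epsilon_true = -6.9,
                         k_oh_base = 0.109, k_oh_amp = 0.01,
                         k_oh_period = 11,
                         soil_delta = -47.3,
                         ch4_noise_sigma = 0, d13c_noise_sigma = 0,
                         init_ch4_ppb = 1736, init_d13c = -47.3,
                         seed = 20170101) {
  stopifnot(all(diff(years) == 1), length(years) >= 5,
            nlat >= 4, nlon >= 4, k_oh_base > 0)
  structure(list(years = years, nlat = nlat, nlon = nlon, sectors = sectors,
                 epsilon_true = epsilon_true, k_oh_base = k_oh_base,
                 k_oh_amp = k_oh_amp, k_oh_period = k_oh_period,
                 soil_delta = soil_delta,
                 ch4_noise_sigma = ch4_noise_sigma,
                 d13c_noise_sigma = d13c_noise_sigma,
                 init_ch4_ppb = init_ch4_ppb, init_d13c = init_d13c,
                 seed = as.integer(seed)),
            class = "truth_config")
}

#' Default sector definitions of the synthetic truth
#'
#' One row per emitting sector: category, base flux (Tg/yr at the first
#' year), linear trend (Tg/yr per yr) applying from `trend_start`, an
#' optional step change, interannual variability (1-sigma, Tg/yr), the
#' latitudinal placement pattern, the signature mean and cell 1-sigma
#' (permil), and whether the sector carries a gridded signature map or a
#' scalar value. `soil_uptake` is the (sink) magnitude subtracted in the net
#' source.
#'
#' @return Data frame of sector definitions.
#' @export
default_truth_sectors <- function() {
  s <- function(sector, category, base, trend, trend_start, step_year, step,
                iav, pattern, sig_mean, sig_sigma, gridded) {
    data.frame(sector = sector, category = category, base = base,
               trend = trend, trend_start = trend_start,
               step_year = step_year, step = step, iav = iav,
               pattern = pattern, sig_mean = sig_mean, sig_sigma = sig_sigma,
               gridded = gridded, stringsAsFactors = FALSE)
  }
  rbind(
    s("coal", "IFF", 40, 0.9, 2003, NA, 0, 0.5, "midlat_n", -45.8, 3.0, TRUE),
    s("oil", "IFF", 30, 0.25, 1993, NA, 0, 0.3, "industrial_n", -43.8, 2.0, TRUE),
    s("gas", "IFF", 35, 0.35, 1993, NA, 0, 0.3, "industrial_n", -43.8, 2.0, TRUE),
    s("enteric", "AGW", 90, 1.4, 1993, NA, 0, 0.8, "livestock", -65.4, 2.0, TRUE),
    s("manure", "AGW", 25, 0.3, 1993, NA, 0, 0.3, "livestock", -65.4, 2.0, TRUE),
    s("rice", "AGW", 30, 0.0, 1993, NA, 0, 0.5, "tropics_n", -62.2, 1.5, FALSE),
    s("landfill", "AGW", 40, 0.4, 1993, NA, 0, 0.4, "midlat_n", -55.4, 2.0, FALSE),
    s("waste", "AGW", 25, 0.2, 1993, NA, 0, 0.3, "midlat_n", -55.4, 2.0, FALSE),
    s("wetland_tropical", "WET", 115, 0.0, 1993, 2007, 7.3, 4.0, "tropics",
      -56.7, 2.0, TRUE),
    s("wetland_boreal", "WET", 50, 0.0, 1993, NA, 0, 2.0, "boreal",
      -67.8, 2.0, TRUE),
    s("biomass_burning", "BB", 22, -0.2, 1993, NA, 0, 2.5, "tropics",
      -23.9, 1.5, TRUE),
    s("geological", "GEO", 15, 0.0, 1993, NA, 0, 0.0, "industrial_n",
      -49.0, 3.0, FALSE),
    s("termites", "OTH", 20, 0.0, 1993, NA, 0, 0.0, "tropics", -63.0, 2.0, FALSE),
    s("freshwater", "OTH", 15, 0.0, 1993, NA, 0, 0.0, "boreal", -61.0, 2.0, FALSE),
    s("wild_animals", "OTH", 5, 0.0, 1993, NA, 0, 0.0, "livestock", -62.0,
      2.0, FALSE),
    s("soil_uptake", "SOIL", 30, 0.0, 1993, NA, 0, 0.0, "midlat_n", -47.3,
      0.0, FALSE)
  )
}

# stylized latitudinal placement masks; value per cell proportional to
# cos(lat) inside the band (area weighting), normalized to sum 1
pattern_weights <- function(pattern, lat, nlon) {
  band <- switch(pattern,
    midlat_n = lat >= 30 & lat <= 55,
    industrial_n = lat >= 20 & lat <= 60,
    livestock = lat >= -35 & lat <= 55,
    tropics = lat >= -20 & lat <= 20,
    tropics_n = lat >= 5 & lat <= 35,
    boreal = lat >= 50 & lat <= 70,
    stop("unknown pattern ", pattern))
  if (!any(band)) stop("pattern ", pattern, " empty on this grid")
  w <- matrix(0, length(lat), nlon)
  w[band, ] <- cos(lat[band] * pi / 180)
  w / sum(w)
}

grid_centers <- function(nlat, nlon) {
  list(lat = seq(-90 + 90 / nlat, 90 - 90 / nlat, length.out = nlat),
       lon = seq(-180 + 180 / nlon, 180 - 180 / nlon, length.out = nlon))
}

# annual total series of one sector row (deterministic given cfg seed);
# idx gives the sector its own noise substream
sector_total_series <- function(row, years, seed, idx) {
  v <- row$base + row$trend * pmax(0, years - max(years[1], row$trend_start))
  if (!is.na(row$step_year)) v <- v + ifelse(years >= row$step_year, row$step, 0)
  if (row$iav > 0) {
    set.seed(substream_seed(seed, 7L, idx))
    v <- v + stats::rnorm(length(years), 0, row$iav)
  }
  if (any(v < 0)) stop("sector ", row$sector, " produced a negative flux")
  v
}

#' Generate the full synthetic world
#'
#' Builds gridded sector emissions (a fixed stylized spatial pattern scaled
#' by an annual total series), signature maps with Gaussian cell-level
#' uncertainty for the mapped sectors and scalar signatures for the rest,
#' the true sink parameters, and pseudo-observations produced by running the
#' forward model on the truth (plus optional observation noise). A truth
#' ledger records everything needed for recovery tests. Byte-identical for a
#' given configuration.
#'
#' @param cfg A [truth_config()].
#' @param units,conv Unit and delta conventions.
#' @return An object of class `ch4_world`: list with `grid`, `sectors` (per
#'   sector: definition row, pattern field, annual totals, hemispheric
#'   split), `signatures` (per sector: gridded field with sigma, or scalar
#'   mean/sigma), `obs` (an [observation_record()]), and `truth` (k_oh
#'   series, epsilon, forcing, per-category series, noise-free trajectory).
#' @export
generate_world <- function(cfg = truth_config(), units = unit_convention(),
                           conv = delta_convention()) {
  stopifnot(inherits(cfg, "truth_config"))
  g <- grid_centers(cfg$nlat, cfg$nlon)
  years <- cfg$years
  n_hemi_frac <- function(w) min(max(sum(w[g$lat >= 0, ]), 0), 1)

  sectors <- list()
  signatures <- list()
  for (i in seq_len(nrow(cfg$sectors))) {
    row <- cfg$sectors[i, ]
    w <- pattern_weights(row$pattern, g$lat, cfg$nlon)
    totals <- sector_total_series(row, years, cfg$seed, i)
    sectors[[row$sector]] <- list(
      def = row,
      pattern = gridded_field(g$lat, g$lon, w),
      totals = data.frame(year = years, total = totals),
      n_frac = n_hemi_frac(w)
    )
    signatures[[row$sector]] <- if (row$gridded) {
      gridded_field(g$lat, g$lon,
                    matrix(row$sig_mean, cfg$nlat, cfg$nlon),
                    matrix(row$sig_sigma, cfg$nlat, cfg$nlon))
    } else {
      list(mean = row$sig_mean, sigma = row$sig_sigma)
    }
  }

  # unperturbed emission-weighted sector signature equals the map mean here
  # (constant mean maps); hemispheric values likewise
  sig0 <- stats::setNames(cfg$sectors$sig_mean, cfg$sectors$sector)

  # truth forcing: per-hemisphere isotopologue sources summed over sectors,
  # soil uptake subtracted at its effective signature
  forcing <- truth_forcing(sectors, sig0, cfg$soil_delta, years, conv)

  k_oh <- cfg$k_oh_base *
    (1 + cfg$k_oh_amp * sin(2 * pi * (years - years[1]) / cfg$k_oh_period))
  sinks <- sink_parameters(stats::setNames(k_oh, years),
                           epsilon = cfg$epsilon_true)
  init <- state_from_observation(years[1], cfg$init_ch4_ppb, cfg$init_d13c,
                                 units, conv)
  traj <- run_forward(forcing, sinks, init, n_years = length(years) - 1,
                      units = units, conv = conv)

  set.seed(substream_seed(cfg$seed, 11L, 1L))
  ch4_obs <- traj$ch4_ppb_global +
    stats::rnorm(length(years), 0, cfg$ch4_noise_sigma)
  set.seed(substream_seed(cfg$seed, 11L, 2L))
  d13c_obs <- traj$d13c_global +
    stats::rnorm(length(years), 0, cfg$d13c_noise_sigma)
  obs <- observation_record(data.frame(
    year = years, ch4_ppb = ch4_obs, ch4_sigma = cfg$ch4_noise_sigma,
    d13c_permil = d13c_obs, d13c_sigma = 0.04))

  category_series <- truth_category_series(sectors, years)
  structure(list(
    cfg = cfg, grid = g, sectors = sectors, signatures = signatures,
    obs = obs,
    truth = list(k_oh = stats::setNames(k_oh, years),
                 epsilon = cfg$epsilon_true, forcing = forcing,
                 sector_sig = sig0, category_series = category_series,
                 trajectory = traj, init = init)
  ), class = "ch4_world")
}

# sum sector fluxes into per-category hemispheric series
truth_category_series <- function(sectors, years) {
  out <- list()
  for (s in sectors) {
    cat <- s$def$category
    fn <- s$totals$total * s$n_frac
    fs <- s$totals$total * (1 - s$n_frac)
    if (is.null(out[[cat]])) {
      out[[cat]] <- data.frame(year = years, flux_n = fn, flux_s = fs)
    } else {
      out[[cat]]$flux_n <- out[[cat]]$flux_n + fn
      out[[cat]]$flux_s <- out[[cat]]$flux_s + fs
    }
  }
  out
}

# net isotopologue forcing from sector lists + sector signatures
truth_forcing <- function(sectors, sig, soil_delta, years, conv) {
  z <- numeric(length(years))
  f <- data.frame(year = years, s12_n = z, s12_s = z, s13_n = z, s13_s = z)
  for (s in sectors) {
    nm <- s$def$sector
    sgn <- if (s$def$category == "SOIL") -1 else 1
    d <- if (s$def$category == "SOIL") soil_delta else sig[[nm]]
    sp_n <- split_isotopologues(s$totals$total * s$n_frac, d, conv)
    sp_s <- split_isotopologues(s$totals$total * (1 - s$n_frac), d, conv)
    f$s12_n <- f$s12_n + sgn * sp_n$s12
    f$s12_s <- f$s12_s + sgn * sp_s$s12
    f$s13_n <- f$s13_n + sgn * sp_n$s13
    f$s13_s <- f$s13_s + sgn * sp_s$s13
  }
  f
}

#' Build a factorial scenario catalogue around the truth
#'
#' Creates candidate variants per category emulating the spread of bottom-up
#' inventories: the truth plus trend offsets (steeper/shallower inventories),
#' a flat-trend fossil-fuel variant at an upward-revised level, a no-step
#' wetland variant, a non-declining biomass-burning variant, and the low (15
#' Tg/yr, the truth) versus high (52 Tg/yr) geological source. The truth is
#' always candidate 1 of each category, so the true scenario is the first
#' enumerated one.
#'
#' @param world A `ch4_world` from [generate_world()].
#' @param counts Named or positional counts of candidates per category, in
#'   the order (IFF, AGW, WET, BB, GEO); defaults to `c(4, 3, 2, 2, 2)`
#'   giving 96 scenarios.
#' @return List: `catalogue` (a [scenario_catalogue()]) and `composition`
#'   (per category candidate, the per-sector annual totals used for
#'   signature weighting).
#' @export
make_scenario_catalogue <- function(world, counts = c(4, 3, 2, 2, 2)) {
  stopifnot(inherits(world, "ch4_world"), length(counts) == 5)
  counts <- stats::setNames(as.integer(counts),
                            c("IFF", "AGW", "WET", "BB", "GEO"))
  if (any(counts < 1)) stop("every category needs at least one candidate")
  years <- world$cfg$years
  t_rel <- years - years[1]
  sec_of <- function(cat) {
    Filter(function(s) s$def$category == cat, world$sectors)
  }

  # a candidate = list(label, sectors = named list of annual total vectors)
  truth_cand <- function(cat) {
    list(label = "truth",
         sectors = lapply(sec_of(cat), function(s) s$totals$total))
  }
  scale_cand <- function(cand, label, f) {
    list(label = label, sectors = lapply(cand$sectors, function(v) {
      pmax(v * f, 0)
    }))
  }
  trend_cand <- function(cand, label, slope) {
    tot <- Reduce(`+`, cand$sectors)
    add <- slope * t_rel
    list(label = label, sectors = lapply(cand$sectors, function(v) {
      pmax(v + add * v / tot, 0)
    }))
  }

  variants <- list(
    IFF = list(truth_cand("IFF"),
               trend_cand(truth_cand("IFF"), "steep", 1.0),
               trend_cand(truth_cand("IFF"), "shallow", -0.8),
               {
                 tc <- truth_cand("IFF")
                 flat <- lapply(tc$sectors, function(v) {
                   rep(mean(v) + 8, length(v))  # flat, upward-revised level
                 })
                 list(label = "flat_high", sectors = flat)
               }),
    AGW = list(truth_cand("AGW"),
               trend_cand(truth_cand("AGW"), "steep", 0.8),
               trend_cand(truth_cand("AGW"), "shallow", -0.8)),
    WET = list(truth_cand("WET"),
               {
                 tc <- truth_cand("WET")
                 tc$sectors$wetland_tropical <-
                   tc$sectors$wetland_tropical -
                   ifelse(years >= 2007, 7.3, 0)  # step removed
                 tc$label <- "nostep"
                 tc
               }),
    BB = list(truth_cand("BB"),
              {
                tc <- truth_cand("BB")
                tot <- tc$sectors$biomass_burning
                tc$sectors$biomass_burning <- tot + 0.2 * t_rel  # no decline
                tc$label <- "flat"
                tc
              }),
    GEO = list(truth_cand("GEO"),
               scale_cand(truth_cand("GEO"), "high", 52 / 15))
  )
  variants$GEO[[1]]$label <- "low"

  candidates <- list()
  composition <- list()
  for (cat in names(variants)) {
    v <- variants[[cat]][seq_len(counts[cat])]
    cand_list <- list()
    comp_list <- list()
    for (cv in v) {
      nfr <- vapply(sec_of(cat), function(s) s$n_frac, numeric(1))
      tot_n <- Reduce(`+`, Map(function(tv, f) tv * f, cv$sectors,
                               nfr[names(cv$sectors)]))
      tot_s <- Reduce(`+`, Map(function(tv, f) tv * (1 - f), cv$sectors,
                               nfr[names(cv$sectors)]))
      cand_list[[cv$label]] <- data.frame(year = years, flux_n = tot_n,
                                          flux_s = tot_s)
      comp_list[[cv$label]] <- cv$sectors
    }
    candidates[[cat]] <- cand_list
    composition[[cat]] <- comp_list
  }

  oth_sec <- sec_of("OTH")
  oth <- data.frame(
    year = years,
    flux_n = Reduce(`+`, lapply(oth_sec, function(s) s$totals$total * s$n_frac)),
    flux_s = Reduce(`+`, lapply(oth_sec, function(s) {
      s$totals$total * (1 - s$n_frac)
    })))
  soil_s <- world$sectors$soil_uptake
  soil <- data.frame(year = years,
                     flux_n = soil_s$totals$total * soil_s$n_frac,
                     flux_s = soil_s$totals$total * (1 - soil_s$n_frac))
  composition$OTH <- list(shared = lapply(oth_sec, function(s) s$totals$total))

  list(catalogue = scenario_catalogue(candidates, oth, soil),
       composition = composition)
}
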