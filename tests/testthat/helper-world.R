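# shared fixtures, built in code and cached per test session

.world_cache <- new.env(parent = emptyenv())

test_world <- function() {
  if (is.null(.world_cache$world)) {
    .world_cache$world <- generate_world(truth_config())
  }
  .world_cache$world
}

test_catalogue <- function() {
  if (is.null(.world_cache$cat)) {
    .world_cache$cat <- make_scenario_catalogue(test_world())
  }
  .world_cache$cat
}

# truth forcing with the wetland contribution removed, plus the truth wetland
# series and its per-year flux-weighted signature (for the joint inversion)
wetland_free_forcing <- function(world) {
  conv <- delta_convention()
  wet <- Filter(function(s) s$def$category == "WET", world$sectors)
  f <- world$truth$forcing
  for (s in wet) {
    spn <- split_isotopologues(s$totals$total * s$n_frac, s$def$sig_mean, conv)
    sps <- split_isotopologues(s$totals$total * (1 - s$n_frac),
                               s$def$sig_mean, conv)
    f$s12_n <- f$s12_n - spn$s12
    f$s12_s <- f$s12_s - sps$s12
    f$s13_n <- f$s13_n - spn$s13
    f$s13_s <- f$s13_s - sps$s13
  }
  tot <- Reduce(`+`, lapply(wet, function(s) s$totals$total))
  tot_n <- Reduce(`+`, lapply(wet, function(s) s$totals$total * s$n_frac))
  wdelta <- Reduce(`+`, lapply(wet, function(s) {
    s$totals$total * s$def$sig_mean
  })) / tot
  list(forcing = f, wet_total = tot, n_frac = mean(tot_n / tot),
       wet_delta = stats::setNames(wdelta, world$cfg$years))
}

# constant flat forcing for analytic box-model checks
flat_forcing <- function(years, s12_n, s12_s, s13_n, s13_s) {
  data.frame(year = years, s12_n = s12_n, s12_s = s12_s,
             s13_n = s13_n, s13_s = s13_s)
}
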