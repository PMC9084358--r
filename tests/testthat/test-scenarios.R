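make_series <- function(years, n, s) data.frame(year = years, flux_n = n,
                                                flux_s = s)

tiny_catalogue <- function(counts = c(2, 1, 1, 1, 1), years = 2000:2004) {
  mk <- function(lvl) make_series(years, lvl, lvl / 2)
  cand <- list(
    IFF = lapply(seq_len(counts[1]), function(i) mk(100 + 10 * i)),
    AGW = lapply(seq_len(counts[2]), function(i) mk(200 + i)),
    WET = lapply(seq_len(counts[3]), function(i) mk(150 + i)),
    BB = lapply(seq_len(counts[4]), function(i) mk(20 + i)),
    GEO = lapply(seq_len(counts[5]), function(i) mk(15 * i))
  )
  for (cat in names(cand)) {
    names(cand[[cat]]) <- paste0(tolower(cat), seq_along(cand[[cat]]))
  }
  scenario_catalogue(cand, oth = mk(40), soil = mk(30))
}

test_that("sector mapping sums member sectors into categories", {
  inv <- data.frame(
    sector = c("coal", "gas", "rice", "landfill", "enteric"),
    year = 2000, hemisphere = "N",
    flux_tg = c(30, 20, 30, 25, 60))
  out <- map_sectors(inv)
  expect_equal(out$flux_tg[out$category == "IFF"], 50)
  expect_equal(out$flux_tg[out$category == "AGW"], 115)
})

test_that("unmapped sectors fall into OTH with a warning; bad rows are rejected", {
  inv <- data.frame(sector = c("coal", "volcano"), year = 2000,
                    hemisphere = "N", flux_tg = c(30, 5))
  expect_warning(out <- map_sectors(inv), "volcano")
  expect_equal(out$flux_tg[out$category == "OTH"], 5)
  expect_error(map_sectors(data.frame(sector = "coal", year = 2000,
                                      hemisphere = "N", flux_tg = -1)),
               "negative")
  empty <- map_sectors(data.frame(sector = character(), year = numeric(),
                                  hemisphere = character(),
                                  flux_tg = numeric()))
  expect_equal(nrow(empty), 0L)
})

test_that("the mapping table shipped as CSV matches the built-in default", {
  path <- system.file("extdata", "sector_mapping.csv", package = "ch4box")
  csv <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(csv, default_sector_mapping())
})

test_that("scenario enumeration is the factorial product in stable order", {
  cat96 <- tiny_catalogue(c(4, 3, 2, 2, 2))
  scen <- enumerate_scenarios(cat96)
  expect_equal(nrow(scen), 96)
  expect_equal(nrow(enumerate_scenarios(tiny_catalogue(c(1, 1, 1, 1, 1)))), 1)
  two <- enumerate_scenarios(tiny_catalogue(c(2, 1, 1, 1, 1)))
  expect_equal(nrow(two), 2)
  expect_identical(two$scenario_id,
                   enumerate_scenarios(tiny_catalogue(c(2, 1, 1, 1, 1)))$scenario_id)
  # lexicographic: IFF index most significant, GEO fastest
  expect_equal(scen$iff, rep(1:4, each = 24))
  expect_equal(scen$geo, rep(1:2, times = 48))
  expect_equal(anyDuplicated(scen$scenario_id), 0L)
})

test_that("combine_total applies the net-source sum with soil subtracted", {
  years <- 2000:2004
  cand <- list(IFF = list(a = make_series(years, 60, 40)),
               AGW = list(a = make_series(years, 120, 80)),
               WET = list(a = make_series(years, 60, 90)),
               BB = list(a = make_series(years, 10, 10)),
               GEO = list(a = make_series(years, 10, 5)))
  cat1 <- scenario_catalogue(cand, oth = make_series(years, 25, 15),
                             soil = make_series(years, 20, 10))
  scen <- enumerate_scenarios(cat1)
  tot <- combine_total(cat1, scen[1, ])
  # 100 + 200 + 150 + 20 + 15 + 40 - 30 = 495 globally
  expect_equal(tot$flux_n + tot$flux_s, rep(495, length(years)))
  expect_equal(tot$flux_n, rep(60 + 120 + 60 + 10 + 10 + 25 - 20, 5))
})

test_that("a soil sink exceeding the sources is rejected", {
  years <- 2000:2004
  zero <- make_series(years, 0, 0)
  cand <- list(IFF = list(a = zero), AGW = list(a = zero),
               WET = list(a = zero), BB = list(a = zero),
               GEO = list(a = zero))
  cat0 <- scenario_catalogue(cand, oth = zero,
                             soil = make_series(years, 20, 10))
  expect_error(combine_total(cat0, enumerate_scenarios(cat0)[1, ]),
               "negative net source")
})

test_that("high vs low geological candidates shift the total by their difference", {
  years <- 2000:2004
  mk <- function(lvl) make_series(years, lvl * 2 / 3, lvl / 3)
  cand <- list(IFF = list(a = mk(100)), AGW = list(a = mk(200)),
               WET = list(a = mk(150)), BB = list(a = mk(20)),
               GEO = list(low = mk(15), high = mk(52)))
  catg <- scenario_catalogue(cand, oth = mk(40), soil = mk(30))
  scen <- enumerate_scenarios(catg)
  lo <- combine_total(catg, scen[scen$geo_label == "low", ])
  hi <- combine_total(catg, scen[scen$geo_label == "high", ])
  expect_equal(hi$flux_n + hi$flux_s - (lo$flux_n + lo$flux_s),
               rep(37, length(years)))
})

test_that("catalogue validation rejects mismatched years and negative fluxes", {
  years <- 2000:2004
  mk <- function(lvl) make_series(years, lvl, lvl)
  cand <- list(IFF = list(a = mk(10)), AGW = list(a = mk(10)),
               WET = list(a = mk(10)), BB = list(a = mk(10)),
               GEO = list(a = mk(10)))
  expect_error(scenario_catalogue(
    modifyList(cand, list(GEO = list(a = make_series(2001:2005, 10, 10)))),
    oth = mk(1), soil = mk(1)), "year range")
  expect_error(scenario_catalogue(
    modifyList(cand, list(BB = list(a = make_series(years, -1, 0)))),
    oth = mk(1), soil = mk(1)), "negative")
  expect_error(scenario_catalogue(cand[-1], oth = mk(1), soil = mk(1)),
               "IFF")
})
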