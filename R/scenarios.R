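#' Default sector-to-category mapping
#'
#' Maps inventory sector names onto the six source categories plus the soil
#' sink: IFF (industrial fossil fuel: coal, oil, gas), AGW (agriculture,
#' landfills and waste: enteric fermentation, manure, rice, landfill, waste),
#' WET (natural wetlands), BB (biomass burning), GEO (geological seeps), OTH
#' (other natural: termites, freshwater, wild animals) and SOIL (soil uptake,
#' a sink). The same table ships as an editable CSV in
#' `system.file("extdata", "sector_mapping.csv", package = "ch4box")`.
#'
#' @return Data frame with columns `sector` and `category`.
#' @export
default_sector_mapping <- function() {
  data.frame(
    sector = c("coal", "oil", "gas", "oil_gas",
               "enteric", "manure", "livestock", "rice", "landfill", "waste",
               "wetland", "wetland_tropical", "wetland_boreal",
               "biomass_burning", "geological",
               "termites", "freshwater", "wild_animals", "soil_uptake"),
    category = c("IFF", "IFF", "IFF", "IFF",
                 "AGW", "AGW", "AGW", "AGW", "AGW", "AGW",
                 "WET", "WET", "WET",
                 "BB", "GEO",
                 "OTH", "OTH", "OTH", "SOIL"),
    stringsAsFactors = FALSE
  )
}

ch4_categories <- function() c("IFF", "AGW", "WET", "BB", "GEO", "OTH")

#' Aggregate an inventory table into category series
#'
#' Sums sector rows into per-category hemispheric flux series. Sectors absent
#' from the mapping are assigned to OTH with a warning; negative fluxes are
#' rejected. An empty inventory returns a zero-row frame rather than zeros.
#'
#' @param inventory Data frame with columns `sector`, `year`, `hemisphere`
#'   ("N"/"S") and `flux_tg` (Tg CH4/yr); an optional `dataset` column is
#'   carried through grouping.
#' @param mapping Data frame with columns `sector`, `category`, or a path to a
#'   CSV with those columns. Defaults to [default_sector_mapping()].
#' @return Data frame with columns `category`, `year`, `hemisphere`,
#'   `flux_tg`.
#' @export
map_sectors <- function(inventory, mapping = default_sector_mapping()) {
  if (is.character(mapping)) {
    mapping <- utils::read.csv(mapping, stringsAsFactors = FALSE)
  }
  req <- c("sector", "year", "hemisphere", "flux_tg")
  if (!all(req %in% names(inventory))) {
    stop("inventory must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(inventory) == 0L) {
    return(data.frame(category = character(), year = numeric(),
                      hemisphere = character(), flux_tg = numeric()))
  }
  if (!all(is.finite(inventory$flux_tg)) || any(inventory$flux_tg < 0)) {
    stop("negative or non-finite flux rows in inventory")
  }
  if (!all(inventory$hemisphere %in% c("N", "S"))) {
    stop("hemisphere must be 'N' or 'S'")
  }
  cat <- mapping$category[match(inventory$sector, mapping$sector)]
  unmapped <- unique(inventory$sector[is.na(cat)])
  if (length(unmapped) > 0L) {
    warning("unmapped sectors assigned to OTH: ",
            paste(unmapped, collapse = ", "))
    cat[is.na(cat)] <- "OTH"
  }
  agg <- stats::aggregate(
    list(flux_tg = inventory$flux_tg),
    by = list(category = cat, year = inventory$year,
              hemisphere = inventory$hemisphere),
    FUN = sum)
  agg[order(agg$category, agg$year, agg$hemisphere), , drop = FALSE]
}

# validate a category flux series: data.frame(year, flux_n, flux_s)
check_category_series <- function(x, name = "series") {
  req <- c("year", "flux_n", "flux_s")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    stop(name, " must be a data.frame with columns year, flux_n, flux_s")
  }
  if (any(diff(x$year) != 1)) stop(name, ": years must be contiguous")
  if (!all(is.finite(c(x$flux_n, x$flux_s)))) {
    stop(name, ": non-finite fluxes")
  }
  if (any(x$flux_n < 0) || any(x$flux_s < 0)) {
    stop(name, ": negative fluxes")
  }
  invisible(x)
}

#' Assemble a factorial catalogue of emission scenarios
#'
#' Each source category carries an ordered list of candidate flux series; one
#' scenario picks one candidate per category. OTH is a single shared series
#' and the soil sink is a single uptake series subtracted from every scenario.
#'
#' @param candidates Named list with elements `IFF`, `AGW`, `WET`, `BB`,
#'   `GEO`; each a named list of candidate series, a candidate being a data
#'   frame with columns `year`, `flux_n`, `flux_s` (Tg CH4/yr, >= 0).
#' @param oth Single candidate series for the OTH category.
#' @param soil Soil-sink series in the same format; fluxes are non-negative
#'   uptake magnitudes that `combine_total()` subtracts.
#' @return An object of class `scenario_catalogue`.
#' @export
scenario_catalogue <- function(candidates, oth, soil) {
  varied <- c("IFF", "AGW", "WET", "BB", "GEO")
  if (!all(varied %in% names(candidates))) {
    stop("candidates must name all of ", paste(varied, collapse = ", "))
  }
  years <- NULL
  for (cat in varied) {
    cand <- candidates[[cat]]
    if (length(cand) == 0L) stop("category ", cat, " has no candidates")
    if (is.null(names(cand)) || any(names(cand) == "")) {
      names(cand) <- paste0(cat, seq_along(cand))
      candidates[[cat]] <- cand
    }
    for (nm in names(cand)) {
      check_category_series(cand[[nm]], paste(cat, nm))
      if (is.null(years)) years <- cand[[nm]]$year
      if (!identical(years, cand[[nm]]$year)) {
        stop("candidate ", cat, "/", nm, " year range differs")
      }
    }
  }
  check_category_series(oth, "OTH")
  check_category_series(soil, "SOIL")
  if (!identical(years, oth$year) || !identical(years, soil$year)) {
    stop("OTH/SOIL year range differs from candidates")
  }
  structure(list(candidates = candidates, oth = oth, soil = soil,
                 years = years),
            class = "scenario_catalogue")
}

#' Enumerate all scenarios of a catalogue
#'
#' Cartesian product over the five varied categories, in deterministic
#' lexicographic order of the (IFF, AGW, WET, BB, GEO) candidate indices (IFF
#' most significant). Scenario ids are stable across runs.
#'
#' @param catalogue A [scenario_catalogue()].
#' @return Data frame with one row per scenario: `scenario_id`, per-category
#'   candidate indices (`iff`, `agw`, `wet`, `bb`, `geo`) and labels
#'   (`iff_label`, ...).
#' @export
enumerate_scenarios <- function(catalogue) {
  stopifnot(inherits(catalogue, "scenario_catalogue"))
  cand <- catalogue$candidates
  n <- vapply(cand, length, integer(1))[c("IFF", "AGW", "WET", "BB", "GEO")]
  # expand.grid varies its first factor fastest; feed reversed order so that
  # IFF is the most significant index
  g <- expand.grid(geo = seq_len(n["GEO"]), bb = seq_len(n["BB"]),
                   wet = seq_len(n["WET"]), agw = seq_len(n["AGW"]),
                   iff = seq_len(n["IFF"]))
  g <- g[, c("iff", "agw", "wet", "bb", "geo")]
  g <- g[do.call(order, g), , drop = FALSE]
  rownames(g) <- NULL
  g$iff_label <- names(cand$IFF)[g$iff]
  g$agw_label <- names(cand$AGW)[g$agw]
  g$wet_label <- names(cand$WET)[g$wet]
  g$bb_label <- names(cand$BB)[g$bb]
  g$geo_label <- names(cand$GEO)[g$geo]
  g$scenario_id <- sprintf("S%03d_%s", seq_len(nrow(g)),
                           paste(g$iff_label, g$agw_label, g$wet_label,
                                 g$bb_label, g$geo_label, sep = "."))
  g[, c("scenario_id", "iff", "agw", "wet", "bb", "geo",
        "iff_label", "agw_label", "wet_label", "bb_label", "geo_label")]
}

# fetch the per-category series of one scenario (row of enumerate_scenarios())
scenario_series <- function(catalogue, scenario) {
  list(
    IFF = catalogue$candidates$IFF[[scenario$iff]],
    AGW = catalogue$candidates$AGW[[scenario$agw]],
    WET = catalogue$candidates$WET[[scenario$wet]],
    BB = catalogue$candidates$BB[[scenario$bb]],
    GEO = catalogue$candidates$GEO[[scenario$geo]],
    OTH = catalogue$oth,
    SOIL = catalogue$soil
  )
}

#' Net total source series of one scenario
#'
#' Per-year, per-hemisphere sum of the six category sources with the soil
#' uptake subtracted:
#' `S_tot = S_IFF + S_AGW + S_WET + S_BB + S_GEO + S_OTH - S_soil`.
#'
#' @param catalogue A [scenario_catalogue()].
#' @param scenario One row of [enumerate_scenarios()] (or a list with
#'   components `iff`, `agw`, `wet`, `bb`, `geo`).
#' @return Data frame with columns `year`, `flux_n`, `flux_s`. Errors if the
#'   net source is negative in any year and hemisphere.
#' @export
combine_total <- function(catalogue, scenario) {
  ser <- scenario_series(catalogue, scenario)
  years <- catalogue$years
  fn <- rowSums(vapply(ser[ch4_categories()], function(s) s$flux_n,
                       numeric(length(years))))
  fs <- rowSums(vapply(ser[ch4_categories()], function(s) s$flux_s,
                       numeric(length(years))))
  fn <- fn - ser$SOIL$flux_n
  fs <- fs - ser$SOIL$flux_s
  if (any(fn < 0) || any(fs < 0)) {
    stop("negative net source after soil subtraction")
  }
  data.frame(year = years, flux_n = fn, flux_s = fs)
}
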