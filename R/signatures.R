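#' Regular lat/lon gridded field
#'
#' A value (flux in Tg/yr per cell, or a delta-13C signature in permil) on a
#' regular latitude/longitude grid, with an optional per-cell 1-sigma layer.
#' Hemisphere membership is decided by the cell-center latitude
#' (`lat >= 0` is northern); cells are never split across the equator.
#'
#' @param lat Ascending vector of cell-center latitudes (degrees).
#' @param lon Vector of cell-center longitudes (degrees).
#' @param values Matrix `length(lat) x length(lon)` of cell values.
#' @param sigma Optional matrix of the same shape with per-cell 1-sigma
#'   uncertainties (>= 0).
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(lat, lon, values, sigma = NULL) {
  stopifnot(is.numeric(lat), is.numeric(lon), !is.unsorted(lat))
  if (!is.matrix(values) || nrow(values) != length(lat) ||
      ncol(values) != length(lon)) {
    stop("values must be a length(lat) x length(lon) matrix")
  }
  if (!is.null(sigma)) {
    if (!is.matrix(sigma) || !all(dim(sigma) == dim(values))) {
      stop("sigma layer must match the value grid")
    }
    if (any(sigma < 0)) stop("sigma must be non-negative")
  }
  structure(list(lat = lat, lon = lon, values = values, sigma = sigma),
            class = "gridded_field")
}

congruent_grids <- function(a, b) {
  identical(a$lat, b$lat) && identical(a$lon, b$lon)
}

hemisphere_mask <- function(field, region = c("global", "N", "S")) {
  region <- match.arg(region)
  keep <- switch(region,
                 global = rep(TRUE, length(field$lat)),
                 N = field$lat >= 0,
                 S = field$lat < 0)
  matrix(keep, nrow = length(field$lat), ncol = length(field$lon))
}

#' Emission-weighted mean signature over a region
#'
#' Flux-weighted mean of the cell signatures over the cells of one hemisphere
#' (or the whole grid): `sum(F_c * delta_c) / sum(F_c)`.
#'
#' @param flux A [gridded_field()] of cell fluxes (Tg/yr).
#' @param sig A congruent [gridded_field()] of cell signatures (permil).
#' @param region `"global"`, `"N"` or `"S"`.
#' @return The weighted signature (permil). Errors if the regional flux total
#'   is zero.
#' @export
weighted_signature <- function(flux, sig, region = c("global", "N", "S")) {
  stopifnot(inherits(flux, "gridded_field"), inherits(sig, "gridded_field"))
  if (!congruent_grids(flux, sig)) stop("flux and signature grids differ")
  m <- hemisphere_mask(flux, region)
  w <- flux$values[m]
  if (any(w < 0)) stop("negative flux cell")
  tot <- sum(w)
  if (tot <= 0) stop("zero total flux in region: weighted signature undefined")
  sum(w * sig$values[m]) / tot
}

# deterministic per-draw substream seed; `stream` separates independent
# sources sharing one master seed. Kept below 2^31 - 1.
substream_seed <- function(master, stream, draw) {
  (as.integer(master) + 100003L * as.integer(stream) + as.integer(draw)) %%
    2147483647L
}

#' Monte Carlo perturbations of a signature map
#'
#' Draws `n` maps with independent cell-wise Gaussian perturbations at the
#' map's 1-sigma layer, clipped to `clip` to guard unphysical tails. Draw `i`
#' is generated from its own counter-based substream, so individual draws are
#' reproducible from `(seed, stream, i)` independent of evaluation order.
#'
#' @param sig A [gridded_field()] with a `sigma` layer.
#' @param n Number of draws (>= 1).
#' @param seed Master integer seed.
#' @param stream Integer stream id separating independent sources under one
#'   master seed.
#' @param clip Length-2 clipping bounds in permil.
#' @return A 3-d array `lat x lon x n` of perturbed signature values.
#' @export
sample_signature_maps <- function(sig, n, seed, stream = 0L,
                                  clip = c(-120, 10)) {
  stopifnot(inherits(sig, "gridded_field"), n >= 1)
  if (is.null(sig$sigma)) stop("signature field has no sigma layer")
  out <- array(NA_real_, dim = c(length(sig$lat), length(sig$lon), n))
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, stream, i))
    z <- matrix(stats::rnorm(length(sig$values)), nrow = nrow(sig$values))
    out[, , i] <- pmin(pmax(sig$values + sig$sigma * z, clip[1]), clip[2])
  }
  out
}

#' Monte Carlo draws of a scalar (globally averaged) signature
#'
#' For source categories without a resolved map, draws `n` Gaussian samples
#' of the global-representative signature, clipped like the map draws.
#'
#' @param mean Signature mean (permil).
#' @param sigma 1-sigma uncertainty (permil, >= 0).
#' @param n Number of draws (>= 0); `n = 0` returns an empty vector.
#' @inheritParams sample_signature_maps
#' @return Numeric vector of length `n`.
#' @export
scalar_signature <- function(mean, sigma, n, seed, stream = 0L,
                             clip = c(-120, 10)) {
  stopifnot(is.finite(mean), is.finite(sigma), sigma >= 0, n >= 0)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(substream_seed(seed, stream, i))
    out[i] <- stats::rnorm(1, mean, sigma)
  }
  pmin(pmax(out, clip[1]), clip[2])
}
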