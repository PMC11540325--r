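#' Vegetation indices from plot-level band means
#'
#' Normalized-difference and ratio indices computed from mean plot
#' reflectance.  Reflectances are expected on a 0--1 scale; values above 1
#' (uncalibrated digital numbers) are accepted with a warning.  A zero
#' denominator yields `NA` with a warning, never a silent zero.
#'
#' * `ndvi()`  -- (NIR - Red) / (NIR + Red)
#' * `gndvi()` -- (NIR - Green) / (NIR + Green)
#' * `ndre()`  -- (NIR - RedEdge) / (NIR + RedEdge)
#' * `simple_ratio()` -- NIR / Red, related to NDVI by
#'   NDVI = (SR - 1) / (SR + 1)
#'
#' @param nir,red,green,rededge numeric vectors of mean plot reflectance,
#'   non-negative.
#' @return numeric vector; normalized-difference indices lie in \[-1, 1\]
#'   for non-negative bands, the simple ratio is non-negative.
#' @examples
#' ndvi(0.5, 0.1)          # 0.667
#' simple_ratio(0.5, 0.1)  # 5
#' @export
ndvi <- function(nir, red) {
  normalized_difference(nir, red, "ndvi")
}

#' @rdname ndvi
#' @export
gndvi <- function(nir, green) {
  normalized_difference(nir, green, "gndvi")
}

#' @rdname ndvi
#' @export
ndre <- function(nir, rededge) {
  normalized_difference(nir, rededge, "ndre")
}

#' @rdname ndvi
#' @export
simple_ratio <- function(nir, red) {
  check_band(nir, "nir")
  check_band(red, "red")
  out <- nir / red
  bad <- !is.na(red) & red == 0
  if (any(bad)) {
    warning("simple_ratio undefined where red band is zero; returning NA")
    out[bad] <- NA_real_
  }
  out
}

normalized_difference <- function(a, b, name) {
  check_band(a, "first band")
  check_band(b, "second band")
  denom <- a + b
  out <- (a - b) / denom
  bad <- !is.na(denom) & denom == 0
  if (any(bad)) {
    warning(sprintf("%s undefined where both bands are zero; returning NA",
                    name))
    out[bad] <- NA_real_
  }
  out
}

check_band <- function(x, what) {
  if (!is.numeric(x)) {
    stop(sprintf("%s must be numeric", what), call. = FALSE)
  }
  if (any(x < 0, na.rm = TRUE)) {
    stop(sprintf("%s contains negative reflectance", what), call. = FALSE)
  }
  if (any(x > 1, na.rm = TRUE)) {
    warning(sprintf("%s exceeds 1; treating as uncalibrated digital numbers",
                    what), call. = FALSE)
  }
  invisible(x)
}

#' Add standard vegetation-index columns to a plot table
#'
#' Computes the five indices used throughout the package (`ndvi`, `gndvi`,
#' `ndre`, `nir`, `ratio`) from band-mean columns `band_nir`, `band_red`,
#' `band_green`, `band_rededge`.  `nir` is the raw NIR band mean carried
#' through as an index in its own right.
#'
#' @param plots data frame with `band_*` columns.
#' @return `plots` with index columns appended.
#' @export
vegetation_indices <- function(plots) {
  need <- c("band_nir", "band_red", "band_green", "band_rededge")
  missing_cols <- setdiff(need, names(plots))
  if (length(missing_cols)) {
    stop("missing band columns: ", paste(missing_cols, collapse = ", "))
  }
  plots$ndvi  <- ndvi(plots$band_nir, plots$band_red)
  plots$gndvi <- gndvi(plots$band_nir, plots$band_green)
  plots$ndre  <- ndre(plots$band_nir, plots$band_rededge)
  plots$nir   <- plots$band_nir
  plots$ratio <- simple_ratio(plots$band_nir, plots$band_red)
  plots
}
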