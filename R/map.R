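#' Intensity map container
#'
#' A 2D intensity map in arbitrary units, either on the polar
#' reconstruction grid (rows = radii, columns = azimuths) or on the 1 mm
#' Cartesian grid (rows top-to-bottom, row 1 at y = +max_radius; columns
#' left-to-right).  "Upper zone" always means the upper half of the
#' image, i.e. rows above the center row.
#'
#' @param values Numeric matrix, finite and non-negative.
#' @param kind `"polar"` or `"cartesian"`.
#' @param radii,az_deg Polar axes (m, degrees); required for polar maps.
#' @param max_radius Disc radius in meters (Cartesian maps).
#' @param pixel Cartesian pixel size in meters.
#' @param conductivity Conductivity label (S/m) of the reconstruction
#'   that produced the map, or `NA`.
#' @param breast_id Optional identifier.
#' @return An object of class `mwi_map`.
#' @export
intensity_map_new <- function(values, kind = c("cartesian", "polar"),
                              radii = NULL, az_deg = NULL,
                              max_radius = 0.07, pixel = 0.001,
                              conductivity = NA_real_, breast_id = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !all(is.finite(values)))
    stop("values must be a finite numeric matrix", call. = FALSE)
  if (any(values < 0))
    stop("intensity values must be non-negative", call. = FALSE)
  if (kind == "polar") {
    stopifnot(length(radii) == nrow(values), length(az_deg) == ncol(values))
    max_radius <- max(radii)
  }
  structure(list(values = values, kind = kind, radii = radii,
                 az_deg = az_deg, max_radius = max_radius, pixel = pixel,
                 conductivity = conductivity, breast_id = breast_id),
            class = "mwi_map")
}

#' @export
print.mwi_map <- function(x, ...) {
  cat(sprintf("mwi_map (%s) %dx%d, range [%.4g, %.4g]",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  if (!is.na(x$conductivity)) cat(sprintf(", sigma = %g S/m", x$conductivity))
  cat("\n")
  invisible(x)
}

#' Logical disc mask of a Cartesian map
#'
#' `TRUE` for pixels whose center lies inside (or on) the imaging disc.
#'
#' @param map An `mwi_map` of kind `"cartesian"`, or an odd integer side
#'   length (interpreted as a 1 mm grid spanning the default 7 cm disc).
#' @return Logical matrix.
#' @export
disc_mask <- function(map) {
  if (inherits(map, "mwi_map")) {
    stopifnot(map$kind == "cartesian")
    n <- nrow(map$values)
    rad_px <- map$max_radius / map$pixel
  } else {
    n <- as.integer(map)
    rad_px <- (n - 1) / 2
  }
  ctr <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  sqrt((rr - ctr)^2 + (cc - ctr)^2) <= rad_px + 1e-9
}

## x/y coordinate (meters) of a cartesian pixel center; row 1 is y = +R
.cart_axes <- function(n, pixel, max_radius) {
  x <- (seq_len(n) - (n + 1) / 2) * pixel
  y <- -x
  list(x = x, y = y)
}
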