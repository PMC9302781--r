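#' Polar reconstruction grid
#'
#' The native grid of the Huygens-principle reconstruction: radial
#' sampling of 1 mm out to the receiver ring radius and azimuthal
#' sampling of 3 degrees.
#'
#' @param max_radius Maximum radius in meters (equals the receiver ring
#'   radius; default 0.07).
#' @param radial_step Radial sampling in meters (default 0.001).
#' @param az_step Azimuthal sampling in degrees (default 3; must divide
#'   360).
#' @return Object of class `mwi_grid` with `radii` (m) and `az_deg`.
#' @export
reconstruction_grid <- function(max_radius = 0.07, radial_step = 0.001,
                                az_step = 3) {
  if (max_radius <= 0 || radial_step <= 0 || az_step <= 0)
    stop("grid samplings must be positive", call. = FALSE)
  if (abs(360 / az_step - round(360 / az_step)) > 1e-9)
    stop("az_step must divide 360 degrees", call. = FALSE)
  structure(list(radii = seq(radial_step, max_radius, by = radial_step),
                 az_deg = seq(0, 360 - az_step, by = az_step),
                 radial_step = radial_step, az_step = az_step,
                 max_radius = max_radius),
            class = "mwi_grid")
}

## distances (meters) from every grid point (row-major rho x phi) to every
## receiver; clamped away from zero so receiver-coincident grid points do
## not hit the kernel singularity
.grid_receiver_dist <- function(grid, geometry, clamp = 1e-6) {
  rho <- grid$radii
  phi <- .deg2rad(grid$az_deg)
  gx <- outer(rho, cos(phi))
  gy <- outer(rho, sin(phi))
  d <- sqrt(outer(c(gx), geometry$receiver_x, "-")^2 +
              outer(c(gy), geometry$receiver_y, "-")^2)
  pmax(d, clamp)
}

#' Huygens-principle internal field
#'
#' Back-propagates the doublet-differenced signals from the receiving
#' circle into the imaging domain: for each section m and frequency f,
#' \deqn{E(\rho, \phi; m; f) \propto \sum_{n=1}^{N_{PT}}
#'   \Delta S21(n, m, f)\; G(k_1 |\rho_n - \rho|)}
#' with \eqn{G = H_0^{(2)}(k_1 r)} and, for a lossy medium, the
#' attenuation-compensation factor \eqn{e^{+|Im k_1| r}} so that image
#' points deep inside the medium are not penalized.
#'
#' @param diff Differenced signals from [doublet_difference()], shape
#'   (receivers, sections, frequencies).
#' @param geometry The acquisition geometry.
#' @param medium A [medium_model()]; its conductivity selects the
#'   weighting of the kernel.
#' @param grid A [reconstruction_grid()].
#' @param frequencies Frequencies (Hz) matching the third dimension of
#'   `diff`; defaults to `geometry$frequencies`.
#' @param compensate Attenuation compensation flag; default on (a no-op
#'   when the medium is lossless).
#' @return Complex array of shape (radii, azimuths, sections,
#'   frequencies).
#' @export
huygens_field <- function(diff, geometry, medium = medium_model(),
                          grid = reconstruction_grid(geometry$receiver_radius),
                          frequencies = geometry$frequencies,
                          compensate = TRUE) {
  stopifnot(inherits(geometry, "mwi_geometry"), inherits(grid, "mwi_grid"))
  d <- dim(diff)
  if (length(d) != 3 || d[1] != geometry$n_receivers)
    stop("diff must be (receivers x sections x frequencies)", call. = FALSE)
  if (d[3] != length(frequencies))
    stop("frequency axis mismatch", call. = FALSE)
  if (max(grid$radii) > geometry$receiver_radius + 1e-12)
    stop("grid extends beyond the receiver circle", call. = FALSE)

  n_rho <- length(grid$radii)
  n_phi <- length(grid$az_deg)
  dist <- .grid_receiver_dist(grid, geometry)   # (n_rho*n_phi) x N_PT

  E <- array(0 + 0i, dim = c(n_rho, n_phi, d[2], d[3]))
  for (i in seq_len(d[3])) {
    k1 <- complex_wavenumber(frequencies[i], medium)
    G <- matrix(greens_2d(k1, dist, kind = 2, compensate = compensate),
                nrow = nrow(dist))
    fields <- G %*% matrix(diff[, , i], nrow = d[1])   # points x sections
    E[, , , i] <- array(fields, dim = c(n_rho, n_phi, d[2]))
  }
  E
}

#' Incoherent intensity map
#'
#' Sums the squared magnitudes of the reconstructed fields over all
#' sections and frequencies: \eqn{I(\rho,\phi) = \sum_m \sum_i
#' |E(\rho,\phi; m; f_i)|^2}.  The result is non-negative and additive
#' over the frequency set.
#'
#' @param E Field array from [huygens_field()] (radii x azimuths x
#'   sections x frequencies).
#' @param grid The grid the fields live on.
#' @param conductivity Conductivity label stored with the map.
#' @param breast_id Optional identifier.
#' @return Polar `mwi_map`.
#' @export
intensity_map <- function(E, grid, conductivity = NA_real_, breast_id = NULL) {
  stopifnot(length(dim(E)) == 4, inherits(grid, "mwi_grid"))
  if (dim(E)[1] != length(grid$radii) || dim(E)[2] != length(grid$az_deg))
    stop("field and grid shapes do not match", call. = FALSE)
  I <- apply(Mod(E)^2, c(1, 2), sum)
  intensity_map_new(I, kind = "polar", radii = grid$radii,
                    az_deg = grid$az_deg, conductivity = conductivity,
                    breast_id = breast_id)
}

#' Interpolate a polar map onto the 1 mm Cartesian grid
#'
#' Bilinear interpolation in \eqn{(\rho, \phi)} with azimuthal
#' wrap-around; radii below the first ring are clamped to it.  Pixels
#' outside the disc are zero.  For the default 7 cm radius the output is
#' 141 x 141 (rows top to bottom: row 1 is y = +70 mm).
#'
#' @param pmap Polar `mwi_map`.
#' @param pixel Cartesian sampling in meters (default 0.001).
#' @return Cartesian `mwi_map`.
#' @export
polar_to_cartesian <- function(pmap, pixel = 0.001) {
  stopifnot(inherits(pmap, "mwi_map"), pmap$kind == "polar")
  R <- max(pmap$radii)
  half <- round(R / pixel)
  n <- 2L * half + 1L
  ax <- .cart_axes(n, pixel, R)
  xm <- matrix(ax$x, n, n, byrow = TRUE)
  ym <- matrix(ax$y, n, n)
  rho <- sqrt(xm^2 + ym^2)
  inside <- rho <= R + 1e-12
  phi <- .wrap360(.rad2deg(atan2(ym, xm)))

  n_r <- length(pmap$radii)
  n_a <- length(pmap$az_deg)
  r0 <- pmap$radii[1]
  dr <- pmap$radii[2] - pmap$radii[1]
  da <- pmap$az_deg[2] - pmap$az_deg[1]

  u <- pmin(pmax((rho[inside] - r0) / dr, 0), n_r - 1)
  iu0 <- floor(u); fu <- u - iu0
  iu1 <- pmin(iu0 + 1, n_r - 1)
  v <- phi[inside] / da
  iv0 <- floor(v) %% n_a; fv <- v - floor(v)
  iv1 <- (iv0 + 1) %% n_a

  m <- pmap$values
  at <- function(iu, iv) m[cbind(iu + 1, iv + 1)]
  vals <- (1 - fu) * (1 - fv) * at(iu0, iv0) +
    (1 - fu) * fv * at(iu0, iv1) +
    fu * (1 - fv) * at(iu1, iv0) +
    fu * fv * at(iu1, iv1)

  out <- matrix(0, n, n)
  out[inside] <- vals
  intensity_map_new(out, kind = "cartesian", max_radius = R, pixel = pixel,
                    conductivity = pmap$conductivity, breast_id = pmap$breast_id)
}

#' Full reconstruction: S21 dataset to Cartesian intensity map
#'
#' Convenience chain: doublet subtraction, Huygens back-propagation with
#' the requested conductivity weighting, incoherent summation, and
#' polar-to-Cartesian interpolation.
#'
#' @param s21 An `mwi_s21` dataset.
#' @param conductivity Medium conductivity in S/m (default 0.40, the
#'   level found optimal for lesion localization).
#' @param compensate Attenuation compensation flag.
#' @param grid Optional [reconstruction_grid()].
#' @param cartesian If `FALSE`, return the polar map instead.
#' @param breast_id Optional identifier.
#' @return An `mwi_map`.
#' @export
reconstruct_map <- function(s21, conductivity = 0.40, compensate = TRUE,
                            grid = NULL, cartesian = TRUE, breast_id = NULL) {
  stopifnot(inherits(s21, "mwi_s21"))
  geometry <- s21$geometry
  if (is.null(grid)) grid <- reconstruction_grid(geometry$receiver_radius)
  med <- medium_model(conductivity = conductivity)
  E <- huygens_field(doublet_difference(s21), geometry, med, grid,
                     compensate = compensate)
  pol <- intensity_map(E, grid, conductivity = conductivity,
                       breast_id = breast_id)
  if (cartesian) polar_to_cartesian(pol) else pol
}

#' Locate the maximum of an intensity map
#'
#' @param map An `mwi_map`.
#' @return For polar maps, a list with `rho` (m) and `phi` (deg); for
#'   Cartesian maps, a list with `row`, `col`, `x`, `y` (m) and `phi`.
#' @export
map_peak <- function(map) {
  stopifnot(inherits(map, "mwi_map"))
  idx <- which(map$values == max(map$values), arr.ind = TRUE)[1, ]
  if (map$kind == "polar") {
    list(rho = map$radii[idx[1]], phi = map$az_deg[idx[2]])
  } else {
    n <- nrow(map$values)
    ax <- .cart_axes(n, map$pixel, map$max_radius)
    x <- ax$x[idx[2]]; y <- ax$y[idx[1]]
    list(row = unname(idx[1]), col = unname(idx[2]), x = x, y = y,
         phi = .wrap360(.rad2deg(atan2(y, x))))
  }
}
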