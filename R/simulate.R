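#' Simulate a multi-bistatic S21 acquisition
#'
#' Single-scattering (Born-type) forward model over the acquisition
#' geometry.  For each receiver n, section m, doublet member p and
#' frequency f the recorded complex transmission parameter is
#' \deqn{S21 = D(n, m, f) + \sum_{inc} a_{inc}\,
#'   G(k_0 |r_{tx} - r_{inc}|)\, G(k_0 |r_{inc} - r_{rx}|) + \nu}
#' where the direct-coupling term `D` is evaluated from the section
#' *center* so that it is identical for both doublet members: the doublet
#' subtraction performed during image formation then removes it exactly
#' in the noiseless case.  Propagation uses the free-space wavenumber and
#' the `kind = 1` cylindrical kernel (see [greens_2d()]); `nu` is
#' additive circular complex Gaussian noise.
#'
#' This is a test-bed stand-in for the measured physics, not a full-wave
#' solver: no mutual coupling, no antenna pattern, no cup rim.
#'
#' @param phantom A [phantom_spec()].
#' @param geometry A [build_geometry()].
#' @param noise_sd Standard deviation of the complex noise per real and
#'   imaginary component (>= 0).
#' @param seed Integer seed; the simulation is bit-reproducible for a
#'   fixed (phantom, geometry, seed).
#' @return Object of class `mwi_s21`: list with `values`, a complex array
#'   of shape (receivers, sections, 2, frequencies), and `geometry`.
#' @examples
#' g <- build_geometry(freq_step = 1e9)
#' ph <- phantom_spec(inclusions = list(
#'   list(rho = 0.03, phi = 90, radius = 0.005, amplitude = 1 + 0i)))
#' s <- simulate_s21(ph, g)
#' dim(s$values)
#' @export
simulate_s21 <- function(phantom, geometry, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(phantom, "mwi_phantom"), inherits(geometry, "mwi_geometry"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (phantom$cup_radius > geometry$receiver_radius + 1e-12)
    stop("cup_radius exceeds the receiver ring radius", call. = FALSE)

  n_rx <- geometry$n_receivers
  n_sec <- geometry$n_sections
  freqs <- geometry$frequencies
  n_f <- length(freqs)
  vals <- array(0 + 0i, dim = c(n_rx, n_sec, 2, n_f))

  rx <- cbind(geometry$receiver_x, geometry$receiver_y)
  inc_xy <- lapply(phantom$inclusions, function(inc)
    c(inc$rho * cos(.deg2rad(inc$phi)), inc$rho * sin(.deg2rad(inc$phi))))

  k0 <- Re(complex_wavenumber(freqs, medium_model(conductivity = 0)))

  for (m in seq_len(n_sec)) {
    ctr <- .deg2rad(geometry$section_centers[m])
    cxy <- geometry$tx_radius * c(cos(ctr), sin(ctr))
    d_direct <- sqrt((rx[, 1] - cxy[1])^2 + (rx[, 2] - cxy[2])^2)
    for (p in 1:2) {
      tx_row <- geometry$tx[geometry$tx$section == m & geometry$tx$doublet == p, ]
      txy <- c(tx_row$x, tx_row$y)
      for (i in seq_len(n_f)) {
        s <- greens_2d(k0[i], d_direct, kind = 1)
        for (j in seq_along(phantom$inclusions)) {
          pin <- inc_xy[[j]]
          d_ti <- sqrt(sum((txy - pin)^2))
          d_ir <- sqrt((rx[, 1] - pin[1])^2 + (rx[, 2] - pin[2])^2)
          s <- s + phantom$inclusions[[j]]$amplitude *
            greens_2d(k0[i], d_ti, kind = 1) *
            greens_2d(k0[i], d_ir, kind = 1)
        }
        vals[, m, p, i] <- s
      }
    }
  }

  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    nn <- length(vals)
    vals <- vals + complex(real = stats::rnorm(nn, 0, noise_sd),
                           imaginary = stats::rnorm(nn, 0, noise_sd))
  }

  structure(list(values = vals, geometry = geometry), class = "mwi_s21")
}

#' Doublet subtraction
#'
#' Subtracts the two recordings of each section's transmitter doublet,
#' removing every contribution that does not depend on the transmitter
#' position within the section (direct antenna coupling and other fixed
#' artifacts).
#'
#' @param s21 An `mwi_s21` dataset (third dimension must have length 2).
#' @return Complex array of shape (receivers, sections, frequencies).
#' @export
doublet_difference <- function(s21) {
  stopifnot(inherits(s21, "mwi_s21"))
  d <- dim(s21$values)
  if (length(d) != 4 || d[3] != 2)
    stop("dataset must hold exactly 2 doublet positions per section", call. = FALSE)
  a1 <- array(s21$values[, , 1, ], dim = d[c(1, 2, 4)])
  a2 <- array(s21$values[, , 2, ], dim = d[c(1, 2, 4)])
  a1 - a2
}
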