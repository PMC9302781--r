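## Zeroth-order Hankel functions of complex argument.
##
## Base R's besselJ/besselY accept real arguments only, and none of the
## installed numeric packages evaluate cylinder functions off the real
## axis, so the kernel is computed here: the ascending series for
## moderate |z| and the large-argument (Hankel) asymptotic expansion
## beyond.  Arguments arising in the reconstruction satisfy Re z > 0,
## Im z <= 0, well away from the negative real axis, so the principal
## log branch is safe.

.besselh0_series <- function(z, kind) {
  ## J0 and Y0 by ascending series; converges well for |z| <= ~12
  q <- -(z * z) / 4            # successive term ratio numerator
  term <- rep(1 + 0i, length(z))
  j0 <- term
  y0s <- rep(0 + 0i, length(z))  # sum with harmonic-number weights
  hm <- 0
  for (m in seq_len(30)) {
    term <- term * q / (m * m)
    j0 <- j0 + term
    hm <- hm + 1 / m
    y0s <- y0s + hm * term       # term already carries (-1)^m
  }
  euler_gamma <- 0.57721566490153286
  y0 <- (2 / pi) * ((log(z / 2) + euler_gamma) * j0 - y0s)
  if (kind == 1) j0 + 1i * y0 else j0 - 1i * y0
}

.besselh0_asym <- function(z, kind) {
  s <- if (kind == 1) 1i else -1i
  acc <- rep(1 + 0i, length(z))
  a <- 1
  zk <- rep(1 + 0i, length(z))
  for (k in seq_len(12)) {
    a <- a * (-(2 * k - 1)^2) / (8 * k)
    zk <- zk * (s / z)
    acc <- acc + a * zk
  }
  sqrt(2 / (pi * z)) * exp(s * (z - pi / 4)) * acc
}

#' Hankel function of order zero for complex argument
#'
#' @param z Complex (or numeric) vector; must be nonzero with
#'   `Re(z) >= 0`.
#' @param kind 1 for \eqn{H_0^{(1)}}, 2 for \eqn{H_0^{(2)}}.
#' @return Complex vector of the same length.
#' @export
besselh0 <- function(z, kind = 2) {
  if (!kind %in% c(1, 2)) stop("kind must be 1 or 2", call. = FALSE)
  z <- as.complex(z)
  if (any(z == 0)) stop("H0 is singular at z = 0", call. = FALSE)
  out <- complex(length(z))
  small <- Mod(z) <= 11
  if (any(small)) out[small] <- .besselh0_series(z[small], kind)
  if (any(!small)) out[!small] <- .besselh0_asym(z[!small], kind)
  out
}

#' Medium model for the reconstruction kernel
#'
#' The assumed propagation medium inside the imaging domain.  The relative
#' permittivity defaults to 1 (free space, matching the antennas'
#' operation in air); the conductivity weights the kernel and is the
#' quantity varied across reconstructions, see [conductivity_levels].
#'
#' @param conductivity Conductivity in S/m (>= 0).
#' @param rel_permittivity Relative permittivity (>= 1).
#' @export
medium_model <- function(conductivity = 0.40, rel_permittivity = 1) {
  if (conductivity < 0) stop("conductivity must be >= 0", call. = FALSE)
  if (rel_permittivity < 1) stop("rel_permittivity must be >= 1", call. = FALSE)
  structure(list(conductivity = conductivity,
                 rel_permittivity = rel_permittivity),
            class = "mwi_medium")
}

#' Complex wavenumber of a conductive medium
#'
#' \eqn{k_1 = \omega \sqrt{\mu_0 \hat\varepsilon}} with
#' \eqn{\hat\varepsilon = \varepsilon_0 \varepsilon_r (1 - j\sigma/(\omega
#' \varepsilon_0 \varepsilon_r))} under the \eqn{e^{+j\omega t}} time
#' convention, so a lossy medium gives `Im(k1) < 0` and the outgoing
#' \eqn{H_0^{(2)}(k_1 r)} wave decays with distance.
#'
#' @param f Frequency in Hz (> 0), vectorized.
#' @param medium A [medium_model()].
#' @return Complex vector of wavenumbers (rad/m).
#' @examples
#' complex_wavenumber(1e9, medium_model(conductivity = 0))  # 2*pi/0.2998 m^-1
#' @export
complex_wavenumber <- function(f, medium = medium_model()) {
  if (any(f <= 0)) stop("frequency must be positive", call. = FALSE)
  w <- 2 * pi * f
  eps <- .eps0 * medium$rel_permittivity
  eps_hat <- eps * (1 - 1i * medium$conductivity / (w * eps))
  w * sqrt(as.complex(.mu0 * eps_hat))
}

#' Two-dimensional cylindrical-wave kernel
#'
#' The zeroth-order outgoing cylindrical-wave Green's function used to
#' propagate signals between antennas and image points, up to an
#' irrelevant constant prefactor (maps are in arbitrary units).  Under the
#' \eqn{e^{+j\omega t}} convention the outgoing kernel is
#' \eqn{H_0^{(2)}(k r)}; `kind = 1` selects the conjugate-convention
#' kernel \eqn{H_0^{(1)}}, which the forward simulator uses so that the
#' imaging operator is phase-matched (back-propagating) to the simulated
#' physics.
#'
#' With `compensate = TRUE` and a lossy wavenumber, the magnitude is
#' multiplied by \eqn{e^{+|\mathrm{Im}\,k| r}} so that scatterers deep in
#' the medium are not penalized by attenuation; for a lossless medium the
#' flag is a no-op.
#'
#' @param k Complex wavenumber (rad/m), scalar.
#' @param distance Distances in meters (> 0), vectorized.
#' @param kind Hankel kind, 1 or 2 (default 2: imaging kernel).
#' @param compensate Apply attenuation compensation (default `FALSE`).
#' @return Complex vector.
#' @export
greens_2d <- function(k, distance, kind = 2, compensate = FALSE) {
  if (any(distance <= 0)) stop("distance must be positive", call. = FALSE)
  g <- besselh0(k * distance, kind = kind)
  if (compensate) {
    alpha <- abs(Im(k))
    if (alpha > 0) g <- g * exp(alpha * distance)
  }
  g
}
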