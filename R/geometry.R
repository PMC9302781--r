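#' Build the multi-bistatic acquisition geometry
#'
#' Describes the azimuthal scanning scheme: a receiving antenna stepped
#' around a circle of radius `receiver_radius` in increments of
#' `receiver_step` degrees, and a transmitting antenna at radius
#' `tx_radius` occupying two positions (a *doublet*) inside each of five
#' transmitting sections.  Defaults reproduce the clinical device: 80
#' receiving points every 4.5 degrees at 7 cm, transmitters at 30 cm in
#' sections centered at 0, 72, 144, 216 and 288 degrees, and a 1-9 GHz
#' sweep sampled every 5 MHz.
#'
#' The two doublet members of a section sit at the section center plus or
#' minus half of `doublet_offset`.  Azimuths are measured counterclockwise
#' from the +x axis in degrees within \[0, 360).
#'
#' @param receiver_radius Receiver ring radius in meters.
#' @param tx_radius Transmitter ring radius in meters (must exceed
#'   `receiver_radius`).
#' @param receiver_step Receiver azimuthal increment in degrees; must
#'   divide 360.
#' @param section_centers Section center azimuths in degrees.
#' @param doublet_offset Angular separation of the two transmitter
#'   positions within a section, degrees.  The device value is not
#'   published; the default of 9 degrees corresponds to two adjacent
#'   transmitter slots.
#' @param freq_start,freq_stop,freq_step Frequency sweep in Hz.  Tests and
#'   examples typically decimate `freq_step` (e.g. 5e8) to keep runtime
#'   down; the device samples at 5e6.
#' @return An object of class `mwi_geometry`: a list with the receiver
#'   azimuths (`receiver_az_deg`), a transmitter table (`tx`, one row per
#'   (section, doublet) pair), and the frequency grid (`frequencies`).
#' @examples
#' g <- build_geometry(freq_step = 5e8)
#' g$n_receivers       # 80
#' nrow(g$tx)          # 10 transmitter positions
#' @export
build_geometry <- function(receiver_radius = 0.07,
                           tx_radius = 0.30,
                           receiver_step = 4.5,
                           section_centers = c(0, 72, 144, 216, 288),
                           doublet_offset = 9,
                           freq_start = 1e9,
                           freq_stop = 9e9,
                           freq_step = 5e6) {
  if (receiver_radius <= 0 || tx_radius <= 0)
    stop("radii must be positive", call. = FALSE)
  if (receiver_radius >= tx_radius)
    stop("receiver_radius must be smaller than tx_radius", call. = FALSE)
  if (receiver_step <= 0 || abs(360 / receiver_step - round(360 / receiver_step)) > 1e-9)
    stop("receiver_step must divide 360 degrees", call. = FALSE)
  if (length(section_centers) < 1)
    stop("at least one transmitting section is required", call. = FALSE)
  if (doublet_offset <= 0)
    stop("doublet_offset must be positive", call. = FALSE)
  if (freq_step <= 0 || freq_stop <= freq_start)
    stop("invalid frequency sweep", call. = FALSE)

  n_receivers <- as.integer(round(360 / receiver_step))
  receiver_az <- (seq_len(n_receivers) - 1) * receiver_step

  tx <- expand.grid(doublet = 1:2, section = seq_along(section_centers))
  tx <- tx[, c("section", "doublet")]
  tx$center_deg <- section_centers[tx$section]
  tx$az_deg <- .wrap360(tx$center_deg +
                          ifelse(tx$doublet == 1, -1, 1) * doublet_offset / 2)
  tx$x <- tx_radius * cos(.deg2rad(tx$az_deg))
  tx$y <- tx_radius * sin(.deg2rad(tx$az_deg))

  frequencies <- seq(freq_start, freq_stop, by = freq_step)
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequencies must be strictly ascending", call. = FALSE)

  structure(list(
    receiver_radius = receiver_radius,
    tx_radius = tx_radius,
    receiver_step = receiver_step,
    n_receivers = n_receivers,
    receiver_az_deg = receiver_az,
    receiver_x = receiver_radius * cos(.deg2rad(receiver_az)),
    receiver_y = receiver_radius * sin(.deg2rad(receiver_az)),
    section_centers = section_centers,
    n_sections = length(section_centers),
    doublet_offset = doublet_offset,
    tx = tx,
    frequencies = frequencies
  ), class = "mwi_geometry")
}

#' @export
print.mwi_geometry <- function(x, ...) {
  cat("Multi-bistatic acquisition geometry\n")
  cat(sprintf("  %d receivers every %g deg at %.3f m\n",
              x$n_receivers, x$receiver_step, x$receiver_radius))
  cat(sprintf("  %d transmitter positions (%d sections x 2 doublet members) at %.2f m\n",
              nrow(x$tx), x$n_sections, x$tx_radius))
  cat(sprintf("  %d frequencies, %.2f-%.2f GHz\n",
              length(x$frequencies),
              min(x$frequencies) / 1e9, max(x$frequencies) / 1e9))
  invisible(x)
}

#' Specify a scattering phantom
#'
#' A phantom is the simulated breast under test: a cup of radius
#' `cup_radius` holding zero or more point-like inclusions, each with a
#' polar position, a nominal radius and a complex scattering amplitude.
#'
#' @param cup_radius Cup radius in meters; must not exceed the receiver
#'   ring radius it is measured in.
#' @param inclusions A list; each element a list with fields `rho` (radial
#'   position, m), `phi` (azimuth, degrees), `radius` (m) and `amplitude`
#'   (complex scattering strength).
#' @param background_conductivity Conductivity of the cup medium (S/m);
#'   informational, the single-scattering forward model propagates in free
#'   space.
#' @return An object of class `mwi_phantom`.
#' @examples
#' ph <- phantom_spec(inclusions = list(
#'   list(rho = 0.03, phi = 90, radius = 0.005, amplitude = 1 + 0i)))
#' @export
phantom_spec <- function(cup_radius = 0.07,
                         inclusions = list(),
                         background_conductivity = 0) {
  if (cup_radius <= 0) stop("cup_radius must be positive", call. = FALSE)
  if (background_conductivity < 0)
    stop("background_conductivity must be >= 0", call. = FALSE)
  inclusions <- lapply(inclusions, function(inc) {
    inc <- as.list(inc)
    for (f in c("rho", "phi", "radius", "amplitude"))
      if (is.null(inc[[f]])) stop("inclusion missing field: ", f, call. = FALSE)
    if (inc$rho < 0 || inc$rho >= cup_radius)
      stop("inclusion lies outside the cup", call. = FALSE)
    if (inc$radius <= 0) stop("inclusion radius must be positive", call. = FALSE)
    if (!is.finite(Re(inc$amplitude)) || !is.finite(Im(inc$amplitude)))
      stop("inclusion amplitude must be finite", call. = FALSE)
    inc$amplitude <- as.complex(inc$amplitude)
    inc
  })
  structure(list(cup_radius = cup_radius,
                 inclusions = inclusions,
                 background_conductivity = background_conductivity),
            class = "mwi_phantom")
}
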