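# Microfluidic channel hydraulics and electrolyte screening.
#
# All constructors take the bench units a practitioner reads off the chip
# design and the buffer bottle (micrometres, microlitres per minute, molar)
# and convert ONCE to SI; every internal computation is SI, and accessors
# convert back at the boundary. This avoids the compounding of rounded
# intermediates that plagues back-of-envelope reproductions.

#' Rectangular microfluidic channel geometry
#'
#' @param width_um channel width in micrometres (> 0)
#' @param height_um channel height in micrometres (> 0)
#' @return an object of class `channel_geometry` with the cross-sectional
#'   area and perimeter precomputed in SI units
#' @examples
#' ch <- channel_geometry(4000, 1500)
#' hydraulic_diameter(ch)
#' @export
channel_geometry <- function(width_um, height_um) {
  stopifnot(is.numeric(width_um), is.numeric(height_um),
            length(width_um) == 1, length(height_um) == 1)
  if (!is.finite(width_um) || !is.finite(height_um) ||
      width_um <= 0 || height_um <= 0)
    stop("channel dimensions must be strictly positive and finite")
  w <- width_um * 1e-6
  h <- height_um * 1e-6
  structure(
    list(width = w, height = h, area = w * h, perimeter = 2 * (w + h)),
    class = "channel_geometry")
}

#' Carrier fluid and its imposed volumetric flow
#'
#' @param density_kg_m3 fluid density in kg/m^3 (water: 1000)
#' @param viscosity_pa_s dynamic viscosity in Pa s (water at 20 C: 0.001002)
#' @param flow_ul_min imposed volumetric flow rate in microlitres per minute
#' @return an object of class `fluid`
#' @export
fluid <- function(density_kg_m3 = 1000, viscosity_pa_s = 0.001002,
                  flow_ul_min = 80) {
  vals <- c(density_kg_m3, viscosity_pa_s, flow_ul_min)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("density, viscosity and flow rate must be strictly positive")
  structure(
    list(density = density_kg_m3, viscosity = viscosity_pa_s,
         volumetric_rate = flow_ul_min * 1e-9 / 60),  # m^3/s
    class = "fluid")
}

#' Aqueous electrolyte
#'
#' Defaults describe 0.01x phosphate-buffered saline; full-strength 1xPBS has
#' an ionic strength of about 0.150 M.
#'
#' @param ionic_strength_M ionic strength in molar (> 0)
#' @param rel_permittivity relative permittivity (>= 1; PBS is close to
#'   water, ~80)
#' @return an object of class `electrolyte`
#' @export
electrolyte <- function(ionic_strength_M = 0.0015, rel_permittivity = 80) {
  if (!is.finite(ionic_strength_M) || ionic_strength_M <= 0)
    stop("ionic strength must be strictly positive")
  if (!is.finite(rel_permittivity) || rel_permittivity < 1)
    stop("relative permittivity must be >= 1")
  structure(
    list(ionic_strength = ionic_strength_M,
         rel_permittivity = rel_permittivity),
    class = "electrolyte")
}

#' Hydraulic diameter of a rectangular duct
#'
#' D_H = 4 A / P with A the cross-sectional area and P the wetted perimeter;
#' symmetric in width and height, and equal to the side for a square duct.
#'
#' @param geometry a [channel_geometry()]
#' @return hydraulic diameter in micrometres
#' @export
hydraulic_diameter <- function(geometry) {
  stopifnot(inherits(geometry, "channel_geometry"))
  4 * geometry$area / geometry$perimeter * 1e6
}

#' Mean linear flow velocity
#'
#' u = u_V / A for plug flow through the full cross-section. Computed at
#' full precision; the bench shorthand "~220 um/s" for the reference device
#' is a two-significant-figure rounding of the value returned here.
#'
#' @param fl a [fluid()]
#' @param geometry a [channel_geometry()]
#' @return linear velocity in micrometres per second
#' @export
linear_velocity <- function(fl, geometry) {
  stopifnot(inherits(fl, "fluid"), inherits(geometry, "channel_geometry"))
  fl$volumetric_rate / geometry$area * 1e6
}

#' Channel Reynolds number
#'
#' Re = rho u D_H / mu, using the unrounded velocity and hydraulic diameter.
#' Values far below ~2000 indicate laminar flow.
#'
#' @inheritParams linear_velocity
#' @return dimensionless Reynolds number
#' @export
reynolds_number <- function(fl, geometry) {
  stopifnot(inherits(fl, "fluid"), inherits(geometry, "channel_geometry"))
  u <- fl$volumetric_rate / geometry$area              # m/s
  dh <- 4 * geometry$area / geometry$perimeter          # m
  fl$density * u * dh / fl$viscosity
}

#' Debye screening length of an aqueous electrolyte
#'
#' Uses the room-temperature aqueous approximation
#' lambda_D ~ 0.3 / sqrt(I) nanometres with I the ionic strength in molar,
#' so 0.150 M (1xPBS) gives ~0.77 nm and 0.0015 M (0.01xPBS) ~7.75 nm.
#'
#' @param el an [electrolyte()], or a bare ionic strength in M
#' @return Debye length in nanometres
#' @export
debye_length <- function(el) {
  i <- if (inherits(el, "electrolyte")) el$ionic_strength else el
  if (!is.numeric(i) || any(!is.finite(i)) || any(i <= 0))
    stop("ionic strength must be strictly positive")
  0.3 / sqrt(i)
}
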