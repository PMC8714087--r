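#' Geometry of a single capillary
#'
#' Capillary flow is modelled as a viscous red-cell core of radius
#' `r0 = 0.3 um + 0.8 r` surrounded by a plasma sleeve, so the radius must
#' be large enough (`r >= 1.5 um`) for the sleeve to be strictly interior.
#'
#' @param diameter Capillary diameter, micrometres.
#' @param length Capillary length, micrometres.
#' @param compartment `"nonGM"` for ordinary brain capillaries or `"GM"` for
#'   germinal-matrix capillaries.
#' @return An object of class `capillary_geometry` storing SI lengths.
#' @export
#' @examples
#' capillary_geometry(5.6, 600)
capillary_geometry <- function(diameter, length, compartment = c("nonGM", "GM")) {
  compartment <- match.arg(compartment)
  if (!is.finite(diameter) || diameter / 2 < 1.5)
    stop("capillary radius must be >= 1.5 um so the red-cell core (r0 = 0.3 + 0.8 r) ",
         "stays strictly inside the lumen", call. = FALSE)
  if (!is.finite(length) || length <= 0)
    stop("capillary length must be positive", call. = FALSE)
  structure(list(radius = um_to_m(diameter / 2),
                 length = um_to_m(length),
                 compartment = compartment),
            class = "capillary_geometry")
}

#' Constants of the two-phase capillary flow model
#'
#' @param mu_rbc Effective viscosity of the red-blood-cell core, Pa*s.
#' @param plasma_coeffs Coefficients `(k, a, b, c)` of the tube-hematocrit
#'   dependent plasma viscosity `mu_PL(H_T) = k * (a + b*H_T)/c` Pa*s.
#' @return An object of class `two_phase_constants`.
#' @export
two_phase_constants <- function(mu_rbc = 0.1,
                                plasma_coeffs = c(0.001, 16, 5, 15)) {
  k <- plasma_coeffs
  stopifnot(length(k) == 4, mu_rbc > 0)
  if (mu_rbc <= max(k[1] * (k[2] + k[3] * c(0, 1)) / k[4]))
    stop("red-cell core viscosity must exceed plasma viscosity at any tube hematocrit",
         call. = FALSE)
  structure(list(mu_rbc = mu_rbc, plasma_coeffs = k), class = "two_phase_constants")
}

#' Tube-hematocrit dependent plasma viscosity
#'
#' `mu_PL(H_T) = 0.001 * (16 + 5 H_T)/15` Pa*s by default: the effective
#' viscosity of the plasma phase rises mildly with the cell content of the
#' tube. Using this law inside both resistance endpoints gives the two-phase
#' resistance its slight curvature in `H_T`.
#'
#' @param h_t Tube hematocrit fraction in `[0, 1]`.
#' @param constants A [two_phase_constants()] object.
#' @return Viscosity in Pa*s.
#' @export
plasma_viscosity <- function(h_t, constants = two_phase_constants()) {
  if (any(!is.finite(h_t)) || any(h_t < 0) || any(h_t > 1))
    stop("tube hematocrit must be a fraction in [0, 1]", call. = FALSE)
  k <- constants$plasma_coeffs
  k[1] * (k[2] + k[3] * h_t) / k[4]
}

#' All-plasma (Poiseuille) capillary resistance
#'
#' The resistance the capillary would have if it carried plasma only:
#' `rho = 8 l mu_PL(H_T) / (pi r^4)`, the `H_T = 0` endpoint of the
#' two-phase interpolation.
#'
#' @param geom A [capillary_geometry()] object.
#' @param h_t Tube hematocrit fraction (enters through `mu_PL`).
#' @param constants A [two_phase_constants()] object.
#' @return Resistance in Pa*s/m^3.
#' @export
rho_plasma <- function(geom, h_t, constants = two_phase_constants()) {
  stopifnot(inherits(geom, "capillary_geometry"))
  8 * geom$length * plasma_viscosity(h_t, constants) / (pi * geom$radius^4)
}

#' Capillary resistance with a continuous red-cell core
#'
#' The `H_T = 1` endpoint of the two-phase model: a core of radius
#' `r0 = 0.3 um + 0.8 r` with viscosity `mu_RBC` inside a plasma annulus,
#' \deqn{\hat\rho = \frac{8 l}{\pi}\left[\frac{r^4 - r_0^4}{\mu_{PL}} +
#'   \frac{r_0^4}{\mu_{RBC}}\right]^{-1}.}
#' Always exceeds [rho_plasma()] because the core is more viscous.
#'
#' @inheritParams rho_plasma
#' @return Resistance in Pa*s/m^3.
#' @export
rho_hat_core <- function(geom, h_t, constants = two_phase_constants()) {
  stopifnot(inherits(geom, "capillary_geometry"))
  r <- geom$radius
  r0 <- um_to_m(0.3) + 0.8 * r
  if (r0 >= r)
    stop("red-cell core radius reaches the wall; capillary radius too small",
         call. = FALSE)
  mu_pl <- plasma_viscosity(h_t, constants)
  (8 * geom$length / pi) / ((r^4 - r0^4) / mu_pl + r0^4 / constants$mu_rbc)
}

#' Hydraulic resistance of a single capillary (two-phase model)
#'
#' Interpolates between the all-plasma and continuous-core endpoints with
#' the tube hematocrit: `RES = rho + (rho_hat - rho) * H_T`. Both endpoints
#' themselves depend on `H_T` through the plasma-viscosity law, so the
#' resistance is slightly convex in `H_T` rather than exactly linear.
#'
#' @inheritParams rho_plasma
#' @return Resistance in Pa*s/m^3.
#' @export
#' @examples
#' g <- capillary_geometry(5.6, 600)
#' capillary_resistance(g, tube_hematocrit(5.6, 0.45)) / 1e16  # ~5.16
capillary_resistance <- function(geom, h_t, constants = two_phase_constants()) {
  rho <- rho_plasma(geom, h_t, constants)
  rho + (rho_hat_core(geom, h_t, constants) - rho) * h_t
}
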