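#' Constants of the in-vivo blood rheology laws
#'
#' Bundles the empirical coefficients of the diameter-dependent apparent
#' viscosity law and of the Fahraeus tube-hematocrit relation. The defaults
#' are the published in-vivo values; any override is recorded in the
#' `modified` field so downstream provenance can report it.
#'
#' @param mu_plasma In-vivo plasma viscosity, Pa*s.
#' @param wall_offset Effective wall-exclusion offset, micrometres. The wall
#'   factor of the viscosity law is `(d/(d - wall_offset))^2`; the apparent
#'   viscosity is singular at `d = wall_offset`, so all diameters must exceed
#'   it.
#' @param fahraeus_coeffs Coefficients `(a, b, c, e)` of the tube-hematocrit
#'   relation `H_T/H_D = H_D + (1 - H_D) * (1 + a*exp(b*d) + c*exp(e*d))`.
#' @param visc45_coeffs Coefficients of the relative apparent viscosity at
#'   45% discharge hematocrit,
#'   `mu_0.45(d) = k1*exp(k2*d) + k3 + k4*exp(k5*d^k6)`.
#' @param c_coeffs Coefficients `(c1, c2, c3, c4)` of the shape exponent
#'   `C(d) = (c1 + exp(c2*d)) * (-1 + q) + q`, `q = 1/(1 + c3*d^c4)`.
#'
#' @return An object of class `rheology_constants`.
#' @export
#' @examples
#' rc <- rheology_constants()
#' apparent_viscosity(10, 0.45, rc)
rheology_constants <- function(mu_plasma = 0.001,
                               wall_offset = 1.1,
                               fahraeus_coeffs = c(1.7, -0.35, -0.6, -0.01),
                               visc45_coeffs = c(6, -0.085, 3.2, -2.44, -0.06, 0.645),
                               c_coeffs = c(0.8, -0.075, 1e-11, 12)) {
  stopifnot(mu_plasma > 0, wall_offset > 0,
            length(fahraeus_coeffs) == 4, length(visc45_coeffs) == 6,
            length(c_coeffs) == 4)
  defaults <- list(mu_plasma = 0.001, wall_offset = 1.1,
                   fahraeus_coeffs = c(1.7, -0.35, -0.6, -0.01),
                   visc45_coeffs = c(6, -0.085, 3.2, -2.44, -0.06, 0.645),
                   c_coeffs = c(0.8, -0.075, 1e-11, 12))
  obj <- list(mu_plasma = mu_plasma, wall_offset = wall_offset,
              fahraeus_coeffs = fahraeus_coeffs,
              visc45_coeffs = visc45_coeffs, c_coeffs = c_coeffs)
  obj$modified <- names(obj)[!vapply(names(obj), function(nm)
    isTRUE(all.equal(obj[[nm]], defaults[[nm]])), logical(1))]
  structure(obj, class = "rheology_constants")
}

#' Relative apparent viscosity at 45% discharge hematocrit
#'
#' The diameter-dependent relative (plasma = 1) apparent blood viscosity at
#' the reference discharge hematocrit of 45%. It falls steeply below ~300 um
#' (Fahraeus-Lindqvist effect) and tends to a plateau in wide tubes.
#'
#' @param d Vessel diameter(s), micrometres. Must exceed the wall offset.
#' @param constants A [rheology_constants()] object.
#' @return Dimensionless relative viscosity, same length as `d`.
#' @export
relative_viscosity_45 <- function(d, constants = rheology_constants()) {
  if (any(!is.finite(d)) || any(d <= constants$wall_offset))
    stop("diameter must exceed the wall offset (", constants$wall_offset,
         " um): the viscosity law is singular at d = wall offset", call. = FALSE)
  k <- constants$visc45_coeffs
  k[1] * exp(k[2] * d) + k[3] + k[4] * exp(k[5] * d^k[6])
}

#' Shape exponent of the hematocrit dependence
#'
#' The exponent `C(d)` controlling how the apparent viscosity departs from
#' its 45%-hematocrit reference as the discharge hematocrit varies. The
#' `d^12` terms are evaluated in log space so diameters up to 1e4 um (and far
#' beyond) cannot overflow.
#'
#' @inheritParams relative_viscosity_45
#' @return Dimensionless exponent, same length as `d`.
#' @export
shape_exponent_c <- function(d, constants = rheology_constants()) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diameter must be positive", call. = FALSE)
  cc <- constants$c_coeffs
  # q = 1/(1 + c3 * d^c4), computed as 1/(1 + exp(t)) with t = log(c3) + c4*log(d)
  t <- log(cc[3]) + cc[4] * log(d)
  q <- ifelse(t > 300, 0, 1 / (1 + exp(t)))
  (cc[1] + exp(cc[2] * d)) * (-1 + q) + q
}

#' Apparent blood viscosity (in-vivo law)
#'
#' Absolute apparent viscosity of blood flowing in a vessel of diameter `d`
#' at discharge hematocrit `h_d`, from the phenomenological in-vivo law:
#' \deqn{\mu_a = \mu_{PL}\left[1 + (\mu_{0.45} - 1)\,
#'   \frac{(1-H_D)^C - 1}{(1-0.45)^C - 1}\, W\right] W,\qquad
#'   W = \left(\frac{d}{d - \delta}\right)^2}
#' with wall offset \eqn{\delta}. At `h_d = 0.45` the hematocrit correction
#' factor is exactly 1 regardless of `C`.
#'
#' @param d Vessel diameter(s), micrometres (`d > wall_offset`).
#' @param h_d Discharge hematocrit as a fraction, `0 <= h_d < 1`. Recycled
#'   against `d`.
#' @param constants A [rheology_constants()] object.
#' @return Apparent viscosity in Pa*s.
#' @export
#' @examples
#' apparent_viscosity(10, 0.45)   # 5.87e-3 Pa*s
#' apparent_viscosity(500, 0.60)  # 4.76e-3 Pa*s
apparent_viscosity <- function(d, h_d, constants = rheology_constants()) {
  if (any(!is.finite(h_d)) || any(h_d < 0) || any(h_d >= 1))
    stop("discharge hematocrit must be a fraction in [0, 1)", call. = FALSE)
  if (any(!is.finite(d)) || any(d <= constants$wall_offset))
    stop("diameter must exceed the wall offset (", constants$wall_offset,
         " um): the viscosity law is singular at d = wall offset", call. = FALSE)
  W <- (d / (d - constants$wall_offset))^2
  C <- shape_exponent_c(d, constants)
  corr <- ((1 - h_d)^C - 1) / ((1 - 0.45)^C - 1)
  constants$mu_plasma * (1 + (relative_viscosity_45(d, constants) - 1) * corr * W) * W
}

#' Tube hematocrit from the Fahraeus relation
#'
#' In narrow tubes red blood cells travel faster than the bulk, so the
#' instantaneous (tube) hematocrit `H_T` is lower than the discharge
#' hematocrit `H_D` (Fahraeus effect). The reduction follows
#' \deqn{H_T/H_D = H_D + (1 - H_D)(1 + 1.7 e^{-0.35 d} - 0.6 e^{-0.01 d}).}
#' The effect vanishes in wide tubes (`H_T -> H_D`).
#'
#' @param d Tube diameter(s), micrometres, `d > 0`.
#' @param h_d Discharge hematocrit fraction in `[0, 1]`.
#' @param constants A [rheology_constants()] object.
#' @return Tube hematocrit fraction.
#' @export
#' @examples
#' tube_hematocrit(5.6, 0.45)  # 0.369
tube_hematocrit <- function(d, h_d, constants = rheology_constants()) {
  if (any(!is.finite(h_d)) || any(h_d < 0) || any(h_d > 1))
    stop("discharge hematocrit must be a fraction in [0, 1]", call. = FALSE)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("diameter must be positive", call. = FALSE)
  f <- constants$fahraeus_coeffs
  h_d * (h_d + (1 - h_d) * (1 + f[1] * exp(f[2] * d) + f[3] * exp(f[4] * d)))
}

#' Hematocrit bookkeeping for one evaluation
#'
#' Records the systemic hematocrit together with the discharge hematocrit
#' (set equal to the systemic value, following the clinical identification
#' `H_D = H_SYS`) and, optionally, the tube hematocrit derived at a given
#' capillary diameter.
#'
#' @param h_sys Systemic hematocrit fraction in `[0, 1]`.
#' @param source One of `"measured"`, `"assumed"`, `"derived"`.
#' @param diameter Optional capillary diameter (um) at which to derive `h_t`.
#' @param constants A [rheology_constants()] object.
#' @return An object of class `hematocrit_set` with fields `h_sys`, `h_d`,
#'   `h_t` (possibly `NA`) and `source`.
#' @export
hematocrit_set <- function(h_sys, source = c("measured", "assumed", "derived"),
                           diameter = NULL, constants = rheology_constants()) {
  source <- match.arg(source)
  if (!is.finite(h_sys) || h_sys < 0 || h_sys > 1)
    stop("systemic hematocrit must be a fraction in [0, 1]", call. = FALSE)
  h_t <- if (is.null(diameter)) NA_real_ else tube_hematocrit(diameter, h_sys, constants)
  structure(list(h_sys = h_sys, h_d = h_sys, h_t = h_t,
                 derived_at_um = if (is.null(diameter)) NA_real_ else diameter,
                 source = source),
            class = "hematocrit_set")
}

#' @export
print.hematocrit_set <- function(x, ...) {
  cat(sprintf("hematocrit_set: H_SYS = H_D = %.1f%% (%s)", 100 * x$h_sys, x$source))
  if (!is.na(x$h_t))
    cat(sprintf(", H_T = %.1f%% at d = %.2f um", 100 * x$h_t, x$derived_at_um))
  cat("\n")
  invisible(x)
}
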