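# Centralized unit conversions. All internal arithmetic is SI:
# lengths in m, pressures in Pa, viscosities in Pa*s, resistances in Pa*s/m^3,
# hematocrit as a volume fraction in [0, 1]. Micrometres, mmHg and percent
# exist only at user/file boundaries and are converted through these helpers,
# so that a um^4 -> m^4 slip (24 orders of magnitude) cannot happen silently.

#' @keywords internal
um_to_m <- function(x) x * 1e-6

#' @keywords internal
mmHg_to_Pa <- function(x) x * 133.322

#' @keywords internal
pct_to_frac <- function(x) x / 100

#' @keywords internal
frac_to_pct <- function(x) x * 100

# m^3/s -> ml/min
#' @keywords internal
q_si_to_ml_min <- function(q) q * 1e6 * 60
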