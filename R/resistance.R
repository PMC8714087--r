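#' Evaluation conditions for one model run
#'
#' @param gestational_age Weeks of gestation.
#' @param map_pressure Mean arterial pressure, mmHg.
#' @param h_sys Systemic hematocrit as a fraction in `[0, 1)`; equated to the
#'   discharge hematocrit in the viscosity law.
#' @param icp Intracranial pressure, mmHg (default 5, the constant value used
#'   for preterm infants in whom it cannot be measured).
#' @param birth_weight Optional birth weight, g (used to estimate brain
#'   weight when `brain_weight` is absent).
#' @param brain_weight Optional brain weight, g; when absent it is estimated
#'   from `gestational_age` (or `birth_weight`) via [estimate_brain_weight()].
#' @param viscosity_mode `"hematocrit_dependent"` (in-vivo law plus two-phase
#'   capillaries) or `"constant_003"` (legacy constant viscosity 0.003 Pa*s
#'   in every vessel, hematocrit-invariant).
#' @return An object of class `run_conditions`.
#' @export
run_conditions <- function(gestational_age, map_pressure, h_sys,
                           icp = 5, birth_weight = NULL, brain_weight = NULL,
                           viscosity_mode = c("hematocrit_dependent", "constant_003")) {
  viscosity_mode <- match.arg(viscosity_mode)
  if (!is.finite(map_pressure) || !is.finite(icp) || map_pressure <= icp)
    stop("non-positive perfusion pressure: MAP must exceed intracranial pressure",
         call. = FALSE)
  if (!is.finite(h_sys) || h_sys < 0 || h_sys >= 1)
    stop("systemic hematocrit must be a fraction in [0, 1)", call. = FALSE)
  structure(list(gestational_age = gestational_age,
                 map_pressure = map_pressure, icp = icp, h_sys = h_sys,
                 birth_weight = birth_weight, brain_weight = brain_weight,
                 viscosity_mode = viscosity_mode),
            class = "run_conditions")
}

#' @keywords internal
resolve_brain_weight <- function(conditions, config) {
  if (!is.null(conditions$brain_weight)) return(conditions$brain_weight)
  estimate_brain_weight(birth_weight = conditions$birth_weight,
                        gestational_age = conditions$gestational_age,
                        config = config)
}

# Poiseuille resistance of one vessel, SI. d, l in micrometres.
#' @keywords internal
poiseuille_resistance <- function(d_um, l_um, mu) {
  128 * mu * um_to_m(l_um) / (pi * um_to_m(d_um)^4)
}

#' Assemble the resistance of the full vascular tree
#'
#' Scales the morphometry to the subject's brain weight, computes the
#' resistance of a single vessel on every level (Poiseuille flow with the
#' diameter- and hematocrit-dependent apparent viscosity for the
#' non-capillary levels; the two-phase model with the Fahraeus tube
#' hematocrit for the GM and non-GM capillary branches of level 10), and
#' combines them by Kirchhoff's laws: parallel within a level
#' (`RES_j^level = RES_j / m_j`, GM harmonic with non-GM on level 10) and
#' series across the 19 levels.
#'
#' @param config A `morphometry_config` (reference geometry).
#' @param conditions A [run_conditions()] object.
#' @param diameter_modifier Optional vasoreactivity hook: a function
#'   `(diameter_um, conditions) -> diameter_um` applied to the non-capillary
#'   diameters before resistance evaluation (e.g. MAP- or pCO2-driven
#'   vasodilation). Default `NULL` leaves diameters unchanged.
#' @return An object of class `resistance_breakdown` with elements
#'   `levels` (per-level table: count, geometry, per-vessel and per-level
#'   resistance in Pa*s/m^3), `gm_level` (capillary branch detail), `total`,
#'   `brain_weight_g` and `conditions`.
#' @export
#' @examples
#' rb <- assemble_resistances(default_morphometry(),
#'                            run_conditions(25, 40, 0.45))
#' rb$total / 1e8
assemble_resistances <- function(config, conditions, diameter_modifier = NULL) {
  stopifnot(inherits(config, "morphometry_config"),
            inherits(conditions, "run_conditions"))
  bw <- resolve_brain_weight(conditions, config)
  scaled <- scale_levels(config, bw)
  legacy <- conditions$viscosity_mode == "constant_003"
  h <- conditions$h_sys
  rc <- config$rheology
  tp <- config$two_phase
  lv <- scaled$levels
  noncap <- lv$j != 10
  if (!is.null(diameter_modifier)) {
    d_new <- diameter_modifier(lv$diameter_um[noncap], conditions)
    if (any(!is.finite(d_new)) || any(d_new <= rc$wall_offset))
      stop("diameter_modifier produced diameters at or below the wall offset",
           call. = FALSE)
    lv$diameter_um[noncap] <- d_new
  }

  mu <- if (legacy) rep(config$legacy_viscosity, sum(noncap))
        else apparent_viscosity(lv$diameter_um[noncap], h, rc)
  res_vessel <- rep(NA_real_, nrow(lv))
  res_vessel[noncap] <- poiseuille_resistance(lv$diameter_um[noncap],
                                              lv$length_um[noncap], mu)
  res_level <- rep(NA_real_, nrow(lv))
  res_level[noncap] <- res_vessel[noncap] / lv$count[noncap]

  # capillary level: GM branch in parallel with non-GM branch
  gm <- scaled$gm
  m_gm <- gm_vessel_count(conditions$gestational_age, bw, scaled)
  m_ngm <- gm$ngm_count
  geo_ngm <- capillary_geometry(gm$ngm_diameter_um, gm$ngm_length_um, "nonGM")
  geo_gm <- capillary_geometry(gm$gm_diameter_um, gm$gm_length_um, "GM")
  if (legacy) {
    res_ngm <- poiseuille_resistance(gm$ngm_diameter_um, gm$ngm_length_um,
                                     config$legacy_viscosity)
    res_gm <- poiseuille_resistance(gm$gm_diameter_um, gm$gm_length_um,
                                    config$legacy_viscosity)
  } else {
    ht_ngm <- tube_hematocrit(gm$ngm_diameter_um, h, rc)
    ht_gm <- if (isTRUE(gm$shared_tube_hematocrit)) ht_ngm
             else tube_hematocrit(gm$gm_diameter_um, h, rc)
    res_ngm <- capillary_resistance(geo_ngm, ht_ngm, tp)
    res_gm <- capillary_resistance(geo_gm, ht_gm, tp)
  }
  cond_cap <- m_ngm / res_ngm + if (m_gm > 0) m_gm / res_gm else 0
  res_level[lv$j == 10] <- 1 / cond_cap
  res_vessel[lv$j == 10] <- res_ngm
  lv$count[lv$j == 10] <- m_ngm + m_gm

  structure(list(
    levels = data.frame(j = lv$j, name = lv$name, count = lv$count,
                        diameter_um = lv$diameter_um, length_um = lv$length_um,
                        res_vessel = res_vessel, res_level = res_level),
    gm_level = list(res_gm_vessel = res_gm, res_ngm_vessel = res_ngm,
                    m_gm = m_gm, m_ngm = m_ngm,
                    res_gm_level = if (m_gm > 0) res_gm / m_gm else Inf,
                    res_ngm_level = res_ngm / m_ngm,
                    res_level = 1 / cond_cap),
    total = sum(res_level),
    brain_weight_g = bw,
    conditions = conditions), class = "resistance_breakdown")
}

#' @export
print.resistance_breakdown <- function(x, ...) {
  cat(sprintf("resistance_breakdown: total RES = %.3g Pa*s/m^3 (%.1f x 1e8)\n",
              x$total, x$total / 1e8))
  cat(sprintf("  GA %.1f wk, brain %.1f g, H_SYS %.0f%%, mode %s\n",
              x$conditions$gestational_age, x$brain_weight_g,
              100 * x$conditions$h_sys, x$conditions$viscosity_mode))
  df <- x$levels
  df$res_level_1e8 <- round(df$res_level / 1e8, 2)
  print(df[, c("j", "name", "count", "diameter_um", "res_level_1e8")],
        row.names = FALSE)
  invisible(x)
}

#' Export a resistance breakdown as a flat table
#'
#' One row per level with count, geometry and resistances, suitable for
#' writing to CSV for audit.
#'
#' @param breakdown A `resistance_breakdown`.
#' @return A `tibble`.
#' @export
breakdown_table <- function(breakdown) {
  stopifnot(inherits(breakdown, "resistance_breakdown"))
  tibble::as_tibble(breakdown$levels)
}
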