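#' Cerebral blood flow from assembled resistances
#'
#' Applies Kirchhoff's law `CBF = (MAP - P_ic)/RES` with the pressure head
#' converted from mmHg to Pa, normalizes the volumetric flow per 100 g of
#' brain tissue, and attaches the per-vessel flows
#' `CBF_j = CBF * RES_j^level / RES_j = CBF / m_j`.
#'
#' @param conditions A [run_conditions()] object.
#' @param config A `morphometry_config`.
#' @return An object of class `cbf_result`: `cbf_global` (ml/min/100 g),
#'   `q_total` (m^3/s), `per_vessel_flow` (per-level single-vessel CBF,
#'   ml/min/100 g) and the `resistance_breakdown`.
#' @export
#' @examples
#' res <- compute_cbf(run_conditions(25, 40, 0.45), default_morphometry())
#' res$cbf_global
compute_cbf <- function(conditions, config = default_morphometry()) {
  breakdown <- assemble_resistances(config, conditions)
  dp <- mmHg_to_Pa(conditions$map_pressure - conditions$icp)
  q <- dp / breakdown$total
  cbf <- q_si_to_ml_min(q) / (breakdown$brain_weight_g / 100)
  per_vessel <- cbf / breakdown$levels$count
  names(per_vessel) <- breakdown$levels$name
  structure(list(cbf_global = cbf, q_total = q,
                 per_vessel_flow = per_vessel,
                 cbf_capillary_ngm = cbf / breakdown$gm_level$m_ngm,
                 breakdown = breakdown),
            class = "cbf_result")
}

#' @export
print.cbf_result <- function(x, ...) {
  b <- x$breakdown
  cat(sprintf("CBF = %.2f ml/min/100 g  (GA %.1f wk, MAP %.1f mmHg, H_SYS %.0f%%)\n",
              x$cbf_global, b$conditions$gestational_age,
              b$conditions$map_pressure, 100 * b$conditions$h_sys))
  cat(sprintf("  total RES = %.1f x 1e8 Pa*s/m^3, brain %.1f g\n",
              b$total / 1e8, b$brain_weight_g))
  cat(sprintf("  single non-GM capillary CBF = %.2f x 1e-6 ml/min/100 g\n",
              1e6 * x$cbf_capillary_ngm))
  invisible(x)
}

#' Sweep total resistance and CBF over hematocrit and gestational age
#'
#' Evaluates the full model on the grid `ga_grid x h_sys_grid` and, when
#' `include_reference = TRUE`, adds a hematocrit-invariant constant-viscosity
#' (0.003 Pa*s) reference row per gestational age.
#'
#' @param config A `morphometry_config`.
#' @param h_sys_grid Systemic hematocrit fractions.
#' @param ga_grid Gestational ages, weeks.
#' @param map_pressure MAP in mmHg: a single value, or one per `ga_grid`
#'   entry.
#' @param icp Intracranial pressure, mmHg.
#' @param include_reference Add the legacy constant-viscosity rows.
#' @return A long-format `tibble` with columns `ga_weeks`, `h_sys`,
#'   `viscosity_mode`, `res_total`, `cbf`.
#' @export
sweep_hematocrit_ga <- function(config = default_morphometry(),
                                h_sys_grid, ga_grid, map_pressure, icp = 5,
                                include_reference = TRUE) {
  stopifnot(length(h_sys_grid) >= 1, length(ga_grid) >= 1)
  map <- rep_len(map_pressure, length(ga_grid))
  rows <- list()
  for (i in seq_along(ga_grid)) {
    for (h in h_sys_grid) {
      r <- compute_cbf(run_conditions(ga_grid[i], map[i], h, icp = icp), config)
      rows[[length(rows) + 1]] <- tibble::tibble(
        ga_weeks = ga_grid[i], h_sys = h, viscosity_mode = "hematocrit_dependent",
        res_total = r$breakdown$total, cbf = r$cbf_global)
    }
    if (include_reference) {
      r <- compute_cbf(run_conditions(ga_grid[i], map[i], 0.45, icp = icp,
                                      viscosity_mode = "constant_003"), config)
      rows[[length(rows) + 1]] <- tibble::tibble(
        ga_weeks = ga_grid[i], h_sys = NA_real_, viscosity_mode = "constant_003",
        res_total = r$breakdown$total, cbf = r$cbf_global)
    }
  }
  dplyr::bind_rows(rows)
}

#' Apparent-viscosity profile over vessel diameter
#'
#' Tabulates the in-vivo apparent viscosity over a diameter grid for one or
#' more systemic hematocrit values (the classic viscosity-vs-diameter
#' curves).
#'
#' @param h_sys_values Hematocrit fractions.
#' @param d_grid Diameters, micrometres (each must exceed the wall offset).
#' @param constants A [rheology_constants()] object.
#' @return A `tibble` with columns `diameter_um`, `h_sys`, `mu_a` (Pa*s).
#' @export
viscosity_diameter_profile <- function(h_sys_values, d_grid,
                                       constants = rheology_constants()) {
  grid <- expand.grid(diameter_um = d_grid, h_sys = h_sys_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mu_a <- apparent_viscosity(grid$diameter_um, grid$h_sys, constants)
  tibble::as_tibble(grid)
}

# Fast vectorized path used by the cohort pipeline: total resistance of a
# brain-weight scaled tree over a vector of hematocrit values. Avoids
# re-validating and re-scaling the config per time point.
#' @keywords internal
resistance_curve <- function(config, gestational_age, brain_weight, h_vec) {
  scaled <- scale_levels(config, brain_weight)
  lv <- scaled$levels
  noncap <- lv$j != 10
  d <- lv$diameter_um[noncap]; l <- lv$length_um[noncap]; m <- lv$count[noncap]
  rc <- config$rheology; tp <- config$two_phase
  nd <- length(d); nh <- length(h_vec)
  # (levels x h) apparent viscosities in one vectorized call
  mu <- matrix(apparent_viscosity(rep(d, nh), rep(h_vec, each = nd), rc),
               nrow = nd)
  geom_fac <- 128 * um_to_m(l) / (pi * um_to_m(d)^4 * m)
  noncap_tot <- colSums(mu * geom_fac)

  gm <- scaled$gm
  m_gm <- gm_vessel_count(gestational_age, brain_weight, scaled)
  geo_ngm <- capillary_geometry(gm$ngm_diameter_um, gm$ngm_length_um, "nonGM")
  res_ngm <- capillary_resistance(
    geo_ngm, tube_hematocrit(gm$ngm_diameter_um, h_vec, rc), tp)
  cond <- gm$ngm_count / res_ngm
  if (m_gm > 0) {
    geo_gm <- capillary_geometry(gm$gm_diameter_um, gm$gm_length_um, "GM")
    res_gm <- capillary_resistance(
      geo_gm, tube_hematocrit(gm$gm_diameter_um, h_vec, rc), tp)
    cond <- cond + m_gm / res_gm
  }
  list(total = noncap_tot + 1 / cond, m_ngm = gm$ngm_count)
}
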