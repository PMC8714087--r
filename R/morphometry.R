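#' Load and validate a morphometry configuration
#'
#' The morphometry configuration is the model's single source of anatomical
#' truth: the 19 vascular levels connected in series (counts, diameters,
#' lengths at a reference brain weight), the germinal-matrix (GM) and non-GM
#' capillary compartments of level 10, the brain-weight scaling rule and the
#' rheological constants. Accepts a JSON file, a YAML file (extension
#' `.yml`/`.yaml`, requires the yaml package) or an already-parsed list.
#'
#' @param x Path to a JSON/YAML document, or a list with the same structure
#'   as the shipped default (see `system.file("extdata",
#'   "morphometry_default.json", package = "cerebroflow")`).
#' @return A validated object of class `morphometry_config`.
#' @seealso [default_morphometry()], [write_morphometry()], [scale_levels()]
#' @export
load_morphometry <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("morphometry file not found: ", x, call. = FALSE)
    raw <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML morphometry requires the 'yaml' package", call. = FALSE)
      yaml::read_yaml(x)
    } else {
      jsonlite::read_json(x, simplifyVector = TRUE)
    }
  } else if (is.list(x)) {
    raw <- x
  } else stop("morphometry input must be a file path or a list", call. = FALSE)
  validate_morphometry(raw)
}

#' The shipped calibrated morphometry
#'
#' Loads the default 19-level configuration calibrated against the
#' 25-week-gestation reference (see the package vignette for the calibration
#' targets and procedure).
#'
#' @return A `morphometry_config` object.
#' @export
default_morphometry <- function() {
  load_morphometry(system.file("extdata", "morphometry_default.json",
                               package = "cerebroflow", mustWork = TRUE))
}

# structural + invariant checks; errors name the offending key
#' @keywords internal
validate_morphometry <- function(raw) {
  need <- c("reference_brain_weight_g", "scaling_exponents", "brain_weight_table",
            "levels", "gm")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("morphometry config is missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lv <- as.data.frame(raw$levels)
  for (col in c("j", "name", "compartment"))
    if (is.null(lv[[col]]))
      stop("morphometry levels: missing column 'levels$", col, "'", call. = FALSE)
  if (anyDuplicated(lv$j))
    stop("morphometry levels: duplicate level index j = ",
         lv$j[duplicated(lv$j)][1], call. = FALSE)
  missing_j <- setdiff(1:19, lv$j)
  if (length(missing_j) || nrow(lv) != 19)
    stop("morphometry levels: expected indices 1..19 exactly once; missing j = ",
         paste(missing_j, collapse = ", "), call. = FALSE)
  lv <- lv[order(lv$j), ]
  if (lv$compartment[lv$j == 10] != "capillary")
    stop("morphometry levels: level 10 must have compartment = 'capillary' ",
         "(found '", lv$compartment[lv$j == 10], "')", call. = FALSE)
  ok <- lv$j != 10
  if (any(!is.finite(lv$count[ok]) | lv$count[ok] < 1))
    stop("morphometry levels: count must be >= 1 for level j = ",
         lv$j[ok][which(!(lv$count[ok] >= 1))[1]], call. = FALSE)
  if (any(!is.finite(lv$diameter_um[ok]) | lv$diameter_um[ok] <= 0) ||
      any(!is.finite(lv$length_um[ok]) | lv$length_um[ok] <= 0))
    stop("morphometry levels: diameter_um and length_um must be positive for ",
         "all non-capillary levels", call. = FALSE)

  gm <- raw$gm
  for (key in c("gm_diameter_um", "gm_length_um", "ngm_diameter_um",
                "ngm_length_um", "gm_count", "ngm_count"))
    if (is.null(gm[[key]]))
      stop("morphometry config: missing key 'gm$", key, "'", call. = FALSE)
  if (gm$ngm_count <= 0)
    stop("morphometry config: gm$ngm_count must be positive", call. = FALSE)
  if (gm$gm_count < 0)
    stop("morphometry config: gm$gm_count must be non-negative", call. = FALSE)
  if (gm$gm_diameter_um <= gm$ngm_diameter_um)
    stop("morphometry config: GM capillaries must have larger diameter than ",
         "non-GM ones (gm$gm_diameter_um <= gm$ngm_diameter_um)", call. = FALSE)
  if (is.null(gm$involution_onset_wk)) gm$involution_onset_wk <- 25
  if (is.null(gm$involution_complete_wk)) gm$involution_complete_wk <- 32
  if (is.null(gm$shared_tube_hematocrit)) gm$shared_tube_hematocrit <- FALSE

  bw <- raw$brain_weight_table
  if (is.null(bw$ga_weeks) || is.null(bw$weight_g) ||
      length(bw$ga_weeks) != length(bw$weight_g))
    stop("morphometry config: brain_weight_table needs parallel 'ga_weeks' and ",
         "'weight_g' vectors", call. = FALSE)
  if (is.unsorted(bw$ga_weeks, strictly = TRUE) || is.unsorted(bw$weight_g))
    stop("morphometry config: brain_weight_table must be increasing in ga_weeks ",
         "and non-decreasing in weight_g", call. = FALSE)

  se <- raw$scaling_exponents
  for (key in c("count", "length", "diameter"))
    if (is.null(se[[key]]))
      stop("morphometry config: missing key 'scaling_exponents$", key, "'",
           call. = FALSE)

  rh <- raw$rheology
  rheo <- rheology_constants(
    mu_plasma = if (!is.null(rh$mu_plasma_Pa_s)) rh$mu_plasma_Pa_s else 0.001,
    wall_offset = if (!is.null(rh$wall_offset_um)) rh$wall_offset_um else 1.1)
  tp <- raw$two_phase
  twop <- two_phase_constants(
    mu_rbc = if (!is.null(tp$mu_rbc_Pa_s)) tp$mu_rbc_Pa_s else 0.1)
  if (any(lv$diameter_um[ok] <= rheo$wall_offset))
    stop("morphometry levels: non-capillary diameters must exceed the wall ",
         "offset (", rheo$wall_offset, " um)", call. = FALSE)

  structure(list(
    schema_version = if (!is.null(raw$schema_version)) raw$schema_version else "1.0",
    provenance = if (!is.null(raw$provenance)) raw$provenance else "",
    reference_brain_weight_g = raw$reference_brain_weight_g,
    scaling_exponents = se[c("count", "length", "diameter")],
    brain_weight_table = bw[c("ga_weeks", "weight_g")],
    birth_weight_allometry = raw$birth_weight_allometry,
    levels = lv[, c("j", "name", "count", "diameter_um", "length_um", "compartment")],
    gm = gm,
    rheology = rheo,
    two_phase = twop,
    legacy_viscosity = 0.003
  ), class = "morphometry_config")
}

#' Serialize a morphometry configuration
#'
#' Writes JSON that [load_morphometry()] reads back to an identical
#' configuration (round-trip identity).
#'
#' @param config A `morphometry_config`.
#' @param path Output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(config, path) {
  stopifnot(inherits(config, "morphometry_config"))
  out <- list(
    schema_version = config$schema_version,
    provenance = config$provenance,
    reference_brain_weight_g = config$reference_brain_weight_g,
    scaling_exponents = config$scaling_exponents,
    brain_weight_table = config$brain_weight_table,
    birth_weight_allometry = config$birth_weight_allometry,
    levels = config$levels,
    gm = config$gm,
    rheology = list(mu_plasma_Pa_s = config$rheology$mu_plasma,
                    wall_offset_um = config$rheology$wall_offset),
    two_phase = list(mu_rbc_Pa_s = config$two_phase$mu_rbc))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.morphometry_config <- function(x, ...) {
  cat("morphometry_config:", nrow(x$levels), "vascular levels,",
      "reference brain weight", x$reference_brain_weight_g, "g\n")
  cat(sprintf("  GM capillaries: d = %.2f um, n = %.3g (involution %g-%g wk)\n",
              x$gm$gm_diameter_um, x$gm$gm_count,
              x$gm$involution_onset_wk, x$gm$involution_complete_wk))
  cat(sprintf("  non-GM capillaries: d = %.2f um, n = %.3g\n",
              x$gm$ngm_diameter_um, x$gm$ngm_count))
  invisible(x)
}

#' Estimate brain weight from birth weight and/or gestational age
#'
#' Brain weight drives the scaling of the vascular tree. When the
#' gestational age is supplied, the configured gestational-age table is
#' interpolated; otherwise an allometric relation on birth weight is used.
#' Inputs outside the supported range (gestational age 22-36 weeks, birth
#' weight 200-2500 g) are clamped with a warning.
#'
#' @param birth_weight Birth weight in grams, or `NULL`.
#' @param gestational_age Gestational age in weeks, or `NULL`.
#' @param config A `morphometry_config`.
#' @return Brain weight in grams (vectorized over the supplied argument).
#' @export
estimate_brain_weight <- function(birth_weight = NULL, gestational_age = NULL,
                                  config = default_morphometry()) {
  if (is.null(birth_weight) && is.null(gestational_age))
    stop("need birth_weight and/or gestational_age", call. = FALSE)
  if (!is.null(gestational_age)) {
    ga <- gestational_age
    if (any(ga < 22 | ga > 36)) {
      warning("gestational age outside 22-36 weeks; clamped", call. = FALSE)
      ga <- pmin(pmax(ga, 22), 36)
    }
    tb <- config$brain_weight_table
    stats::approx(tb$ga_weeks, tb$weight_g, xout = ga, rule = 2)$y
  } else {
    bw <- birth_weight
    if (any(bw < 200 | bw > 2500)) {
      warning("birth weight outside 200-2500 g; clamped", call. = FALSE)
      bw <- pmin(pmax(bw, 200), 2500)
    }
    al <- config$birth_weight_allometry
    al$coef * bw^al$exponent
  }
}

#' Scale the vascular tree to a subject's brain weight
#'
#' Each level's vessel count, length and diameter are multiplied by
#' `(BW/BW_ref)^alpha` with the configured exponents (defaults: counts grow
#' linearly with brain weight, geometry fixed). The capillary compartment
#' counts scale with the count exponent as well. Counts are floored at 1 so
#' the series circuit always has at least one vessel per level.
#'
#' @param config A `morphometry_config`.
#' @param brain_weight Target brain weight, g.
#' @return A new `morphometry_config` scaled to `brain_weight`.
#' @export
scale_levels <- function(config, brain_weight) {
  stopifnot(inherits(config, "morphometry_config"), brain_weight > 0)
  ratio <- brain_weight / config$reference_brain_weight_g
  e <- config$scaling_exponents
  out <- config
  ok <- out$levels$j != 10
  out$levels$count[ok] <- pmax(1, out$levels$count[ok] * ratio^e$count)
  out$levels$length_um[ok] <- out$levels$length_um[ok] * ratio^e$length
  out$levels$diameter_um[ok] <- out$levels$diameter_um[ok] * ratio^e$diameter
  out$gm$ngm_count <- max(1, out$gm$ngm_count * ratio^e$count)
  out$gm$gm_count <- out$gm$gm_count * ratio^e$count
  out$reference_brain_weight_g <- brain_weight
  out
}

#' Number of germinal-matrix capillaries
#'
#' The germinal matrix is a transient structure: its capillary count holds
#' its (brain-weight scaled) reference value up to the involution onset,
#' declines linearly, and reaches zero at the configured involution age
#' (default 32 weeks), after which the capillary level consists of non-GM
#' vessels only.
#'
#' @param gestational_age Weeks of gestation.
#' @param brain_weight Brain weight, g.
#' @param config A `morphometry_config`.
#' @return Non-negative GM capillary count (0 once involuted).
#' @export
gm_vessel_count <- function(gestational_age, brain_weight,
                            config = default_morphometry()) {
  gm <- config$gm
  onset <- gm$involution_onset_wk
  done <- gm$involution_complete_wk
  ramp <- pmin(1, pmax(0, (done - gestational_age) / (done - onset)))
  e <- config$scaling_exponents$count
  gm$gm_count * ramp * (brain_weight / config$reference_brain_weight_g)^e
}
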