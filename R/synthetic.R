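# truncated-normal draws by inverse-CDF; a, b on the same scale as mean/sd
#' @keywords internal
rtruncnorm_ <- function(n, mean, sd, a, b) {
  if (all(sd <= 0)) return(rep(mean, length.out = n))
  lo <- stats::pnorm(a, mean, sd); hi <- stats::pnorm(b, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the published cohort structure: 254 infants split
#' 118 control / 136 affected, IVH grade counts 38/42/48/8, gestational age
#' and birth weight distributions, group-specific hematocrit means
#' (45.14 ± 7.92 control vs 41.41 ± 7.48 affected, percent), and the
#' monitoring schedule (10 days for controls; 7 days before to 3 days after
#' the hemorrhage for affected infants). Group labels are assigned first and
#' hematocrit drawn per group: the generator encodes the observational
#' design, not a causal hematocrit-to-IVH mechanism.
#'
#' @param n_total,n_control Cohort and control-group sizes.
#' @param grade_counts Named counts for IVH grades I-IV; must sum to
#'   `n_total - n_control`.
#' @param ga_mean_sd_control,ga_mean_sd_affected Gestational age mean/SD,
#'   weeks (truncated to `ga_range`).
#' @param ga_range Truncation bounds for gestational age, weeks.
#' @param bw_anchor_g,bw_ga_slope,bw_resid_sd,bw_range Birth weight model:
#'   `bw = anchor + slope * (GA - 26.46) + N(0, resid_sd)`, truncated.
#' @param hct_control_mean_sd,hct_affected_mean_sd Between-patient hematocrit
#'   mean/SD per group, percent.
#' @param hct_range Truncation bounds for hematocrit, percent.
#' @param hct_within_sd,hct_ar_rho Within-patient hematocrit variation
#'   (percent) and its AR(1) autocorrelation across successive laboratory
#'   records.
#' @param male_fraction_by_group,twin_fraction_by_group,
#'   triplet_fraction_by_group,ivf_fraction_by_group,
#'   natural_fraction_by_group Per-group (control, affected) probabilities.
#' @param map_intercept,map_ga_slope,map_sd,map_ar_rho MAP model, mmHg:
#'   baseline `intercept + slope * GA` plus AR(1) noise.
#' @param pco2_mean_sd pCO2 mean/SD, mmHg.
#' @param meas_per_day Blood-gas measurements per day (hematocrit is drawn
#'   at the first measurement of each day, exercising the carry-forward
#'   alignment).
#' @param control_days,pre_event_days,post_event_days Observation windows.
#' @param event_day_range Range (days) the hemorrhage day is drawn from.
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_total = 254, n_control = 118,
                          grade_counts = c(I = 38, II = 42, III = 48, IV = 8),
                          ga_mean_sd_control = c(26.68, 2.17),
                          ga_mean_sd_affected = c(26.26, 2.04),
                          ga_range = c(23, 30),
                          bw_anchor_g = 864.06, bw_ga_slope = 100,
                          bw_resid_sd = 150, bw_range = c(335, 1580),
                          hct_control_mean_sd = c(45.14, 7.92),
                          hct_affected_mean_sd = c(41.41, 7.48),
                          hct_range = c(15, 65),
                          hct_within_sd = 2, hct_ar_rho = 0.8,
                          male_fraction_by_group = c(0.4068, 0.544),
                          twin_fraction_by_group = c(27 / 118, 37 / 136),
                          triplet_fraction_by_group = c(16 / 118, 15 / 136),
                          ivf_fraction_by_group = c(17 / 118, 15 / 136),
                          natural_fraction_by_group = c(7 / 118, 15 / 136),
                          map_intercept = -1, map_ga_slope = 1, map_sd = 3,
                          map_ar_rho = 0.6,
                          pco2_mean_sd = c(45, 7),
                          meas_per_day = 3,
                          control_days = 10, pre_event_days = 7,
                          post_event_days = 3, event_day_range = c(1, 7),
                          seed = 1L) {
  if (n_control > n_total)
    stop("infeasible cohort parameters: n_control > n_total", call. = FALSE)
  if (sum(grade_counts) != n_total - n_control)
    stop("infeasible cohort parameters: grade counts must sum to the ",
         "affected-group size (", n_total - n_control, ")", call. = FALSE)
  p <- as.list(environment())
  sds <- c(ga_mean_sd_control[2], ga_mean_sd_affected[2], bw_resid_sd,
           hct_control_mean_sd[2], hct_affected_mean_sd[2], hct_within_sd,
           map_sd, pco2_mean_sd[2])
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  structure(p, class = "cohort_params")
}

#' Generate a synthetic monitoring cohort
#'
#' Draws a cohort of preterm-infant records with the statistical structure
#' of routine neonatal monitoring data: per-group gestational age and
#' hematocrit from truncated normals, birth weight conditional on
#' gestational age, AR(1) within-patient hematocrit so the laboratory
#' carry-forward step is non-trivial, MAP rising mildly with gestational
#' age, blood gases several times per day over the group-specific
#' observation window. Identical seeds give identical cohorts.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A list with `records` (list of `patient_record`) and `truth`
#'   (tibble of each patient's generating parameters).
#' @export
generate_cohort <- function(params = cohort_params(), seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  n_aff <- params$n_total - params$n_control
  grades <- c(rep("none", params$n_control),
              rep(names(params$grade_counts), params$grade_counts))
  is_aff <- grades != "none"
  gi <- is_aff + 1L  # 1 = control, 2 = affected

  ga_mean <- ifelse(is_aff, params$ga_mean_sd_affected[1], params$ga_mean_sd_control[1])
  ga_sd <- ifelse(is_aff, params$ga_mean_sd_affected[2], params$ga_mean_sd_control[2])
  ga <- round(rtruncnorm_(params$n_total, ga_mean, ga_sd,
                          params$ga_range[1], params$ga_range[2]), 1)
  bw <- round(pmin(pmax(params$bw_anchor_g + params$bw_ga_slope * (ga - 26.46) +
                          stats::rnorm(params$n_total, 0, params$bw_resid_sd),
                        params$bw_range[1]), params$bw_range[2]))
  hct_mean <- ifelse(is_aff, params$hct_affected_mean_sd[1],
                     params$hct_control_mean_sd[1])
  hct_sd <- ifelse(is_aff, params$hct_affected_mean_sd[2],
                   params$hct_control_mean_sd[2])
  hct_patient <- rtruncnorm_(params$n_total, hct_mean, hct_sd,
                             params$hct_range[1], params$hct_range[2])
  sex <- ifelse(stats::runif(params$n_total) <
                  params$male_fraction_by_group[gi], "male", "female")
  u <- stats::runif(params$n_total)
  multiples <- ifelse(u < params$twin_fraction_by_group[gi], "twin",
                ifelse(u < params$twin_fraction_by_group[gi] +
                         params$triplet_fraction_by_group[gi],
                       "triplet", "singleton"))
  ivf <- stats::runif(params$n_total) < params$ivf_fraction_by_group[gi]
  natural <- stats::runif(params$n_total) < params$natural_fraction_by_group[gi]
  event_day <- ifelse(is_aff,
                      sample(seq(params$event_day_range[1],
                                 params$event_day_range[2]),
                             params$n_total, replace = TRUE), NA_real_)

  records <- vector("list", params$n_total)
  for (i in seq_len(params$n_total)) {
    days <- if (is_aff[i])
      seq(max(0, event_day[i] - params$pre_event_days),
          event_day[i] + params$post_event_days) else
      seq(0, params$control_days - 1)
    n_day <- length(days)
    offs <- seq(0, 23.9, length.out = params$meas_per_day + 1)[seq_len(params$meas_per_day)]
    ts <- as.vector(outer(offs, days * 24, "+")) +
      round(stats::runif(n_day * params$meas_per_day, 0, 1.5), 2)
    ts <- sort(ts)
    np <- length(ts)

    ar <- function(n, rho, sd) {
      e <- numeric(n); e[1] <- stats::rnorm(1, 0, sd)
      for (k in seq_len(n - 1))
        e[k + 1] <- rho * e[k] + stats::rnorm(1, 0, sd * sqrt(1 - rho^2))
      e
    }
    map <- pmax(15, params$map_intercept + params$map_ga_slope * ga[i] +
                  ar(np, params$map_ar_rho, params$map_sd))
    pco2 <- pmax(20, params$pco2_mean_sd[1] + ar(np, 0.5, params$pco2_mean_sd[2]))
    # one laboratory hematocrit per day, at the first gas of the day
    hct_daily <- pmin(pmax(hct_patient[i] +
                             ar(n_day, params$hct_ar_rho, params$hct_within_sd),
                           params$hct_range[1]), params$hct_range[2])
    hsys <- rep(NA_real_, np)
    day_of <- findInterval(ts, days * 24)
    first_of_day <- !duplicated(day_of)
    hsys[first_of_day] <- hct_daily[day_of[first_of_day]]

    records[[i]] <- structure(list(
      patient_id = sprintf("P%03d", i),
      gestational_age = ga[i], birth_weight = bw[i],
      sex = sex[i], multiples = multiples[i], ivf = ivf[i],
      natural_birth = natural[i], ivh_grade = grades[i],
      event_day = event_day[i],
      measurements = tibble::tibble(
        timestamp = round(ts, 2), map = round(map, 1),
        pco2 = round(pco2, 1), h_sys = pct_to_frac(round(hsys, 1)))),
      class = "patient_record")
  }
  truth <- tibble::tibble(
    patient_id = vapply(records, `[[`, "", "patient_id"),
    ivh_grade = grades, gestational_age = ga, birth_weight = bw,
    hct_patient_mean_pct = hct_patient, event_day = event_day)
  list(records = records, truth = truth)
}

#' Write a cohort to the documented CSV schema
#'
#' Produces `measurements.csv` and `metadata.csv` in `out_dir`, in exactly
#' the layout [read_records()] expects (hematocrit as percent; empty cells
#' for gas points without a concurrent laboratory record).
#'
#' @param records List of `patient_record`s.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector with the two file paths, invisibly.
#' @export
write_cohort <- function(records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  empty_meta <- tibble::tibble(
    patient_id = character(), ga_weeks = numeric(), birth_weight_g = numeric(),
    sex = character(), multiples = character(), ivf = logical(),
    natural_birth = logical(), ivh_grade = character(), event_day = numeric())
  empty_meas <- tibble::tibble(
    patient_id = character(), timestamp = numeric(), map_mmHg = numeric(),
    pco2_mmHg = numeric(), hsys_pct = numeric())
  meta <- dplyr::bind_rows(empty_meta, lapply(records, function(r) tibble::tibble(
    patient_id = r$patient_id, ga_weeks = r$gestational_age,
    birth_weight_g = r$birth_weight, sex = r$sex, multiples = r$multiples,
    ivf = r$ivf, natural_birth = r$natural_birth, ivh_grade = r$ivh_grade,
    event_day = r$event_day)))
  meas <- dplyr::bind_rows(empty_meas, lapply(records, function(r) tibble::tibble(
    patient_id = r$patient_id, timestamp = r$measurements$timestamp,
    map_mmHg = r$measurements$map, pco2_mmHg = r$measurements$pco2,
    hsys_pct = frac_to_pct(r$measurements$h_sys))))
  mf <- file.path(out_dir, "measurements.csv")
  pf <- file.path(out_dir, "metadata.csv")
  utils::write.csv(meas, mf, row.names = FALSE, na = "")
  utils::write.csv(meta, pf, row.names = FALSE, na = "")
  invisible(c(measurements = mf, metadata = pf))
}
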