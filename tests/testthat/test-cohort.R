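cfg <- default_morphometry()

# small hand-built cohort exercising the schema
make_meas <- function(pid, ts, map, hsys_pct) {
  data.frame(patient_id = pid, timestamp = ts, map_mmHg = map,
             pco2_mmHg = 45, hsys_pct = hsys_pct)
}
make_meta <- function(pid, grade = "none", event_day = NA, ga = 26, bw = 850) {
  data.frame(patient_id = pid, ga_weeks = ga, birth_weight_g = bw,
             sex = "female", multiples = "singleton", ivf = FALSE,
             natural_birth = FALSE, ivh_grade = grade, event_day = event_day)
}

test_that("records read from CSV with percent hematocrit converted to fractions", {
  dir <- withr::local_tempdir()
  meas <- make_meas("A", c(1, 10, 20), c(30, 31, 32), c(45, NA, 41))
  meta <- make_meta("A")
  utils::write.csv(meas, file.path(dir, "m.csv"), row.names = FALSE, na = "")
  utils::write.csv(meta, file.path(dir, "p.csv"), row.names = FALSE, na = "")
  recs <- read_records(file.path(dir, "m.csv"), file.path(dir, "p.csv"))
  expect_length(recs, 1)
  expect_equal(recs[[1]]$measurements$h_sys, c(0.45, NA, 0.41))
  expect_error(read_records(file.path(dir, "p.csv"), file.path(dir, "p.csv")),
               "missing column")
})

test_that("an empty cohort reads to an empty list with a warning", {
  expect_warning(
    recs <- read_records(make_meas("A", 1, 30, 45)[0, ], make_meta("A")[0, ]),
    "empty cohort")
  expect_length(recs, 0)
})

test_that("hematocrit alignment carries the last laboratory value forward", {
  recs <- read_records(make_meas("A", c(1, 10, 20, 30), c(30, 30, 30, 30),
                                 c(NA, 45, NA, 41)), make_meta("A"))
  al <- align_hematocrit(recs[[1]])
  expect_equal(al$measurements$h_sys_filled, c(NA, 0.45, 0.45, 0.41))
  expect_equal(al$measurements$h_source,
               c("missing", "measured", "carried", "measured"))
  # measured at every point: identity
  full <- align_hematocrit(read_records(
    make_meas("B", c(1, 5), c(30, 30), c(40, 42)), make_meta("B"))[[1]])
  expect_equal(full$measurements$h_sys_filled, full$measurements$h_sys)
  # no hematocrit at all: excluded
  expect_message(
    none <- align_hematocrit(read_records(
      make_meas("C", c(1, 5), c(30, 30), c(NA, NA)), make_meta("C"))[[1]]),
    "excluded")
  expect_null(none)
})

test_that("per-patient CBF honors hematocrit mode, window and monotonicity", {
  rec45 <- read_records(make_meas("A", c(1, 10, 20), c(30, 32, 34), c(45, 45, 45)),
                        make_meta("A"))[[1]]
  m <- compute_patient_cbf(rec45, cfg, "measured")
  f <- compute_patient_cbf(rec45, cfg, "fixed45")
  expect_equal(m$series$cbf, f$series$cbf, tolerance = 1e-12)

  lo <- read_records(make_meas("B", c(1, 10, 20), c(30, 32, 34), c(35, 35, 35)),
                     make_meta("B"))[[1]]
  hi <- read_records(make_meas("C", c(1, 10, 20), c(30, 32, 34), c(55, 55, 55)),
                     make_meta("C"))[[1]]
  expect_gt(compute_patient_cbf(lo, cfg)$mean_cbf,
            compute_patient_cbf(hi, cfg)$mean_cbf)
  # affected window: -7/+3 days around the event
  aff <- read_records(
    make_meas("D", c(1, 5 * 24, 9 * 24, 14 * 24), rep(30, 4), rep(42, 4)),
    make_meta("D", grade = "III", event_day = 6))[[1]]
  out <- compute_patient_cbf(aff, cfg)
  expect_equal(out$series$timestamp, c(1, 5 * 24, 9 * 24))
  # control window: first 10 days only
  ctl <- read_records(
    make_meas("E", c(1, 9 * 24, 12 * 24), rep(30, 3), rep(42, 3)),
    make_meta("E"))[[1]]
  expect_equal(compute_patient_cbf(ctl, cfg)$series$timestamp, c(1, 9 * 24))
  # hypotensive points below the intracranial pressure are skipped
  hypo <- read_records(make_meas("F", c(1, 10), c(4, 30), c(42, 42)),
                       make_meta("F"))[[1]]
  expect_warning(res <- compute_patient_cbf(hypo, cfg), "MAP")
  expect_equal(nrow(res$series), 1L)
})

test_that("measured-vs-fixed ordering follows the patient's hematocrit exactly", {
  # measured-mode mean above fixed-mode mean iff mean hematocrit below 45%
  for (h in c(0.38, 0.45, 0.52)) {
    rec <- read_records(make_meas("X", c(1, 10), c(30, 30), rep(100 * h, 2)),
                        make_meta("X"))[[1]]
    m <- compute_patient_cbf(rec, cfg, "measured")$mean_cbf
    f <- compute_patient_cbf(rec, cfg, "fixed45")$mean_cbf
    if (h < 0.45) expect_gt(m, f)
    if (h == 0.45) expect_equal(m, f, tolerance = 1e-12)
    if (h > 0.45) expect_lt(m, f)
  }
})

test_that("cohort summaries reproduce the published male-split Fisher test", {
  # 48 males of 118 controls vs 74 of 136 affected: p ~ 0.03
  n <- c(118, 136); males <- c(48, 74)
  meta <- dplyr::bind_rows(lapply(1:2, function(g)
    dplyr::bind_rows(lapply(seq_len(n[g]), function(i) {
      md <- make_meta(sprintf("G%d_%03d", g, i),
                      grade = if (g == 2) "I" else "none",
                      event_day = if (g == 2) 3 else NA)
      md$sex <- if (i <= males[g]) "male" else "female"
      md
    }))))
  meas <- dplyr::bind_rows(lapply(meta$patient_id, function(p)
    make_meas(p, c(1, 20), c(30, 30), c(45, 45))))
  recs <- read_records(meas, meta)
  tab <- summarize_cohort(recs, cfg)
  p_male <- tab$demographics$p_value[tab$demographics$parameter == "Male"]
  expect_equal(p_male, 0.03, tolerance = 0.01 / 0.03)
  expect_equal(p_male, stats::fisher.test(cbind(n - males, males))$p.value)
  # identical CBF distributions in both modes: rank-sum p-value of 1
  expect_true(all(is.na(tab$cbf_global$p_value) | tab$cbf_global$p_value > 0.9))
  # single-capillary CBF is global CBF over the scaled capillary count
  per <- tab$patients
  expect_equal(per$cbf_cap_measured, per$cbf_measured /
                 vapply(recs[match(per$patient_id, vapply(recs, `[[`, "", "patient_id"))],
                        function(r) {
                          bw <- estimate_brain_weight(r$birth_weight, r$gestational_age, cfg)
                          scale_levels(cfg, bw)$gm$ngm_count
                        }, 1),
               tolerance = 1e-12)
})
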