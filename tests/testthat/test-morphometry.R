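cfg <- default_morphometry()

test_that("shipped morphometry loads with 19 validated levels and a split capillary bed", {
  expect_s3_class(cfg, "morphometry_config")
  expect_equal(sort(cfg$levels$j), 1:19)
  expect_equal(cfg$levels$compartment[cfg$levels$j == 10], "capillary")
  expect_gt(cfg$gm$gm_diameter_um, cfg$gm$ngm_diameter_um)
  expect_true(all(cfg$levels$count[cfg$levels$j != 10] >= 1))
})

test_that("structural validation errors name the offending key", {
  raw <- jsonlite::read_json(system.file("extdata", "morphometry_default.json",
                                         package = "cerebroflow"),
                             simplifyVector = TRUE)
  broken <- raw
  broken$levels <- broken$levels[broken$levels$j != 7, ]
  expect_error(load_morphometry(broken), "missing j = 7")
  broken <- raw
  broken$levels$j[broken$levels$j == 3] <- 4
  expect_error(load_morphometry(broken), "duplicate")
  broken <- raw
  broken$levels$compartment[broken$levels$j == 10] <- "venous"
  expect_error(load_morphometry(broken), "level 10")
  broken <- raw
  broken$gm$gm_diameter_um <- broken$gm$ngm_diameter_um - 0.1
  expect_error(load_morphometry(broken), "larger diameter")
  broken <- raw
  broken$gm$ngm_count <- NULL
  expect_error(load_morphometry(broken), "ngm_count")
})

test_that("serialization round-trips to an identical configuration", {
  path <- withr::local_tempfile(fileext = ".json")
  write_morphometry(cfg, path)
  back <- load_morphometry(path)
  expect_equal(back$levels, cfg$levels, tolerance = 1e-12)
  expect_equal(back$gm[order(names(back$gm))], cfg$gm[order(names(cfg$gm))],
               tolerance = 1e-12)
  expect_equal(back$brain_weight_table, cfg$brain_weight_table)
  expect_equal(back$scaling_exponents, cfg$scaling_exponents)
})

test_that("brain-weight estimation is monotone and clamps out-of-range inputs", {
  expect_lt(estimate_brain_weight(gestational_age = 25, config = cfg),
            estimate_brain_weight(gestational_age = 30, config = cfg))
  ga <- seq(22, 36, 0.5)
  bw <- estimate_brain_weight(gestational_age = ga, config = cfg)
  expect_true(all(diff(bw) >= 0))
  # cohort mean birth weight maps to a finite positive brain weight
  wb <- estimate_brain_weight(birth_weight = 864.06, config = cfg)
  expect_true(is.finite(wb) && wb > 0)
  bws <- estimate_brain_weight(birth_weight = c(400, 900, 1500), config = cfg)
  expect_true(all(diff(bws) > 0))
  expect_warning(estimate_brain_weight(gestational_age = 40, config = cfg),
                 "clamped")
  expect_warning(estimate_brain_weight(birth_weight = 100, config = cfg),
                 "clamped")
  expect_error(estimate_brain_weight(), "need")
})

test_that("scaling the tree by brain weight follows the configured exponents", {
  ref <- cfg$reference_brain_weight_g
  same <- scale_levels(cfg, ref)
  expect_equal(same$levels, cfg$levels)
  dbl <- scale_levels(cfg, 2 * ref)
  ok <- cfg$levels$j != 10
  expect_equal(dbl$levels$count[ok], 2 * cfg$levels$count[ok])
  expect_equal(dbl$levels$diameter_um[ok], cfg$levels$diameter_um[ok])
  expect_equal(dbl$gm$ngm_count, 2 * cfg$gm$ngm_count)
  # growing from 25 to 30 weeks lowers the total resistance
  r25 <- assemble_resistances(cfg, run_conditions(25, 40, 0.45))
  r30 <- assemble_resistances(cfg, run_conditions(30, 40, 0.45))
  expect_lt(r30$total, r25$total)
})

test_that("germinal-matrix capillary count involutes with gestational age", {
  ref <- cfg$reference_brain_weight_g
  ga <- seq(22, 36, by = 0.5)
  n <- vapply(ga, function(g) gm_vessel_count(g, ref, cfg), 1)
  expect_true(all(n >= 0))
  expect_true(all(diff(n) <= 1e-9))
  expect_equal(n[ga >= 32], rep(0, sum(ga >= 32)))
  # reference count at 25 weeks matches the capillary-resistance anchor
  expect_rel_equal(gm_vessel_count(25, ref, cfg), 1.51e16 / 239e8, 0.02)
})

test_that("series and parallel circuit laws hold on toy trees", {
  # a level of m identical vessels has level resistance RES/m, and levels
  # connected in series add
  rb <- assemble_resistances(cfg, run_conditions(25, 40, 0.45))
  lv <- rb$levels
  ok <- lv$j != 10
  expect_equal(lv$res_level[ok], lv$res_vessel[ok] / lv$count[ok],
               tolerance = 1e-14)
  expect_equal(rb$total, sum(lv$res_level), tolerance = 1e-12)
  # capillary level: harmonic (parallel) combination of the two branches
  g <- rb$gm_level
  expect_equal(g$res_level, 1 / (1 / g$res_gm_level + 1 / g$res_ngm_level),
               tolerance = 1e-12)
  expect_lte(g$res_level, min(g$res_gm_level, g$res_ngm_level))
})

test_that("assembled resistances reproduce the calibrated 25-week reference", {
  rb <- assemble_resistances(cfg, run_conditions(25, 40, 0.45))
  expect_rel_equal(rb$gm_level$res_gm_level, 239e8, 0.01)
  expect_rel_equal(rb$gm_level$res_ngm_level, 25.1e8, 0.01)
  expect_rel_equal(rb$total, 142e8, 0.01)
  rb15 <- assemble_resistances(cfg, run_conditions(25, 40, 0.15))
  expect_rel_equal(rb15$gm_level$res_gm_level, 163.9e8, 0.01)
  expect_rel_equal(rb15$gm_level$res_ngm_level, 16.2e8, 0.01)
  expect_rel_equal(rb15$total, 74.6e8, 0.01)
})

test_that("the precapillary layer carries the largest per-level resistance", {
  rb <- assemble_resistances(cfg, run_conditions(25, 40, 0.45))
  expect_equal(rb$levels$j[which.max(rb$levels$res_level)], 9)
})

test_that("total resistance is monotone in hematocrit and gestational age", {
  for (ga in c(23, 29, 36)) {
    tots <- vapply(c(0.15, 0.45, 0.60), function(h)
      assemble_resistances(cfg, run_conditions(ga, 40, h))$total, 1)
    expect_true(all(diff(tots) > 0))
  }
  for (h in c(0.15, 0.45, 0.60)) {
    tots <- vapply(seq(23, 36), function(ga)
      assemble_resistances(cfg, run_conditions(ga, 40, h))$total, 1)
    expect_true(all(diff(tots) < 0))
  }
})

test_that("removing the GM branch raises the capillary-level resistance", {
  no_gm <- cfg
  no_gm$gm$gm_count <- 0
  with_gm <- assemble_resistances(cfg, run_conditions(25, 40, 0.45))
  without <- assemble_resistances(no_gm, run_conditions(25, 40, 0.45))
  expect_gt(without$gm_level$res_level, with_gm$gm_level$res_level)
})

test_that("the vasoreactivity hook dilates vessels and lowers resistance", {
  base <- assemble_resistances(cfg, run_conditions(25, 40, 0.45))
  dilated <- assemble_resistances(cfg, run_conditions(25, 40, 0.45),
                                  diameter_modifier = function(d, cond) 1.1 * d)
  expect_lt(dilated$total, base$total)
  identity_hook <- assemble_resistances(cfg, run_conditions(25, 40, 0.45),
                                        diameter_modifier = function(d, cond) d)
  expect_equal(identity_hook$total, base$total, tolerance = 1e-14)
  expect_error(assemble_resistances(cfg, run_conditions(25, 40, 0.45),
                                    diameter_modifier = function(d, cond) d * 0),
               "wall offset")
})

test_that("legacy constant-viscosity mode is hematocrit-invariant", {
  tots <- vapply(c(0.15, 0.45, 0.60), function(h)
    assemble_resistances(cfg, run_conditions(
      25, 40, h, viscosity_mode = "constant_003"))$total, 1)
  expect_equal(tots[1], tots[2], tolerance = 1e-14)
  expect_equal(tots[2], tots[3], tolerance = 1e-14)
})
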