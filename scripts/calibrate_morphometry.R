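#!/usr/bin/env Rscript
# Regenerates inst/extdata/morphometry_default.json.
#
# The source morphometry of the hierarchical cerebrovascular model is not
# publicly available; this script recovers a usable default from the
# published 25-week reference quantities:
#   - total resistance at systemic hematocrit 15/45/60%:  74.6/142/209 e8
#   - capillary-level block: RES_GM 1.03/1.51/1.82 e16 per vessel and
#     239e8 per level at 45%; RES_nGM 3.34/5.16/6.33 e16 and 25.1e8
#   - precapillary single-vessel resistance 0.789/1.95/3.03 e16
#   - the 30-week total at 45% (65.9e8) anchors the brain-weight growth
# Exact equality is enforced on the 15% and 45% totals (these carry the
# hematocrit fold-ratios); the 60% total is matched as closely as the
# viscosity law permits (comes out ~208.6e8).
#
# Run from the repository root: Rscript scripts/calibrate_morphometry.R

suppressPackageStartupMessages(devtools::load_all("."))

H3 <- c(0.15, 0.45, 0.60)
rc <- rheology_constants()
tp <- two_phase_constants()
poise <- function(d, l, h) 128 * apparent_viscosity(d, h, rc) * (l * 1e-6) /
  (pi * (d * 1e-6)^4)

## germinal-matrix capillary geometry: least squares on the printed triple
tgt_gm <- c(1.03, 1.51, 1.82) * 1e16
fit_gm <- optim(c(6.8, 400), function(p) {
  if (p[1] < 3.2 || p[2] <= 0) return(1e6)
  v <- vapply(H3, function(h) capillary_resistance(
    capillary_geometry(p[1], p[2], "GM"), tube_hematocrit(p[1], h, rc), tp), 1)
  sum((log(v) - log(tgt_gm))^2)
})
d_gm <- fit_gm$par[1]; l_gm <- fit_gm$par[2]

## capillary counts from the printed per-level resistances at 45%
res_ngm <- vapply(H3, function(h) capillary_resistance(
  capillary_geometry(5.6, 600), tube_hematocrit(5.6, h, rc), tp), 1)
res_gm <- vapply(H3, function(h) capillary_resistance(
  capillary_geometry(d_gm, l_gm, "GM"), tube_hematocrit(d_gm, h, rc), tp), 1)
m_ngm <- res_ngm[2] / 25.1e8
m_gm <- res_gm[2] / 239e8
res10l <- 1 / (m_gm / res_gm + m_ngm / res_ngm)

## precapillary diameter/length from the printed single-vessel triple
tgt9 <- c(0.789, 1.95, 3.03) * 1e16
d9 <- optimize(function(d) {
  v <- apparent_viscosity(d, H3, rc)
  sum((log(v / v[2]) - log(tgt9 / tgt9[2]))^2)
}, c(10, 40))$minimum
l9 <- tgt9[2] * pi * (d9 * 1e-6)^4 / (128 * apparent_viscosity(d9, 0.45, rc)) / 1e-6

## remaining levels: per-level shares x_j at 45% solved so the three totals
## are matched (exactly at 15/45%), staying close to a plausible profile
lev <- data.frame(
  j = c(1:9, 11:19),
  name = c("large cerebral arteries", "main arterial branches", "small arteries",
           "pial arteries", "small pial arteries", "penetrating arterioles",
           "arterioles", "small arterioles", "precapillary arterioles",
           "postcapillary venules", "small venules", "venules", "small veins",
           "veins", "large veins", "deep veins", "sinuses", "outflow veins"),
  d = c(1300, 800, 500, 300, 150, 80, 50, 25, d9,
        18, 40, 80, 160, 350, 700, 1000, 1300, 1600),
  l = c(30000, 20000, 12000, 6000, 3500, 2000, 1000, 400, l9,
        300, 600, 1200, 2500, 5000, 8000, 12000, 20000, 25000))
totals <- c(74.6, 142, 209) * 1e8
rest_t <- (totals - res10l) / 1e8
A <- sapply(H3, function(h) apparent_viscosity(lev$d, h, rc))
B <- A / A[, 2]                       # hematocrit response per level
p <- c(3.0, 3.5, 4.0, 4.5, 5.0, 5.5, 6.5, 8.0, 26,
       5.0, 4.5, 3.5, 2.5, 2.0, 1.8, 1.5, 1.2, 1.0)  # prior shape, 1e8 units
Ceq <- t(B[, c(1, 2)]); beq <- rest_t[c(1, 2)]
floorx <- 0.4
fixed <- rep(FALSE, length(p))
repeat {                              # active-set QP with a floor per level
  xf <- rep(floorx, length(p)); free <- !fixed
  Cf <- Ceq[, free, drop = FALSE]
  bf <- beq - Ceq[, !free, drop = FALSE] %*% rep(floorx, sum(!free))
  Dinv <- diag(p[free]^2, nrow = sum(free))
  lam <- solve(Cf %*% Dinv %*% t(Cf), Cf %*% p[free] - bf)
  xs <- p[free] - Dinv %*% t(Cf) %*% lam
  xf[free] <- as.vector(xs)
  if (all(xf[free] >= floorx - 1e-9)) { x <- xf * 1e8; break }
  fixed[free][which(xs < floorx)] <- TRUE
}
m <- vapply(seq_len(nrow(lev)), function(i) poise(lev$d[i], lev$l[i], 0.45) / x[i], 1)

tot <- vapply(seq_along(H3), function(k)
  sum(vapply(seq_len(nrow(lev)), function(i)
    poise(lev$d[i], lev$l[i], H3[k]) / m[i], 1)) + res10l[k], 1)
cat("totals (1e8):", round(tot / 1e8, 2), " fold 15/45:", tot[2] / tot[1], "\n")

## brain-weight growth anchored on the 30-week total (GM partly involuted)
x45 <- x
beta <- uniroot(function(b)
  sum(x45) / b + 1 / (b * ((2 / 7) * m_gm / res_gm[2] + m_ngm / res_ngm[2])) - 65.9e8,
  c(1.5, 3))$root
cat("brain-weight ratio 30wk/25wk:", beta, "\n")
wb25 <- 130
bw_tab <- list(ga_weeks = 22:36,
               weight_g = c(81.3, 95.1, 111.2, 130, 152, 177.7, 207.8, 242.9,
                            round(wb25 * beta, 1), 315, 345, 372, 395, 412, 425))

levels_out <- rbind(
  data.frame(j = lev$j, name = lev$name, count = m, diameter_um = lev$d,
             length_um = lev$l,
             compartment = ifelse(lev$j <= 8, "arterial",
                                  ifelse(lev$j == 9, "precapillary", "venous"))),
  data.frame(j = 10, name = "capillaries", count = NA, diameter_um = NA,
             length_um = NA, compartment = "capillary"))
levels_out <- levels_out[order(levels_out$j), ]

cfg <- list(
  schema_version = "1.0",
  provenance = paste("Calibrated 19-level neonatal cerebrovascular morphometry.",
    "Level geometry/counts fitted so that, at the 25-week reference (brain weight 130 g),",
    "total resistance at systemic hematocrit 15/45/60% approximates the",
    "hematocrit-dependent assembly targets; capillary-level counts anchored to the",
    "two-phase capillary resistances."),
  reference_brain_weight_g = wb25,
  scaling_exponents = list(count = 1, length = 0, diameter = 0),
  brain_weight_table = bw_tab,
  birth_weight_allometry = list(coef = wb25 / 750^0.85, exponent = 0.85),
  levels = levels_out,
  gm = list(gm_diameter_um = d_gm, gm_length_um = l_gm,
            ngm_diameter_um = 5.6, ngm_length_um = 600,
            gm_count = m_gm, ngm_count = m_ngm,
            involution_onset_wk = 25, involution_complete_wk = 32),
  rheology = list(mu_plasma_Pa_s = 0.001, wall_offset_um = 1.1),
  two_phase = list(mu_rbc_Pa_s = 0.1))

out <- "inst/extdata/morphometry_default.json"
jsonlite::write_json(cfg, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", out, "\n")
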