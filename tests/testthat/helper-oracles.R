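# Independent brute-force oracles, written directly from the printed
# formulas with plain arithmetic. They deliberately share no code with the
# package implementation (separate parenthesization, no unit helpers).

oracle_mu45 <- function(d) 6 * exp(-0.085 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)

oracle_C <- function(d) {
  q <- 1 / (1 + 1e-11 * d^12)
  (0.8 + exp(-0.075 * d)) * (q - 1) + q
}

oracle_mu_a <- function(d, hd, mu_pl = 0.001, delta = 1.1) {
  W <- d * d / ((d - delta) * (d - delta))
  C <- oracle_C(d)
  mu_pl * (1 + (oracle_mu45(d) - 1) * (((1 - hd)^C - 1) / (0.55^C - 1)) * W) * W
}

oracle_ht <- function(d, hd)
  hd * (hd + (1 - hd) * (1 + 1.7 * exp(-0.35 * d) - 0.6 * exp(-0.01 * d)))

# two-phase capillary oracle; r, l in metres, straight from the formulas
oracle_capillary <- function(r, l, ht, mu_rbc = 0.1) {
  mu_pl <- 0.001 * (16 + 5 * ht) / 15
  r0 <- 0.3e-6 + 0.8 * r
  rho <- (pi * r^4 / (8 * l * mu_pl))^-1
  rho_hat <- (8 * l / pi) * ((r^4 - r0^4) / mu_pl + r0^4 / mu_rbc)^-1
  rho + (rho_hat - rho) * ht
}

# random but valid 19-level trees for property-style circuit tests
random_config <- function(seed) {
  set.seed(seed)
  lv <- data.frame(
    j = 1:19, name = paste0("L", 1:19),
    count = c(round(runif(9, 1, 1e5)), NA, round(runif(9, 1, 1e5))),
    diameter_um = c(round(runif(9, 15, 1500), 1), NA, round(runif(9, 15, 1500), 1)),
    length_um = c(round(runif(9, 100, 20000)), NA, round(runif(9, 100, 20000))),
    compartment = c(rep("arterial", 8), "precapillary", "capillary",
                    rep("venous", 9)))
  ngm_d <- runif(1, 4.5, 6); gm_d <- ngm_d + runif(1, 0.5, 2)
  load_morphometry(list(
    reference_brain_weight_g = 130,
    scaling_exponents = list(count = 1, length = 0, diameter = 0),
    brain_weight_table = list(ga_weeks = c(22, 36), weight_g = c(80, 420)),
    birth_weight_allometry = list(coef = 0.47, exponent = 0.85),
    levels = lv,
    gm = list(gm_diameter_um = gm_d, gm_length_um = round(runif(1, 200, 600)),
              ngm_diameter_um = ngm_d, ngm_length_um = round(runif(1, 300, 800)),
              gm_count = round(runif(1, 1e4, 1e6)),
              ngm_count = round(runif(1, 1e6, 5e7)),
              involution_onset_wk = 25, involution_complete_wk = 32)))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
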