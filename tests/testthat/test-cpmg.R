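test_that("R2eff from intensities follows the log identity", {
  expect_equal(r2eff_from_intensity(100, 100, 0.05), 0)
  expect_equal(r2eff_from_intensity(50, 100, 0.05), log(2) / 0.05,
               tolerance = 1e-12)
  expect_equal(r2eff_from_intensity(100 * exp(-1), 100, 0.05), 20,
               tolerance = 1e-12)
  expect_error(r2eff_from_intensity(-1, 100, 0.05), class = "domain_error")
  expect_error(r2eff_from_intensity(50, 0, 0.05), class = "domain_error")
})

test_that("no-exchange limits give flat curves at R20", {
  nu <- cpmg_nu
  flat1 <- cr_dispersion(exchange_params(0, 0.3, 500, 9), nu, 800)
  flat2 <- cr_dispersion(exchange_params(0.05, 0, 500, 9), nu, 800)
  expect_equal(flat1, rep(9, length(nu)))
  expect_equal(flat2, rep(9, length(nu)))
  expect_equal(bm_oracle(exchange_params(0, 0.3, 500, 9), nu, 800),
               rep(9, length(nu)))
  # frozen exchange: kex -> 0 with the major state observed
  slow <- bm_oracle(exchange_params(0.1, 0.3, 1e-3, 9), nu, 800)
  expect_equal(slow, rep(9, length(nu)), tolerance = 1e-5)
})

test_that("closed form matches the Bloch-McConnell oracle across 100 draws", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    ep <- exchange_params(p_b = runif(1, 0.005, 0.15),
                          delta_omega_n = runif(1, 0.05, 1),
                          kex = exp(runif(1, log(50), log(5000))), r20 = 8)
    f <- sample(c(500, 800), 1)
    dev <- max(abs(bm_oracle(ep, cpmg_nu, f) - cr_dispersion(ep, cpmg_nu, f)))
    worst <- max(worst, dev)
  }
  expect_lt(worst, 0.1)
})

test_that("fast-exchange regime reproduces the Luz-Meiboom expression", {
  for (f in c(500, 800)) {
    pb <- 0.05; dw <- 0.2
    dwr <- ppm_to_rads(dw, f)
    kex <- 50 * dwr
    ep <- exchange_params(pb, dw, kex, 8)
    got <- cr_dispersion(ep, cpmg_nu, f)
    want <- luz_meiboom(pb, dwr, kex, 8, cpmg_nu)
    expect_lt(max(abs(got - want) / pmax(want - 8, 1e-12)), 0.02)
    expect_lt(max(abs(got - want) / want), 0.02)
  }
})

test_that("dispersion is non-increasing in nu over valid SQ draws", {
  # regime where the two-state SQ profile is monotone; deep slow exchange
  # (delta-omega >> kex) genuinely oscillates and is excluded
  set.seed(13)
  for (i in 1:200) {
    ep <- exchange_params(p_b = runif(1, 0.002, 0.15),
                          delta_omega_n = runif(1, 0.02, 1),
                          kex = exp(runif(1, log(50), log(5000))),
                          r20 = runif(1, 4, 20))
    r <- cr_dispersion(ep, seq(40, 960, by = 40), sample(c(500, 800), 1))
    expect_true(all(diff(r) < 1e-6))
  }
})

test_that("field scaling never decreases the dispersion amplitude", {
  set.seed(14)
  for (i in 1:50) {
    ep <- exchange_params(p_b = runif(1, 0.01, 0.15),
                          delta_omega_n = runif(1, 0.05, 0.8),
                          kex = exp(runif(1, log(100), log(4000))), r20 = 8)
    a1 <- diff(rev(cr_dispersion(ep, c(80, 960), 400)))
    a2 <- diff(rev(cr_dispersion(ep, c(80, 960), 800)))
    expect_gte(a2, a1 - 1e-10)
  }
})

test_that("the oracle rejects non-integral echo-cycle schedules", {
  ep <- exchange_params(0.05, 0.3, 500, 8)
  expect_error(bm_oracle(ep, 50, 800, t_cp = 0.05), class = "schedule_error")
  expect_silent(bm_oracle(ep, 40, 800, t_cp = 0.05))
  cfg <- generator_config(1, 0)
  expect_warning(
    gen_dispersion(list(A = ep), nu_list = c(40, 50), config = cfg),
    class = "schedule_warning")
})

test_that("delta_r2eff differences the stated frequencies with a strict flag", {
  curve <- data.frame(nu_cpmg_hz = cpmg_nu,
                      r2eff = rep(8, length(cpmg_nu)))
  d <- delta_r2eff(curve)
  expect_equal(d$delta_r2eff, 0)
  expect_false(d$dispersing)
  ep <- exchange_params(0.08, 0.4, 400, 8)
  curve2 <- data.frame(nu_cpmg_hz = cpmg_nu,
                       r2eff = cr_dispersion(ep, cpmg_nu, 800))
  expect_gt(delta_r2eff(curve2)$delta_r2eff, 0)
  # boundary convention: exactly 4.0 is not flagged
  curve3 <- data.frame(nu_cpmg_hz = c(80, 960), r2eff = c(12, 8))
  expect_false(delta_r2eff(curve3)$dispersing)
  expect_error(delta_r2eff(curve3, nu_low = 70), class = "schedule_error")
})

test_that("two-field fits recover published exchange parameter sets", {
  for (nm in names(published_exchange)) {
    tr <- published_exchange[[nm]]
    fit <- fit_two_state(make_two_field_curves(tr))
    expect_false(fit$no_exchange)
    expect_lt(abs(fit$kex - tr[["kex"]]) / tr[["kex"]], 0.01)
    expect_lt(abs(fit$p_b - tr[["p_b"]]), 0.005)
    expect_lt(abs(fit$delta_omega_n - tr[["dw"]]) / tr[["dw"]], 0.01)
    expect_equal(unname(fit$r20), c(8, 8), tolerance = 1e-3)
  }
})

test_that("single-field dispersion data are refused", {
  curves <- make_two_field_curves(published_exchange$T30_none)
  expect_error(fit_two_state(curves[curves$field_mhz == 800, ]),
               class = "insufficient_data_error")
  expect_error(fit_two_state(curves[curves$nu_cpmg_hz < 300, ]),
               class = "insufficient_data_error")
})

test_that("flat noisy curves yield a no-exchange result", {
  set.seed(77)
  curves <- do.call(rbind, lapply(c(500, 800), function(f)
    data.frame(field_mhz = f, nu_cpmg_hz = cpmg_nu,
               r2eff = 8 + rnorm(length(cpmg_nu), 0, 0.1),
               r2eff_err = 0.1)))
  fit <- fit_two_state(curves)
  expect_true(fit$no_exchange)
  expect_identical(fit$p_b, 0)
  expect_equal(unname(fit$r20), c(8, 8), tolerance = 0.1)
})

test_that("Monte-Carlo errors are seeded and reproducible", {
  tr <- published_exchange$T30_none
  curves <- make_two_field_curves(tr)
  curves$r2eff_err <- 0.05
  grid <- list(p_b = 0.1, dw = 0.3, kex = 200)
  f1 <- fit_two_state(curves, n_mc = 10, seed = 5, start_grid = grid)
  f2 <- fit_two_state(curves, n_mc = 10, seed = 5, start_grid = grid)
  expect_identical(f1$kex_se, f2$kex_se)
  expect_true(is.finite(f1$kex_se) && f1$kex_se > 0)
})

test_that("exchange parameter validation enforces the major-state convention", {
  expect_error(exchange_params(0.6, 0.3, 500, 8), class = "domain_error")
  expect_error(exchange_params(0.1, -0.3, 500, 8), class = "domain_error")
  expect_error(exchange_params(0.1, 0.3, -5, 8), class = "domain_error")
  ep <- exchange_params(0.1, 0.3, 500, 8)
  expect_equal(ep$p_a, 0.9)
})
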