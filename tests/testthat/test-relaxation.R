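sc500 <- spin_constants(500)

test_that("spectral density: rigid-rotor value at zero frequency", {
  p <- model_free_params(model = 1, s2 = 1, tau_m = 4)
  expect_equal(spectral_density(p, 0), 0.4 * 4e-9, tolerance = 1e-15)
  # vanishing limit: S2 = 0 with tau_loc -> 0 kills both terms
  p0 <- model_free_params(model = 2, s2 = 0, tau_m = 4, tau_loc = 1e-3)
  expect_lt(spectral_density(p0, 0), 1e-15)
})

test_that("spectral density matches an independent two-Lorentzian sum", {
  # extended model evaluated longhand, off the package's code path
  s2f <- 0.9; s2s <- 0.8; tm <- 4e-9; ts <- 50e-12
  tau <- ts * tm / (ts + tm)
  w <- 2 * pi * 50.68e6
  expected <- 0.4 * s2f * (s2s * tm / (1 + (w * tm)^2) +
                             (1 - s2s) * tau / (1 + (w * tau)^2))
  p <- model_free_params(model = 5, s2f = s2f, s2s = s2s, tau_m = 4,
                         tau_loc = 50)
  expect_equal(spectral_density(p, w), expected, tolerance = 1e-14)
})

test_that("J(omega) is strictly decreasing with J(0) maximal", {
  set.seed(20)
  omegas <- sort(c(0, 10^seq(6, 10, length.out = 40)))
  for (i in 1:25) {
    p <- model_free_params(model = 2, s2 = runif(1, 0.05, 0.99),
                           tau_m = runif(1, 2, 12),
                           tau_loc = runif(1, 5, 500))
    j <- spectral_density(p, omegas)
    expect_true(all(diff(j) < 0))
  }
})

test_that("Rex adds to R2 only", {
  p0 <- model_free_params(model = 3, s2 = 0.85, tau_m = 4, rex = 0)
  p5 <- model_free_params(model = 3, s2 = 0.85, tau_m = 4, rex = 5)
  r0 <- rates_from_model(p0, sc500)
  r5 <- rates_from_model(p5, sc500)
  expect_equal(r5$r2 - r0$r2, 5, tolerance = 1e-12)
  expect_equal(r5$r1, r0$r1)
  expect_equal(r5$noe, r0$noe)
})

test_that("rigid-limit rates match an independent single-Lorentzian oracle", {
  # closed-form oracle written directly from the rate equations with
  # J(w) = (2/5) tau_m / (1 + (w tau_m)^2)
  tm <- 4e-9
  jj <- function(w) 0.4 * tm / (1 + (w * tm)^2)
  wh <- sc500$omega_h; wn <- sc500$omega_n
  d2 <- sc500$d^2; c2 <- sc500$c2
  r1_o <- d2 / 4 * (jj(wh - wn) + 3 * jj(wn) + 6 * jj(wh + wn)) + c2 * jj(wn)
  r2_o <- d2 / 8 * (4 * jj(0) + jj(wh - wn) + 3 * jj(wn) + 6 * jj(wh) +
                      6 * jj(wh + wn)) + c2 / 6 * (4 * jj(0) + 3 * jj(wn))
  noe_o <- 1 + d2 / 4 * (sc500$gamma_h / sc500$gamma_n) / r1_o *
    (6 * jj(wh + wn) - jj(wh - wn))
  r <- rates_from_model(model_free_params(model = 1, s2 = 1, tau_m = 4), sc500)
  expect_equal(r$r1, r1_o, tolerance = 1e-13)
  expect_equal(r$r2, r2_o, tolerance = 1e-13)
  expect_equal(r$noe, noe_o, tolerance = 1e-13)
})

test_that("15N NOE never exceeds 1 over a broad random parameter sweep", {
  set.seed(7)
  n <- 10000
  s2 <- runif(n, 0, 1); te <- runif(n, 1, 900); tmv <- runif(n, 1, 15)
  worst <- -Inf
  for (i in seq_len(n)) {
    p <- model_free_params(model = 2, s2 = s2[i], tau_m = tmv[i],
                           tau_loc = min(te[i], tmv[i] * 1e3 * 0.9))
    noe <- rates_from_model(p, sc500)$noe
    worst <- max(worst, noe)
  }
  expect_lt(worst, 1)
})

test_that("exchange-free rates scale consistently across fields", {
  p <- model_free_params(model = 2, s2 = 0.85, tau_m = 4, tau_loc = 50)
  for (f in c(500, 800)) {
    sc <- spin_constants(f)
    r <- rates_from_model(p, sc)
    # direct re-evaluation from J at this field's frequencies
    j <- spectral_density(p, c(0, sc$omega_h - sc$omega_n, sc$omega_n,
                               sc$omega_h, sc$omega_h + sc$omega_n))
    r1 <- sc$d^2 / 4 * (j[2] + 3 * j[3] + 6 * j[5]) + sc$c2 * j[3]
    expect_equal(r$r1, r1, tolerance = 1e-13)
    # CSA constant carries the field dependence: c2 ~ omega_n^2
    expect_equal(sc$c2 / spin_constants(500)$c2, (f / 500)^2,
                 tolerance = 1e-12)
  }
  # Rex declared at 500 MHz scales with B0^2 when evaluated at 800
  prex <- model_free_params(model = 3, s2 = 0.85, tau_m = 4, rex = 3)
  r800 <- rates_from_model(prex, spin_constants(800), rex_field_mhz = 500)
  r800_0 <- rates_from_model(model_free_params(model = 3, s2 = 0.85,
                                               tau_m = 4, rex = 0),
                             spin_constants(800))
  expect_equal(r800$r2 - r800_0$r2, 3 * (800 / 500)^2, tolerance = 1e-12)
})

test_that("fit_decay recovers exact exponentials and rejects flat series", {
  t <- c(10, 80, 200, 200, 320, 360, 420, 500)
  f <- fit_decay(t, 100 * exp(-2.0 * t / 1000))
  expect_equal(f$rate, 2.0, tolerance = 1e-10)
  # equals the log-linear regression estimate on noiseless data
  loglin <- -coef(lm(log(100 * exp(-2.0 * t / 1000)) ~ I(t / 1000)))[[2]]
  expect_equal(f$rate, loglin, tolerance = 1e-9)
  expect_error(fit_decay(t, rep(50, length(t))), class = "fit_error")
  expect_error(fit_decay(c(10, 10, 80, 80), c(9, 9, 5, 5)),
               class = "insufficient_data_error")
  # round trip through the generator
  g <- gen_relaxation(
    list(A = model_free_params(model = 2, s2 = 0.8, tau_m = 4, tau_loc = 50)),
    sc500, config = generator_config(1, 0))
  fr <- fit_decay(g$t1_decays$delay_ms, g$t1_decays$intensity)
  expect_equal(fr$rate, g$records$r1[1], tolerance = 1e-6)
})

test_that("R1rho to R2 conversion handles offset and on-resonance cases", {
  expect_equal(r2_from_r1rho(12.3, 2, offset_hz = 0), 12.3)
  # hand evaluation at sin^2(theta) = 0.9
  theta <- asin(sqrt(0.9))
  off <- 1600 / tan(theta)
  expect_equal(r2_from_r1rho(10, 2, off, 1600), (10 - 2 * 0.1) / 0.9,
               tolerance = 1e-9)
  # continuity: offset -> 0 approaches the on-resonance identity
  offs <- c(100, 10, 1, 0.01)
  vals <- r2_from_r1rho(10, 2, offs, 1600)
  expect_true(all(abs(vals - 10) < abs(c(1, vals[-4] - 10))))
  expect_error(r2_from_r1rho(10, 2, 100, 0), class = "domain_error")
})

test_that("spin constants validate physical ranges", {
  expect_error(spin_constants(-500), class = "domain_error")
  expect_error(spin_constants(500, r_nh = 1.5), class = "domain_error")
  expect_error(spin_constants(500, gamma_n = 2.7e7), class = "domain_error")
  sc <- spin_constants(800)
  expect_equal(sc$omega_n / (2 * pi * 1e6), 800 * 0.101329446,
               tolerance = 1e-12)
})
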