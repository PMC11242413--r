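test_that("csd_index evaluates the weighted 1H/15N norm", {
  expect_identical(csd_index(0, 0), 0)
  expect_identical(csd_index(0.1, 0), 0.1)
  expect_equal(csd_index(0.06, 0.4), sqrt(0.0036 + 0.01), tolerance = 1e-12)
})

test_that("csd_index behaves as a norm on shift deltas", {
  set.seed(1)
  dh <- rnorm(200); dn <- rnorm(200); s <- runif(200, 0.1, 10)
  expect_true(all(csd_index(dh, dn) >= 0))
  expect_true(all(csd_index(dh, dn)[abs(dh) + abs(dn) > 0] > 0))
  expect_equal(csd_index(s * dh, s * dn), s * csd_index(dh, dn),
               tolerance = 1e-12)
  expect_equal(csd_index(dh, dn), csd_index(-dh, -dn), tolerance = 1e-15)
})

test_that("compute_csd rejects mismatched residues and is symmetric", {
  a <- peak_position("T28", 8.2, 118.0)
  b <- peak_position("T28", 8.26, 118.4)
  expect_equal(compute_csd(a, b), compute_csd(b, a))
  expect_equal(compute_csd(a, a), 0)
  c <- peak_position("T29", 8.2, 118.0)
  expect_error(compute_csd(a, c), class = "identity_error")
  expect_warning(peak_position("G1", 4.0, 118), class = "range_warning")
})

test_that("csd_profile is zero at the reference and nonnegative", {
  cfg <- generator_config(seed = 3, noise_sd = 0.001)
  ser <- gen_titration(c(A1 = 50, B2 = 120), c(A1 = 0.2, B2 = 0.1), 0.25,
                       c(0, 10, 50, 100, 150, 200), config = cfg)
  prof <- csd_profile(ser)
  expect_true(all(prof$csd >= 0))
  expect_true(all(prof$csd[prof$concentration_mM == 0] == 0))
})

test_that("significance threshold is mean + SD with strict exceedance", {
  prof <- data.frame(residue_id = c("A", "B", "C", "D"),
                     concentration_mM = 200,
                     csd = c(0.05, 0.05, 0.05, 0.30))
  fl <- flag_significant(prof, 200)
  expect_equal(fl$threshold, 0.1125 + sqrt(0.046875 / 4), tolerance = 1e-12)
  expect_identical(fl$residues, "D")
  # degenerate: identical CSDs, SD = 0, nothing strictly above the mean
  prof$csd <- rep(0.1, 4)
  expect_length(flag_significant(prof, 200)$residues, 0)
  expect_error(flag_significant(prof, 100), class = "schedule_error")
  expect_error(flag_significant(prof[1:2, ], 200),
               class = "insufficient_data_error")
})

test_that("a profile scaled so mean + SD = 0.14 flags residues above 0.14", {
  vals <- c(0.02, 0.03, 0.02, 0.04, 0.05, 0.03, 0.28, 0.3, 0.25, 0.22,
            0.04, 0.03, 0.02, 0.05)
  ids <- sprintf("R%02d", seq_along(vals))
  thr0 <- mean(vals) + sqrt(mean((vals - mean(vals))^2))
  vals <- vals * 0.14 / thr0
  prof <- data.frame(residue_id = ids, concentration_mM = 200, csd = vals)
  fl <- flag_significant(prof, 200)
  expect_equal(fl$threshold, 0.14, tolerance = 1e-12)
  expect_setequal(fl$residues, ids[vals > 0.14])
})

test_that("binding isotherm: zero ligand and half-saturation behaviour", {
  expect_equal(binding_isotherm(0, 0.25, 100, 0.2), 0)
  # [L] = Kd = 100 mM >> [P]: bound fraction ~ 1/2 (quadratic-form value)
  s <- 0.25 + 100 + 100
  frac <- (s - sqrt(s^2 - 4 * 0.25 * 100)) / (2 * 0.25)
  expect_equal(binding_isotherm(100, 0.25, 100, 0.2), 0.2 * frac,
               tolerance = 1e-14)
  expect_equal(binding_isotherm(100, 0.25, 100, 0.2), 0.1, tolerance = 1e-3)
  expect_error(binding_isotherm(10, 0.25, -5, 0.2), class = "domain_error")
})

test_that("fit_kd round-trips noiseless titrations to < 0.1 %", {
  cfg <- generator_config(seed = 1, noise_sd = 0)
  sched <- default_schedules()$titration_mM
  ser <- gen_titration(c(X = 100), c(X = 0.2), 0.25, sched, config = cfg)
  f <- fit_kd(ser, "X")
  expect_equal(f$kd_mM, 100, tolerance = 1e-3)
  expect_equal(f$csd_max_ppm, 0.2, tolerance = 1e-3)
  expect_true(f$reliable)
})

test_that("fit_kd agrees with a dense grid-search oracle on noiseless data", {
  cfg <- generator_config(seed = 2, noise_sd = 0)
  sched <- default_schedules()$titration_mM
  kd_true <- 74.8
  ser <- gen_titration(c(X = kd_true), c(X = 0.28), 0.25, sched, config = cfg)
  prof <- csd_profile(ser)
  y <- prof$csd[order(prof$concentration_mM)]
  conc <- sort(prof$concentration_mM)
  # grid over Kd with the conditionally optimal CSD_max in closed form
  # (the model is linear in CSD_max), equivalent to a dense 2-D grid
  kd_grid <- exp(seq(log(1), log(1000), length.out = 2000))
  rss <- vapply(kd_grid, function(kd) {
    g <- binding_isotherm(conc, 0.25, kd, 1)
    cmax <- sum(y * g) / sum(g^2)
    sum((y - cmax * g)^2)
  }, numeric(1))
  kd_best <- kd_grid[which.min(rss)]
  cell <- diff(log(kd_grid))[1]
  f <- fit_kd(ser, "X")
  expect_lt(abs(log(f$kd_mM) - log(kd_best)), cell)
})

test_that("fitted Kd is invariant to rescaling of all CSDs", {
  cfg <- generator_config(seed = 4, noise_sd = 0)
  sched <- default_schedules()$titration_mM
  f1 <- fit_kd(gen_titration(c(X = 62.4), c(X = 0.1), 0.25, sched,
                             config = cfg), "X")
  f2 <- fit_kd(gen_titration(c(X = 62.4), c(X = 0.27), 0.25, sched,
                             config = cfg), "X")
  expect_equal(f1$kd_mM, f2$kd_mM, tolerance = 1e-6)
  expect_equal(f2$csd_max_ppm / f1$csd_max_ppm, 2.7, tolerance = 1e-6)
})

test_that("fit_kd input guards: few points, decreasing trend, missing peaks", {
  peaks <- data.frame(residue_id = "X",
                      concentration_mM = c(0, 50, 100, 200),
                      h_ppm = 8 + c(0, 0.02, 0.03, 0.04), n_ppm = 118)
  ser <- titration_series(peaks, 0.25)
  expect_error(fit_kd(ser, "X"), class = "insufficient_data_error")
  # exchange-broadened rows simply dropped: fit still works with >= 5 left
  cfg <- generator_config(seed = 9, noise_sd = 0)
  full <- gen_titration(c(X = 80), c(X = 0.2), 0.25,
                        default_schedules()$titration_mM, config = cfg)
  pk <- full$peaks[-c(3, 7), ]
  f <- fit_kd(titration_series(pk, 0.25), "X")
  expect_equal(f$kd_mM, 80, tolerance = 1e-3)
})

test_that("titration series validation catches schema and schedule faults", {
  expect_error(titration_series(data.frame(residue_id = "A"), 0.25),
               class = "schema_error")
  peaks <- data.frame(residue_id = c("A", "B"), concentration_mM = c(0, 50),
                      h_ppm = 8, n_ppm = 118)
  # residue B has no reference-point position
  expect_error(titration_series(peaks, 0.25), class = "schema_error")
  cfg <- generator_config(seed = 1, noise_sd = 0)
  expect_error(gen_titration(c(A = 50), c(A = 0.1), 0.25, c(0, 100, 50),
                             config = cfg), class = "schedule_error")
  expect_error(gen_titration(c(A = -5), c(A = 0.1), 0.25, c(0, 50, 100),
                             config = cfg), class = "domain_error")
})
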