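#' Acquisition schedules used by the generators
#'
#' Default measurement grids of the emulated experiments: titration
#' ligand concentrations (mM, including the zero-ligand reference),
#' T1 and T1rho relaxation delays (ms, with the duplicate repeat points),
#' CPMG pulse-train frequencies (Hz) with the 50 ms constant-time delay,
#' and the thermal-melt temperature grid (Celsius).
#'
#' @return named list of numeric vectors (and `t_cp` in s).
#' @export
default_schedules <- function() {
  list(
    titration_mM = c(0, 3, 6, 10, 20, 30, 40, 60, 80, 100, 125, 150, 200),
    t1_delays_ms = c(10, 80, 200, 200, 320, 360, 420, 500),
    t1rho_delays_ms = c(1, 30, 60, 90, 90, 110, 130, 150, 180),
    nu_cpmg_hz = c(40, 80, 120, 120, 160, 200, 240, 280, 320, 400, 480,
                   560, 640, 720, 800, 960),
    t_cp = 0.05,
    melt_temps_c = seq(20, 90, by = 0.5)
  )
}

#' Generator configuration
#'
#' Seed and noise level shared by all synthetic-data generators. The
#' same (seed, config) always yields bit-identical tables, and
#' `noise_sd = 0` returns the forward model exactly. Random streams are
#' split per residue (a deterministic hash of the residue id offsets the
#' seed), so adding residues never perturbs existing residues' draws.
#'
#' @param seed integer seed (mandatory).
#' @param noise_sd Gaussian noise standard deviation, in units of the
#'   generated observable (ppm for peak positions, intensity units for
#'   decay/CPMG intensities, ellipticity units for melts).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed, noise_sd = 0) {
  if (missing(seed) || !is.finite(seed))
    nmr_error("a seed is mandatory in the generator config", "domain_error")
  if (noise_sd < 0)
    nmr_error("noise_sd must be nonnegative", "domain_error")
  structure(list(seed = as.integer(seed), noise_sd = noise_sd),
            class = "generator_config")
}

# deterministic per-residue substream seed (djb2 hash, 31-bit)
.residue_seed <- function(seed, id, salt = 0L) {
  h <- 5381
  for (ch in utf8ToInt(paste0(id, ":", salt)))
    h <- (h * 33 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# draw Gaussian noise on the residue's own stream
.residue_noise <- function(config, id, n, salt = 0L) {
  if (config$noise_sd == 0) return(rep(0, n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(.residue_seed(config$seed, id, salt))
  rnorm(n, 0, config$noise_sd)
}

#' Generate a synthetic HSQC titration series
#'
#' Forward model of the one-site quadratic binding isotherm
#' ([binding_isotherm()]): at each ligand concentration a residue's peak
#' is displaced from its reference position by the model CSD, decomposed
#' along a per-residue direction in (d1H, d15N/4) space (so the weighted
#' index of the displacement equals the model CSD), plus optional
#' Gaussian noise on both ppm axes.
#'
#' @param kd_map named numeric vector of per-residue Kd, mM (> 0).
#' @param csd_max_map named numeric vector of per-residue saturation CSD,
#'   ppm (same names).
#' @param p_total protein concentration, mM.
#' @param concentrations ligand concentrations, mM, strictly increasing;
#'   the first is the reference (may be 0).
#' @param direction_map optional named vector of angles (degrees) in
#'   (d1H, d15N/4) space; default 45 degrees for every residue.
#' @param ref_positions optional data.frame (residue_id, h_ppm, n_ppm) of
#'   reference peak positions; defaults to a spread around (8.3, 118).
#' @param config [generator_config()].
#' @return [titration_series()].
#' @export
gen_titration <- function(kd_map, csd_max_map, p_total, concentrations,
                          direction_map = NULL, ref_positions = NULL,
                          config) {
  stopifnot(inherits(config, "generator_config"))
  if (any(diff(concentrations) <= 0))
    nmr_error("concentrations must be strictly increasing", "schedule_error")
  if (any(concentrations < 0))
    nmr_error("concentrations must be nonnegative", "schedule_error")
  if (any(kd_map <= 0))
    nmr_error("all Kd must be positive", "domain_error")
  if (any(csd_max_map < 0))
    nmr_error("CSD_max must be nonnegative", "domain_error")
  if (p_total <= 0)
    nmr_error("protein concentration must be positive", "domain_error")
  ids <- names(kd_map)
  if (is.null(ids) || !setequal(ids, names(csd_max_map)))
    nmr_error("kd_map and csd_max_map must share residue names", "domain_error")
  if (is.null(direction_map))
    direction_map <- setNames(rep(45, length(ids)), ids)
  if (is.null(ref_positions)) {
    i <- seq_along(ids)
    ref_positions <- data.frame(
      residue_id = ids,
      h_ppm = 7.6 + 0.13 * (i %% 11),
      n_ppm = 108 + 1.9 * (i %% 13),
      stringsAsFactors = FALSE)
  }
  rows <- lapply(ids, function(id) {
    ref <- ref_positions[ref_positions$residue_id == id, ]
    csd <- binding_isotherm(concentrations, p_total, kd_map[[id]],
                            csd_max_map[[id]])
    phi <- direction_map[[id]] * pi / 180
    nz <- .residue_noise(config, id, 2 * length(concentrations))
    data.frame(
      residue_id = id,
      concentration_mM = concentrations,
      h_ppm = ref$h_ppm + csd * cos(phi) + nz[seq_along(concentrations)],
      n_ppm = ref$n_ppm + 4 * csd * sin(phi) +
        nz[length(concentrations) + seq_along(concentrations)],
      stringsAsFactors = FALSE)
  })
  titration_series(do.call(rbind, rows), p_total_mM = p_total)
}

#' Generate synthetic relaxation decays and NOE intensity pairs
#'
#' Forward model of the dipolar/CSA rate equations
#' ([rates_from_model()]): per residue, monoexponential T1 and T1rho
#' decay tables (R1rho = R2 on resonance) and a saturated/unsaturated
#' NOE intensity pair whose ratio equals the model NOE, with Gaussian
#' noise on intensities.
#'
#' @param params_map named list of [model_free_params()] per residue.
#' @param constants [spin_constants()].
#' @param t1_delays,t1rho_delays delay schedules in ms (duplicates =
#'   replicate measurements).
#' @param config [generator_config()].
#' @param i0 reference intensity (arbitrary units).
#' @return list with `t1_decays`, `t1rho_decays` (residue_id, delay_ms,
#'   intensity, replicate), `noe` (residue_id, i_sat, i_unsat, noe_err)
#'   and `records` (exact rates per residue, for reference).
#' @export
gen_relaxation <- function(params_map, constants,
                           t1_delays = default_schedules()$t1_delays_ms,
                           t1rho_delays = default_schedules()$t1rho_delays_ms,
                           config, i0 = 100) {
  stopifnot(inherits(config, "generator_config"),
            inherits(constants, "spin_constants"))
  ids <- names(params_map)
  if (is.null(ids)) nmr_error("params_map must be named", "domain_error")
  decay_tab <- function(id, delays, rate, salt) {
    nz <- .residue_noise(config, id, length(delays), salt)
    data.frame(residue_id = id, delay_ms = delays,
               intensity = i0 * exp(-rate * delays / 1000) + nz,
               replicate = stats::ave(delays, delays, FUN = seq_along),
               stringsAsFactors = FALSE)
  }
  t1 <- list(); t1r <- list(); noes <- list(); recs <- list()
  for (id in ids) {
    p <- params_map[[id]]
    stopifnot(inherits(p, "model_free_params"))
    r <- rates_from_model(p, constants)
    t1[[id]] <- decay_tab(id, t1_delays, r$r1, 1L)
    t1r[[id]] <- decay_tab(id, t1rho_delays, r$r2, 2L)  # on-resonance R1rho = R2
    nz <- .residue_noise(config, id, 2L, 3L)
    noes[[id]] <- data.frame(residue_id = id,
                             i_sat = i0 * r$noe + nz[1],
                             i_unsat = i0 + nz[2],
                             noe_err = max(config$noise_sd / i0, 1e-6) *
                               sqrt(2) * abs(r$noe),
                             stringsAsFactors = FALSE)
    recs[[id]] <- data.frame(residue_id = id,
                             field_mhz = constants$field_mhz,
                             r1 = r$r1, r2 = r$r2, noe = r$noe,
                             stringsAsFactors = FALSE)
  }
  list(t1_decays = do.call(rbind, t1),
       t1rho_decays = do.call(rbind, t1r),
       noe = do.call(rbind, noes),
       records = do.call(rbind, recs))
}

#' Generate synthetic CPMG dispersion curves
#'
#' Forward model of the two-state dispersion ([cr_dispersion()], or the
#' Bloch-McConnell oracle by flag): per residue and field, peak
#' intensities \eqn{I(\nu) = I_0 e^{-R_2^{eff}(\nu) T_{CP}}} with
#' Gaussian noise, converted back to R2eff via
#' [r2eff_from_intensity()]; propagated errors are attached.
#'
#' @param params_map named list of [exchange_params()] per residue.
#' @param fields 1H spectrometer frequencies, MHz (distinct).
#' @param nu_list CPMG frequencies, Hz.
#' @param t_cp constant-time delay, s. Frequencies whose `t_cp * nu` is
#'   not an integral cycle count raise a schedule warning.
#' @param config [generator_config()].
#' @param use_oracle evaluate via [bm_oracle()] instead of the closed form.
#' @param i0 reference intensity.
#' @return data.frame (residue_id, field_mhz, nu_cpmg_hz, r2eff,
#'   r2eff_err).
#' @export
gen_dispersion <- function(params_map, fields = c(500, 800),
                           nu_list = default_schedules()$nu_cpmg_hz,
                           t_cp = default_schedules()$t_cp, config,
                           use_oracle = FALSE, i0 = 100) {
  stopifnot(inherits(config, "generator_config"))
  if (anyDuplicated(fields))
    nmr_error("fields must be distinct", "domain_error")
  ids <- names(params_map)
  if (is.null(ids)) nmr_error("params_map must be named", "domain_error")
  n_cyc <- t_cp * nu_list
  if (any(abs(n_cyc - round(n_cyc)) > 1e-6))
    nmr_warn("some t_cp * nu are not integral echo-cycle counts",
             "schedule_warning")
  rows <- list()
  for (id in ids) {
    ep <- params_map[[id]]
    stopifnot(inherits(ep, "exchange_params"))
    for (fi in seq_along(fields)) {
      f <- fields[fi]
      r2 <- if (use_oracle) bm_oracle(ep, nu_list, f, t_cp)
            else cr_dispersion(ep, nu_list, f, t_cp)
      nz <- .residue_noise(config, id, length(nu_list) + 1L, 10L + fi)
      i_nu <- i0 * exp(-r2 * t_cp) + nz[-1]
      i_ref <- i0 + nz[1]
      if (any(i_nu <= 0) || i_ref <= 0)
        nmr_error("noise drove an intensity nonpositive; reduce noise_sd",
                  "domain_error")
      r2eff <- r2eff_from_intensity(i_nu, i_ref, t_cp)
      err <- config$noise_sd / (i_nu * t_cp)  # first-order propagation
      rows[[length(rows) + 1L]] <- data.frame(
        residue_id = id, field_mhz = f, nu_cpmg_hz = nu_list,
        r2eff = r2eff, r2eff_err = err, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic thermal melting curve
#'
#' Forward model of the two-state van't Hoff melt with linear baselines
#' (see [unfolded_fraction()]), plus Gaussian noise on the ellipticity.
#'
#' @param tm melting temperature, Celsius (inside the grid).
#' @param dh_vh van't Hoff enthalpy, kJ/mol (> 0).
#' @param baselines list with `folded = c(intercept, slope)` and
#'   `unfolded = c(intercept, slope)` (ellipticity units, per Celsius).
#' @param temps temperature grid, Celsius.
#' @param config [generator_config()].
#' @param condition condition label carried into the curve.
#' @return [melting_curve()].
#' @export
gen_melting <- function(tm, dh_vh,
                        baselines = list(folded = c(-6, 0.005),
                                         unfolded = c(-1.2, 0.004)),
                        temps = default_schedules()$melt_temps_c,
                        config, condition = "") {
  stopifnot(inherits(config, "generator_config"))
  if (dh_vh <= 0) nmr_error("dh_vh must be positive", "domain_error")
  if (tm < min(temps) || tm > max(temps))
    nmr_warn("Tm outside the temperature grid: fit may be unbounded",
             "range_warning")
  y <- .melt_model(temps, tm, dh_vh,
                   baselines$folded[1], baselines$folded[2],
                   baselines$unfolded[1], baselines$unfolded[2])
  nz <- .residue_noise(config, paste0("melt:", condition), length(temps))
  melting_curve(temps, y + nz, condition = condition)
}
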