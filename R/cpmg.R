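#' Effective transverse relaxation rate from constant-time CPMG intensities
#'
#' \deqn{R_2^{eff} = -\ln(I(\nu_{CPMG})/I_0)/T_{CP}}
#'
#' @param i_nu peak intensity with the CPMG block at a given pulse
#'   frequency.
#' @param i0 reference intensity (no CPMG block).
#' @param t_cp constant-time relaxation delay in s (0.05 typical).
#' @return R2eff in s^-1 (vectorized).
#' @examples
#' r2eff_from_intensity(50, 100, 0.05)  # ln(2)/0.05
#' @export
r2eff_from_intensity <- function(i_nu, i0, t_cp) {
  if (any(i0 <= 0) || any(i_nu <= 0))
    nmr_error("intensities must be positive (peak broadened beyond detection?)",
              "domain_error")
  if (t_cp <= 0)
    nmr_error("t_cp must be positive", "domain_error")
  -log(i_nu / i0) / t_cp
}

#' Two-state exchange parameters
#'
#' Parameters of a two-site conformational exchange A <-> B with A the
#' major state: minor population p_b (= 1 - p_a <= 0.5), total exchange
#' rate kex = k_AB + k_BA (s^-1), 15N shift difference between the states
#' in ppm, optional 1H shift difference (0 for single-quantum
#' dispersions), and the exchange-free intrinsic rate R20 (taken equal in
#' both states).
#'
#' @param p_b minor-state population, in `[0, 0.5]` (0 = no exchange).
#' @param delta_omega_n |Delta omega| for 15N, ppm (>= 0).
#' @param kex total exchange rate, s^-1.
#' @param r20 intrinsic transverse rate, s^-1.
#' @param delta_omega_h 1H shift difference, ppm (0 for SQ).
#' @return object of class `exchange_params`.
#' @export
exchange_params <- function(p_b, delta_omega_n, kex, r20,
                            delta_omega_h = 0) {
  if (p_b < 0 || p_b > 0.5)
    nmr_error("p_b must lie in [0, 0.5]", "domain_error")
  if (delta_omega_n < 0)
    nmr_error("delta_omega_n must be nonnegative (ppm)", "domain_error")
  if (kex <= 0)
    nmr_error("kex must be positive", "domain_error")
  if (r20 <= 0)
    nmr_error("r20 must be positive", "domain_error")
  structure(list(p_a = 1 - p_b, p_b = p_b,
                 delta_omega_n = delta_omega_n,
                 delta_omega_h = delta_omega_h,
                 kex = kex, r20 = r20),
            class = "exchange_params")
}

#' @export
print.exchange_params <- function(x, ...) {
  cat(sprintf(
    "two-state exchange: p_b = %.2f%%, dw(15N) = %.3f ppm, kex = %.1f s^-1, R20 = %.2f s^-1\n",
    100 * x$p_b, x$delta_omega_n, x$kex, x$r20))
  invisible(x)
}

# complex-safe acosh: log(z + sqrt(z - 1) * sqrt(z + 1))
.acosh_c <- function(z) {
  z <- as.complex(z)
  log(z + sqrt(z - 1) * sqrt(z + 1))
}

# Carver-Richards-type dominant eigenvalue of the CPMG cycle propagator.
# All frequencies in rad/s; dwh = 0 gives the single-quantum expression.
# Complex throughout so the multiple-quantum case (dwh != 0) and the
# slow-exchange branch (argument of acosh < 1) are handled uniformly.
.cr_lambda1 <- function(pb, dwn, dwh, kex, r20, delta) {
  pa <- 1 - pb
  idwh <- 1i * dwh
  psi <- (idwh + (pa - pb) * kex)^2 - dwn^2 + 4 * pa * pb * kex^2
  zeta <- -2 * dwn * (idwh + (pa - pb) * kex)
  root <- sqrt(psi^2 + zeta^2)
  dpl <- 0.5 * ((psi + 2 * dwn^2) / root + 1)
  dmi <- 0.5 * ((psi + 2 * dwn^2) / root - 1)
  eta_p <- sqrt(2) * delta * sqrt(root + psi)
  eta_m <- sqrt(2) * delta * sqrt(root - psi)
  arg <- dpl * cosh(eta_p) - dmi * cos(eta_m)
  r20 + 0.5 * (kex - (1 / (2 * delta)) * .acosh_c(arg))
}

# Korzhnev amplitude factor Q accounting for magnetization mode mixing
# over the n-cycle CPMG train; reduces to ~1 away from slow exchange.
.cr_q <- function(pb, dwn, dwh, kex, delta) {
  pa <- 1 - pb
  dpl <- (dwh + dwn) + 1i * kex
  dmi <- (dwh + dwn) - 1i * kex
  zpl <- (dwh - dwn) + 1i * kex
  zmi <- (dwh - dwn) - 1i * kex
  mD <- 1i * kex * sqrt(pa * pb) / (dpl * zpl) *
    (zpl + 2 * dwn * sin(zpl * delta) / sin((dpl + zpl) * delta))
  mZ <- -1i * kex * sqrt(pa * pb) / (dmi * zmi) *
    (dmi - 2 * dwn * sin(dmi * delta) / sin((dmi + zmi) * delta))
  Re(1 - mD^2 + mD * mZ - mZ^2 + 0.5 * (mD + mZ) * sqrt(pb / pa))
}

# Exact SQ dispersion: spectral decomposition of the one-cycle propagator.
# One delta-180-2delta-180-delta cycle with ideal pulses is the linear map
# U = P(delta) conj(P(2delta)) P(delta) on the two-site transverse
# magnetization; the signal after n = t_cp*nu cycles is the A-component of
# U^n applied to the equilibrium vector, evaluated in closed form from the
# eigenvalues/eigenvectors of U (no propagation loop).
.sq_exact <- function(pb, dwn, kex, r20, nu, t_cp) {
  pa <- 1 - pb
  a <- matrix(c(-r20 - pb * kex, pa * kex,
                pb * kex, -r20 - pa * kex + 1i * dwn),
              2, 2, byrow = TRUE)
  ac <- Conj(a)
  vapply(seq_along(nu), function(i) {
    delta <- 1 / (4 * nu[i])
    n <- t_cp * nu[i]
    p1 <- .expm2(a, delta)
    u <- p1 %*% .expm2(ac, 2 * delta) %*% p1
    tr <- u[1, 1] + u[2, 2]
    det_u <- u[1, 1] * u[2, 2] - u[1, 2] * u[2, 1]
    disc <- sqrt(as.complex(tr^2 - 4 * det_u))
    mu1 <- (tr + disc) / 2
    mu2 <- (tr - disc) / 2
    m0 <- c(pa, pb)
    if (Mod(mu1 - mu2) < 1e-14 * Mod(mu1)) {
      # defective/degenerate cycle map: fall back to direct powering
      s <- m0
      for (k in seq_len(max(1, round(n)))) s <- u %*% s
      return(-log(Mod(s[1]) / pa) / t_cp)
    }
    # eigenvectors (u12, mu - u11); guard the diagonal case
    if (Mod(u[1, 2]) > 1e-300) {
      v1 <- c(u[1, 2], mu1 - u[1, 1])
      v2 <- c(u[1, 2], mu2 - u[1, 1])
    } else {
      v1 <- c(1, 0); v2 <- c(0, 1)
    }
    den <- v1[1] * v2[2] - v2[1] * v1[2]
    a1 <- (m0[1] * v2[2] - v2[1] * m0[2]) / den
    a2 <- (v1[1] * m0[2] - m0[1] * v1[2]) / den
    s_a <- a1 * v1[1] * exp(n * log(mu1)) + a2 * v2[1] * exp(n * log(mu2))
    -log(Mod(s_a) / pa) / t_cp
  }, numeric(1))
}

#' Closed-form two-state CPMG dispersion profile
#'
#' Effective transverse relaxation rate of the major-state resonance
#' under a constant-time CPMG train with ideal pulses and equal intrinsic
#' rates in both states.
#'
#' For single-quantum dispersions (`delta_omega_h = 0`, the default) the
#' closed form is exact: the Carver-Richards dominant eigenvalue of the
#' CPMG cycle propagator together with the exact amplitude factor, both
#' obtained from the analytic spectral decomposition of the one-cycle
#' evolution map. [bm_oracle()] verifies it by independent step-by-step
#' propagation. For multiple-quantum dispersions (`delta_omega_h != 0`)
#' the Korzhnev closed-form expression (eigenvalue plus
#' \eqn{-\ln(Q)/T_{CP}} mode-mixing correction) is used.
#'
#' Schedule algebra: the quarter-echo delay is \eqn{\delta =
#' 1/(4\nu_{CPMG})} and the train contains \eqn{n = T_{CP}\,\nu_{CPMG}}
#' four-delta cycles; non-integral `n` is accepted by the closed form.
#'
#' @param params [exchange_params()]. `delta_omega_n`/`delta_omega_h` in
#'   ppm are converted to rad/s at the field's 15N (resp. 1H) Larmor
#'   frequency.
#' @param nu CPMG pulse-train frequencies in Hz (vectorized, > 0).
#' @param field_mhz spectrometer 1H frequency, MHz.
#' @param t_cp constant-time delay, s.
#' @return R2eff in s^-1, one value per `nu`.
#' @examples
#' ep <- exchange_params(p_b = 0.03, delta_omega_n = 0.3, kex = 600, r20 = 8)
#' cr_dispersion(ep, c(40, 80, 960), 800, 0.05)
#' @export
cr_dispersion <- function(params, nu, field_mhz, t_cp = 0.05) {
  stopifnot(inherits(params, "exchange_params"))
  if (any(nu <= 0))
    nmr_error("nu_cpmg must be positive", "domain_error")
  dwn <- ppm_to_rads(params$delta_omega_n, field_mhz)
  dwh <- params$delta_omega_h * 2 * pi * field_mhz  # 1H: ppm * MHz * 2pi
  if (params$p_b == 0 || (dwn == 0 && dwh == 0))
    return(rep(params$r20, length(nu)))
  if (dwh == 0) {
    out <- .sq_exact(params$p_b, dwn, params$kex, params$r20, nu, t_cp)
  } else {
    delta <- 1 / (4 * nu)
    n_cyc <- t_cp * nu
    lam <- .cr_lambda1(params$p_b, dwn, dwh, params$kex, params$r20, delta)
    q <- .cr_q(params$p_b, dwn, dwh, params$kex, delta)
    if (any(!is.finite(q)) || any(q <= 0))
      nmr_error("amplitude factor Q is nonpositive or nonfinite",
                "numerical_error")
    out <- Re(lam) - log(q) / (4 * n_cyc * delta)
  }
  if (any(!is.finite(out)))
    nmr_error("dispersion evaluation returned nonfinite values",
              "numerical_error")
  out
}

# 2x2 complex matrix exponential via eigendecomposition (Sylvester form),
# specialized for the Bloch-McConnell evolution matrix.
.expm2 <- function(a, t) {
  tr <- a[1, 1] + a[2, 2]
  det_a <- a[1, 1] * a[2, 2] - a[1, 2] * a[2, 1]
  disc <- sqrt(as.complex(tr^2 - 4 * det_a))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  if (Mod(l1 - l2) < 1e-12) {
    e <- exp(l1 * t)
    return(e * (diag(2) + t * (a - l1 * diag(2))))
  }
  e1 <- exp(l1 * t); e2 <- exp(l2 * t)
  (e1 * (a - l2 * diag(2)) - e2 * (a - l1 * diag(2))) / (l1 - l2)
}

#' Bloch-McConnell propagation oracle for SQ CPMG dispersion
#'
#' Numerically exact R2eff for two-site exchange under an ideal-pulse
#' constant-time CPMG train: transverse magnetization (complex, two
#' sites) is propagated through alternating free-precession blocks and
#' ideal 180-degree pulses (implemented as complex conjugation), one
#' delta-180-2delta-180-delta cycle per 1/nu. The reported rate is
#' \eqn{-\ln(|M_A(T_{CP})|/p_A)/T_{CP}} for the major-state resonance.
#'
#' This is an independent verification route for [cr_dispersion()]; it is
#' deliberately free of the closed form's algebra.
#'
#' @inheritParams cr_dispersion
#' @return R2eff in s^-1, one value per `nu`.
#' @export
bm_oracle <- function(params, nu, field_mhz, t_cp = 0.05) {
  stopifnot(inherits(params, "exchange_params"))
  n_cyc <- t_cp * nu
  bad <- abs(n_cyc - round(n_cyc)) > 0.01 | round(n_cyc) < 1
  if (any(bad))
    nmr_error(sprintf(
      "t_cp * nu must be an integral echo-cycle count; offending nu: %s",
      paste(nu[bad], collapse = ", ")), "schedule_error")
  dwn <- ppm_to_rads(params$delta_omega_n, field_mhz)
  pa <- params$p_a; pb <- params$p_b
  if (pb == 0) return(rep(params$r20, length(nu)))
  kab <- pb * params$kex
  kba <- pa * params$kex
  # free-precession evolution: A on resonance, B offset by dwn
  a <- matrix(c(-params$r20 - kab, kba,
                kab, -params$r20 - kba + 1i * dwn),
              2, 2, byrow = TRUE)
  vapply(seq_along(nu), function(i) {
    n <- round(n_cyc[i])
    delta <- 1 / (4 * nu[i])
    p1 <- .expm2(a, delta)
    p2 <- .expm2(a, 2 * delta)
    m <- c(pa, pb)
    for (k in seq_len(n)) {
      m <- p1 %*% m
      m <- Conj(m)
      m <- p2 %*% m
      m <- Conj(m)
      m <- p1 %*% m
    }
    -log(Mod(m[1]) / pa) / t_cp
  }, numeric(1))
}

#' Dispersion amplitude between two CPMG frequencies
#'
#' \eqn{\Delta R_2^{eff} = R_2^{eff}(\nu_{low}) - R_2^{eff}(\nu_{high})},
#' the standard scalar summary of a dispersion profile. A residue is
#' flagged as dispersing when the amplitude strictly exceeds
#' `flag_threshold` (4 s^-1 by convention).
#'
#' @param curve data.frame with columns `nu_cpmg_hz` and `r2eff` for one
#'   residue at one field.
#' @param nu_low,nu_high the two frequencies to difference, Hz.
#' @param flag_threshold dispersion-significance cutoff, s^-1.
#' @return list with `delta_r2eff` (s^-1) and `dispersing` (logical).
#' @export
delta_r2eff <- function(curve, nu_low = 80, nu_high = 960,
                        flag_threshold = 4) {
  pick <- function(nu) {
    j <- which(abs(curve$nu_cpmg_hz - nu) < 1e-6)
    if (!length(j))
      nmr_error(sprintf("nu = %g Hz not present in curve", nu),
                "schedule_error")
    mean(curve$r2eff[j])
  }
  d <- pick(nu_low) - pick(nu_high)
  list(delta_r2eff = d, dispersing = d > flag_threshold)
}

# weighted residuals of a global two-field dispersion model
.disp_resid <- function(par, dat, t_cp) {
  # par: log-ish transformed (pb, dw_ppm, kex, r20 per field)
  pb <- par[1]; dw <- par[2]; kex <- par[3]
  unlist(lapply(seq_along(dat), function(i) {
    d <- dat[[i]]
    ep <- exchange_params(p_b = pb, delta_omega_n = dw, kex = kex,
                          r20 = par[3 + i])
    pred <- cr_dispersion(ep, d$nu, d$field, t_cp)
    (d$r2eff - pred) * d$w
  }))
}

#' Global two-field fit of a two-state dispersion model
#'
#' Fits (p_b, delta_omega_N, kex) shared across fields with one intrinsic
#' rate R20 per field, by weighted least squares on R2eff. Multi-start
#' over a coarse (p_b, delta_omega, kex) grid; best reduced chi-square
#' wins, ties broken toward the smaller kex. Curves whose largest
#' dispersion amplitude is below `min_amplitude` are reported as
#' no-exchange (p_b pinned to 0) rather than fitted.
#'
#' Parameter uncertainties, when `n_mc > 0` and R2eff errors are
#' available, come from Monte-Carlo resampling of the R2eff values.
#'
#' @param curves data.frame with columns `field_mhz`, `nu_cpmg_hz`,
#'   `r2eff` and optionally `r2eff_err`, covering >= 2 fields with >= 8
#'   frequencies each (one residue).
#' @param t_cp constant-time delay, s.
#' @param min_amplitude flat-curve guard, s^-1.
#' @param n_mc Monte-Carlo draws for parameter SEs (0 = none).
#' @param seed seed for the Monte-Carlo resampling.
#' @param start_grid optional list(p_b=, dw=, kex=) overriding the
#'   default multi-start grid.
#' @return object of class `dispersion_fit`: `p_b`, `delta_omega_n`,
#'   `kex`, per-field `r20`, SEs (NA unless `n_mc > 0`), `chi2_red`,
#'   `no_exchange`, and the multi-start diagnostics table.
#' @export
fit_two_state <- function(curves, t_cp = 0.05, min_amplitude = 1,
                          n_mc = 0, seed = NULL, start_grid = NULL) {
  req <- c("field_mhz", "nu_cpmg_hz", "r2eff")
  miss <- setdiff(req, names(curves))
  if (length(miss))
    nmr_error(paste("dispersion table missing column(s):",
                    paste(miss, collapse = ", ")), "schema_error")
  fields <- sort(unique(curves$field_mhz))
  if (length(fields) < 2L)
    nmr_error(paste("two-state dispersion fitting requires >= 2 fields;",
                    "p_b and delta_omega are degenerate at a single field"),
              "insufficient_data_error")
  dat <- lapply(fields, function(f) {
    sub <- curves[curves$field_mhz == f, ]
    if (length(unique(sub$nu_cpmg_hz)) < 8L)
      nmr_error(sprintf("field %g MHz: need >= 8 CPMG frequencies", f),
                "insufficient_data_error")
    err <- if ("r2eff_err" %in% names(sub)) sub$r2eff_err else rep(0, nrow(sub))
    w <- if (all(is.finite(err)) && all(err > 0)) 1 / err else rep(1, nrow(sub))
    list(field = f, nu = sub$nu_cpmg_hz, r2eff = sub$r2eff, w = w)
  })
  # Flat-curve guard: amplitude across each field. The 'min_amplitude'
  # cutoff is meant for measured data with uncertainties; exact curves
  # (no/zero errors) are only called flat at machine-flatness level, so
  # that genuinely small but noiseless dispersions are still fitted.
  amp <- max(vapply(dat, function(d) {
    o <- order(d$nu)
    mean(d$r2eff[o][seq_len(min(3, length(o)))]) -
      mean(rev(d$r2eff[o])[seq_len(min(3, length(o)))])
  }, numeric(1)))
  npts <- sum(vapply(dat, function(d) length(d$nu), numeric(1)))
  has_err <- "r2eff_err" %in% names(curves) &&
    any(is.finite(curves$r2eff_err) & curves$r2eff_err > 0)
  amp_cut <- if (has_err) min_amplitude else 1e-3
  if (amp < amp_cut) {
    r20 <- vapply(dat, function(d) mean(d$r2eff), numeric(1))
    return(structure(list(
      p_b = 0, delta_omega_n = NA_real_, kex = NA_real_,
      r20 = setNames(r20, paste0("r20_", fields)),
      p_b_se = NA_real_, delta_omega_n_se = NA_real_, kex_se = NA_real_,
      chi2_red = NA_real_, no_exchange = TRUE, fields = fields,
      starts = NULL), class = "dispersion_fit"))
  }
  grid <- if (is.null(start_grid))
    list(p_b = c(0.01, 0.03, 0.08, 0.15), dw = c(0.1, 0.3, 0.6, 1.0),
         kex = c(100, 400, 1000, 3000))
  else start_grid
  r20_init <- vapply(dat, function(d) max(min(d$r2eff), 0.5), numeric(1))
  lower <- c(1e-6, 1e-4, 1, rep(0.1, length(fields)))
  upper <- c(0.5, 10, 5e4, rep(200, length(fields)))
  starts <- expand.grid(p_b = grid$p_b, dw = grid$dw, kex = grid$kex)
  results <- lapply(seq_len(nrow(starts)), function(i) {
    par0 <- c(starts$p_b[i], starts$dw[i], starts$kex[i], r20_init)
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, lower = lower, upper = upper,
                         fn = .disp_resid, dat = dat, t_cp = t_cp,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = fit$par, rss = sum(fit$fvec^2))
  })
  results <- Filter(Negate(is.null), results)
  if (!length(results))
    nmr_error("no multi-start converged for dispersion fit", "fit_error")
  rss <- vapply(results, `[[`, numeric(1), "rss")
  kexs <- vapply(results, function(r) r$par[3], numeric(1))
  best_rss <- min(rss)
  cand <- which(rss <= best_rss * (1 + 1e-9))
  best <- results[[cand[which.min(kexs[cand])]]]
  ndf <- npts - length(best$par)
  starts_tab <- data.frame(starts, rss = rss)

  mc <- list(p_b = NA_real_, dw = NA_real_, kex = NA_real_)
  if (n_mc > 0) {
    errs <- unlist(lapply(dat, function(d)
      ifelse(d$w > 0 & is.finite(1 / d$w), 1 / d$w, 0)))
    if (any(errs > 0)) {
      if (!is.null(seed)) set.seed(seed)
      draws <- replicate(n_mc, {
        dat_mc <- dat
        for (i in seq_along(dat_mc)) {
          e <- ifelse(is.finite(1 / dat_mc[[i]]$w), 1 / dat_mc[[i]]$w, 0)
          dat_mc[[i]]$r2eff <- dat_mc[[i]]$r2eff + rnorm(length(e), 0, e)
        }
        f <- tryCatch(
          minpack.lm::nls.lm(best$par, lower = lower, upper = upper,
                             fn = .disp_resid, dat = dat_mc, t_cp = t_cp,
                             control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(f)) rep(NA_real_, 3) else f$par[1:3]
      })
      mc <- list(p_b = sd(draws[1, ], na.rm = TRUE),
                 dw = sd(draws[2, ], na.rm = TRUE),
                 kex = sd(draws[3, ], na.rm = TRUE))
    }
  }
  structure(list(
    p_b = best$par[1], delta_omega_n = best$par[2], kex = best$par[3],
    r20 = setNames(best$par[-(1:3)], paste0("r20_", fields)),
    p_b_se = mc$p_b, delta_omega_n_se = mc$dw, kex_se = mc$kex,
    chi2_red = best$rss / max(ndf, 1), no_exchange = FALSE,
    fields = fields, starts = starts_tab), class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  if (x$no_exchange) {
    cat("no detectable exchange (flat dispersion); p_b pinned to 0\n")
  } else {
    cat(sprintf(
      "two-state fit: p_b = %.2f%%, dw(15N) = %.3f ppm, kex = %.1f s^-1\n",
      100 * x$p_b, x$delta_omega_n, x$kex))
    cat(sprintf("  %s; reduced chi2 = %.3g\n",
                paste(sprintf("%s = %.2f", names(x$r20), x$r20),
                      collapse = ", "), x$chi2_red))
  }
  invisible(x)
}
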