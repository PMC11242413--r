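#' Thermal melting curve
#'
#' @param temperature_c temperature grid in Celsius, strictly increasing,
#'   >= 10 points.
#' @param ellipticity CD ellipticity (mdeg or molar units) at each
#'   temperature.
#' @param condition free-text condition label.
#' @return object of class `melting_curve`.
#' @export
melting_curve <- function(temperature_c, ellipticity, condition = "") {
  if (length(temperature_c) != length(ellipticity))
    nmr_error("temperature and ellipticity lengths differ", "domain_error")
  if (length(temperature_c) < 10L)
    nmr_error("need >= 10 temperature points", "insufficient_data_error")
  if (any(diff(temperature_c) <= 0))
    nmr_error("temperatures must be strictly increasing", "schedule_error")
  structure(list(temperature_c = temperature_c, ellipticity = ellipticity,
                 condition = condition), class = "melting_curve")
}

#' Two-state unfolded fraction
#'
#' van't Hoff two-state equilibrium with \eqn{\Delta C_p = 0}:
#' \deqn{f_U(T) = \frac{K}{1 + K}, \qquad
#'   K = \exp\!\left[-\frac{\Delta H_{vH}}{R}\left(\frac{1}{T} -
#'   \frac{1}{T_m}\right)\right]}
#' with temperatures in kelvin; \eqn{f_U(T_m) = 1/2} exactly.
#'
#' @param temperature_c temperature in Celsius (vectorized).
#' @param tm_c melting temperature, Celsius.
#' @param dh_kj van't Hoff enthalpy, kJ/mol (> 0).
#' @return unfolded fraction in `[0, 1]`.
#' @export
unfolded_fraction <- function(temperature_c, tm_c, dh_kj) {
  if (dh_kj <= 0) nmr_error("dh_kj must be positive", "domain_error")
  t_k <- temperature_c + 273.15
  tm_k <- tm_c + 273.15
  k <- exp(-dh_kj / .GAS_KJ * (1 / t_k - 1 / tm_k))
  k / (1 + k)
}

# full six-parameter two-state melt model with linear baselines
.melt_model <- function(t_c, tm, dh, bf0, bf1, bu0, bu1) {
  f <- unfolded_fraction(t_c, tm, dh)
  (bf0 + bf1 * t_c) * (1 - f) + (bu0 + bu1 * t_c) * f
}

#' Fit a two-state thermal unfolding curve
#'
#' Six-parameter fit (Tm, van't Hoff enthalpy, linear folded and unfolded
#' baselines) of an ellipticity-versus-temperature melt. The curve must
#' actually span a transition: the baseline-to-baseline signal change has
#' to exceed `amplitude_factor` times the residual scale of the flat
#' ends, otherwise a fit error is raised.
#'
#' @param curve [melting_curve()].
#' @param amplitude_factor transition-detection multiple.
#' @return object of class `unfolding_fit` with `tm_c`, `tm_se`, `dh_kj`,
#'   `dh_se`, `baselines` (bf0, bf1, bu0, bu1), `rss`, `condition`.
#' @export
fit_melting <- function(curve, amplitude_factor = 3) {
  stopifnot(inherits(curve, "melting_curve"))
  t_c <- curve$temperature_c
  y <- curve$ellipticity
  n <- length(t_c)
  edge <- max(3L, floor(0.15 * n))
  head_i <- seq_len(edge); tail_i <- seq(n - edge + 1L, n)
  # transition detection: a single straight line must NOT already explain
  # the data at the edge-noise level (catches flat curves and pure
  # baseline drift alike)
  scatter <- function(i) {
    r <- resid(lm(y[i] ~ t_c[i]))
    sqrt(mean(r^2))
  }
  noise <- max(scatter(head_i), scatter(tail_i))
  lin_rms <- sqrt(mean(resid(lm(y ~ t_c))^2))
  floor_rms <- max(amplitude_factor * noise,
                   1e-9 * max(diff(range(y)), 1e-12))
  if (!is.finite(lin_rms) || lin_rms <= floor_rms)
    nmr_error("no thermal transition detected (flat curve or baseline-dominated)",
              "fit_error")
  # starts: Tm at the steepest point of a smoothed derivative
  dy <- diff(y) / diff(t_c)
  tm0 <- t_c[which.max(abs(dy))]
  bf0_0 <- coef(lm(y[head_i] ~ t_c[head_i]))
  bu0_0 <- coef(lm(y[tail_i] ~ t_c[tail_i]))
  fit <- NULL
  for (dh0 in c(250, 120, 400)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .melt_model(t_c, tm, dh, bf0, bf1, bu0, bu1),
        start = list(tm = tm0, dh = dh0,
                     bf0 = bf0_0[[1]], bf1 = bf0_0[[2]],
                     bu0 = bu0_0[[1]], bu1 = bu0_0[[2]]),
        lower = c(tm = min(t_c) - 20, dh = 1, bf0 = -Inf, bf1 = -Inf,
                  bu0 = -Inf, bu1 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    nmr_error("two-state melt fit failed to converge", "fit_error")
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 6))
  if (est[["tm"]] < min(t_c) || est[["tm"]] > max(t_c))
    nmr_warn("fitted Tm lies outside the measured temperature range",
             "range_warning")
  structure(list(tm_c = unname(est[["tm"]]), tm_se = unname(se[[1]]),
                 dh_kj = unname(est[["dh"]]), dh_se = unname(se[[2]]),
                 baselines = est[c("bf0", "bf1", "bu0", "bu1")],
                 rss = sum(resid(fit)^2), condition = curve$condition),
            class = "unfolding_fit")
}

#' @export
print.unfolding_fit <- function(x, ...) {
  cat(sprintf("%sTm = %.2f +/- %.2f C, dH_vH = %.0f +/- %.0f kJ/mol\n",
              if (nzchar(x$condition)) paste0(x$condition, ": ") else "",
              x$tm_c, x$tm_se, x$dh_kj, x$dh_se))
  invisible(x)
}

#' Denaturant-induced melting-temperature shift
#'
#' \eqn{\Delta T_m = T_m(\mathrm{reference}) - T_m(\mathrm{perturbed})};
#' positive values mean destabilization by the perturbation.
#'
#' @param fit_reference,fit_perturbed [fit_melting()] results.
#' @return Tm difference in Celsius.
#' @export
delta_tm <- function(fit_reference, fit_perturbed) {
  stopifnot(inherits(fit_reference, "unfolding_fit"),
            inherits(fit_perturbed, "unfolding_fit"))
  fit_reference$tm_c - fit_perturbed$tm_c
}
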