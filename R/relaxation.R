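#' Model-free motional parameters for one residue
#'
#' Container for the Lipari-Szabo / extended model-free description of a
#' backbone N-H vector. The model catalogue follows common usage:
#' \describe{
#'   \item{1}{S2 only (internal motion too fast to contribute)}
#'   \item{2}{S2 and internal correlation time tau_e}
#'   \item{3}{S2 and conformational exchange Rex}
#'   \item{4}{S2, tau_e and Rex}
#'   \item{5}{extended: fast/slow order parameters Sf2, Ss2 and slow
#'     internal time tau_s (S2 = Sf2 * Ss2)}
#' }
#'
#' @param model model id, 1-5.
#' @param s2 squared generalized order parameter (models 1-4).
#' @param s2f,s2s fast/slow squared order parameters (model 5).
#' @param tau_m overall isotropic rotational correlation time, ns.
#' @param tau_loc internal correlation time (tau_e or tau_s), ps.
#' @param rex exchange contribution to R2 in s^-1 at the measurement field.
#' @return object of class `model_free_params`.
#' @examples
#' model_free_params(model = 2, s2 = 0.85, tau_m = 4, tau_loc = 50)
#' @export
model_free_params <- function(model = 2L, s2 = NULL, s2f = NULL, s2s = NULL,
                              tau_m, tau_loc = 0, rex = 0) {
  model <- as.integer(model)
  if (!model %in% 1:5)
    nmr_error("'model' must be one of 1..5", "domain_error")
  if (model == 5L) {
    if (is.null(s2f) || is.null(s2s))
      nmr_error("model 5 requires s2f and s2s", "domain_error")
    s2 <- s2f * s2s
  } else {
    if (is.null(s2))
      nmr_error("models 1-4 require s2", "domain_error")
    s2f <- 1
    s2s <- s2
  }
  if (model %in% c(1L, 3L)) tau_loc <- 0
  if (!model %in% c(3L, 4L)) rex <- rex  # rex allowed but only fitted in 3/4
  if (s2 < 0 || s2 > 1 || s2f < 0 || s2f > 1 || s2s < 0 || s2s > 1)
    nmr_error("order parameters must lie in [0, 1]", "domain_error")
  if (s2 > s2f + 1e-12)
    nmr_error("requires s2 <= s2f", "domain_error")
  if (tau_m <= 0)
    nmr_error("tau_m must be positive (ns)", "domain_error")
  if (tau_loc < 0 || tau_loc * 1e-3 >= tau_m)
    nmr_error("tau_loc (ps) must be nonnegative and smaller than tau_m",
              "domain_error")
  if (rex < 0)
    nmr_error("rex must be nonnegative", "domain_error")
  structure(list(model = model, s2 = s2, s2f = s2f, s2s = s2s,
                 tau_m = tau_m, tau_loc = tau_loc, rex = rex),
            class = "model_free_params")
}

#' @export
print.model_free_params <- function(x, ...) {
  cat(sprintf(
    "model-free params (model %d): S2 = %.3f (Sf2 %.3f, Ss2 %.3f), tau_m = %.2f ns, tau_loc = %.1f ps, Rex = %.2f s^-1\n",
    x$model, x$s2, x$s2f, x$s2s, x$tau_m, x$tau_loc, x$rex))
  invisible(x)
}

#' Model-free spectral density function
#'
#' Evaluates the (extended) Lipari-Szabo spectral density
#' \deqn{J(\omega) = \frac{2}{5} S_f^2 \left[ \frac{S_s^2 \tau_m}
#'   {1 + (\omega\tau_m)^2} + \frac{(1 - S_s^2)\,\tau}{1 + (\omega\tau)^2}
#'   \right], \quad \tau = \frac{\tau_s \tau_m}{\tau_s + \tau_m}}
#' which reduces to the classic one-timescale form when \eqn{S_f^2 = 1}.
#'
#' @param params a [model_free_params()] object.
#' @param omega angular frequency (rad/s), vectorized, nonnegative.
#' @return J(omega) in s/rad.
#' @examples
#' p <- model_free_params(model = 1, s2 = 1, tau_m = 4)
#' spectral_density(p, 0)  # 2/5 * 4 ns = 1.6e-9 s/rad
#' @export
spectral_density <- function(params, omega) {
  stopifnot(inherits(params, "model_free_params"))
  if (any(omega < 0))
    nmr_error("omega must be nonnegative", "domain_error")
  tm <- params$tau_m * 1e-9
  ts <- params$tau_loc * 1e-12
  j <- params$s2s * tm / (1 + (omega * tm)^2)
  if (ts > 0) {
    tau <- ts * tm / (ts + tm)
    j <- j + (1 - params$s2s) * tau / (1 + (omega * tau)^2)
  }
  0.4 * params$s2f * j
}

#' 15N relaxation rates from model-free parameters
#'
#' Computes R1, R2 and the steady-state heteronuclear NOE from the
#' dipolar + CSA relaxation expressions, with the spectral density taken
#' from [spectral_density()]:
#' \deqn{R_1 = \frac{d^2}{4}\left[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)\right] + c^2 J(\omega_N)}
#' \deqn{R_2 = \frac{d^2}{8}\left[4J(0) + J(\omega_H-\omega_N) +
#'   3J(\omega_N) + 6J(\omega_H) + 6J(\omega_H+\omega_N)\right] +
#'   \frac{c^2}{6}\left[4J(0) + 3J(\omega_N)\right] + R_{ex}}
#' \deqn{NOE = 1 + \frac{d^2}{4}\frac{\gamma_H}{\gamma_N}\frac{1}{R_1}
#'   \left[6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)\right]}
#' Because \eqn{\gamma_N < 0} the NOE never exceeds 1.
#'
#' Rex is parameterized at `rex_field_mhz` and scaled with the square of
#' the static field when rates at another field are requested.
#'
#' @param params [model_free_params()].
#' @param constants [spin_constants()].
#' @param rex_field_mhz field (1H MHz) at which `params$rex` is defined;
#'   defaults to the field in `constants` (no rescaling).
#' @return named list with elements `r1`, `r2`, `noe` (s^-1, s^-1,
#'   dimensionless).
#' @export
rates_from_model <- function(params, constants,
                             rex_field_mhz = constants$field_mhz) {
  stopifnot(inherits(params, "model_free_params"),
            inherits(constants, "spin_constants"))
  wh <- constants$omega_h
  wn <- constants$omega_n
  j <- spectral_density(params, c(0, wh - wn, wn, wh, wh + wn))
  d2 <- constants$d^2
  c2 <- constants$c2
  r1 <- d2 / 4 * (j[2] + 3 * j[3] + 6 * j[5]) + c2 * j[3]
  rex <- params$rex * (constants$field_mhz / rex_field_mhz)^2
  r2 <- d2 / 8 * (4 * j[1] + j[2] + 3 * j[3] + 6 * j[4] + 6 * j[5]) +
    c2 / 6 * (4 * j[1] + 3 * j[3]) + rex
  noe <- 1 + d2 / 4 * (constants$gamma_h / constants$gamma_n) / r1 *
    (6 * j[5] - j[2])
  list(r1 = r1, r2 = r2, noe = noe)
}

#' Fit a monoexponential decay
#'
#' Two-parameter least-squares fit of \eqn{I(t) = I_0 e^{-R t}} to a
#' relaxation decay series (e.g. T1 or T1rho HSQC peak intensities versus
#' delay). Duplicate delays are used as replicates and enter the fit and
#' its error estimate directly.
#'
#' @param delay_ms relaxation delays in ms (>= 4 distinct values).
#' @param intensity peak intensities (positive, arbitrary units).
#' @return list with `rate` (s^-1), `rate_se`, `i0`, `i0_se`, `rss`.
#' @examples
#' t <- c(10, 80, 200, 320, 500)
#' fit_decay(t, 100 * exp(-2 * t / 1000))$rate  # 2.0 s^-1
#' @export
fit_decay <- function(delay_ms, intensity) {
  if (length(delay_ms) != length(intensity))
    nmr_error("delay and intensity lengths differ", "domain_error")
  keep <- is.finite(delay_ms) & is.finite(intensity)
  delay_ms <- delay_ms[keep]; intensity <- intensity[keep]
  if (length(unique(delay_ms)) < 4L)
    nmr_error("need >= 4 distinct delays", "insufficient_data_error")
  if (any(intensity <= 0))
    nmr_error("intensities must be positive", "domain_error")
  t_s <- delay_ms / 1000
  # log-linear start values; the nonlinear fit refines them
  init <- coef(lm(log(intensity) ~ t_s))
  r0 <- max(-init[[2]], 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ i0 * exp(-r * t_s),
      start = list(i0 = exp(init[[1]]), r = r0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e)
      nmr_error(paste("decay fit failed:", conditionMessage(e)), "fit_error"))
  est <- coef(fit)
  if (est[["r"]] < 1e-4)
    nmr_error("fitted rate is not distinguishable from zero (no decay)",
              "fit_error")
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  list(rate = unname(est[["r"]]), rate_se = unname(se[[2]]),
       i0 = unname(est[["i0"]]), i0_se = unname(se[[1]]),
       rss = sum(resid(fit)^2))
}

#' Convert a rotating-frame rate R1rho to R2
#'
#' Off-resonance correction \eqn{R_2 = (R_{1\rho} - R_1\cos^2\theta) /
#' \sin^2\theta} with \eqn{\tan\theta = \omega_{SL} / \Omega}, where
#' \eqn{\omega_{SL}} is the spin-lock field and \eqn{\Omega} the resonance
#' offset. On resonance (\eqn{\Omega = 0}, \eqn{\theta = \pi/2}) the
#' function returns R1rho unchanged.
#'
#' @param r1rho rotating-frame relaxation rate, s^-1.
#' @param r1 longitudinal rate, s^-1.
#' @param offset_hz resonance offset from the spin-lock carrier, Hz.
#' @param spinlock_hz spin-lock field strength, Hz (1.6 kHz typical).
#' @return R2 in s^-1 (vectorized).
#' @export
r2_from_r1rho <- function(r1rho, r1, offset_hz = 0, spinlock_hz = 1600) {
  if (any(spinlock_hz <= 0))
    nmr_error("spin-lock field must be positive", "domain_error")
  if (any(r1rho < 0))
    nmr_error("r1rho must be nonnegative", "domain_error")
  theta <- atan2(spinlock_hz, offset_hz)
  s2 <- sin(theta)^2
  if (any(s2 < 1e-12))
    nmr_error("sin(theta) = 0: offset correction undefined", "domain_error")
  (r1rho - r1 * cos(theta)^2) / s2
}

#' Assemble per-residue relaxation records from decay and NOE tables
#'
#' Convenience glue from raw measurements to the `(R1, R2, NOE)` records
#' the model-free stage consumes: fits each residue's T1 and T1rho decay
#' with [fit_decay()], converts R1rho to R2 with [r2_from_r1rho()], and
#' forms the NOE as the saturated/unsaturated intensity ratio.
#'
#' @param t1_decays data.frame with columns residue_id, delay_ms, intensity.
#' @param t1rho_decays same layout for the spin-lock experiment.
#' @param noe data.frame with columns residue_id, i_sat, i_unsat and
#'   optionally noe_err.
#' @param field_mhz spectrometer 1H frequency, MHz.
#' @param spinlock_hz spin-lock field, Hz.
#' @param offset_hz per-record resonance offsets (0 = on resonance).
#' @return data.frame in the relaxation-record schema (residue_id,
#'   field_mhz, r1, r1_err, r2, r2_err, noe, noe_err).
#' @export
relaxation_records <- function(t1_decays, t1rho_decays, noe, field_mhz,
                               spinlock_hz = 1600, offset_hz = 0) {
  ids <- sort(unique(t1_decays$residue_id))
  rows <- lapply(ids, function(id) {
    d1 <- t1_decays[t1_decays$residue_id == id, ]
    dr <- t1rho_decays[t1rho_decays$residue_id == id, ]
    nr <- noe[noe$residue_id == id, ]
    if (nrow(dr) == 0L || nrow(nr) == 0L) return(NULL)
    f1 <- fit_decay(d1$delay_ms, d1$intensity)
    fr <- fit_decay(dr$delay_ms, dr$intensity)
    r2 <- r2_from_r1rho(fr$rate, f1$rate, offset_hz, spinlock_hz)
    noe_val <- nr$i_sat[1] / nr$i_unsat[1]
    noe_err <- if ("noe_err" %in% names(nr)) nr$noe_err[1] else NA_real_
    data.frame(residue_id = id, field_mhz = field_mhz,
               r1 = f1$rate, r1_err = f1$rate_se,
               r2 = r2, r2_err = fr$rate_se,
               noe = noe_val, noe_err = noe_err,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
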