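# Fixed physical constants (SI units)
.MU0 <- 4 * pi * 1e-7       # vacuum permeability, T m / A
.PLANCK <- 6.62607015e-34   # Planck constant, J s
.GAS_KJ <- 8.314462618e-3   # gas constant, kJ mol^-1 K^-1

# 15N/1H Larmor frequency ratio used for all ppm <-> rad/s conversions.
.N15_FREQ_RATIO <- 0.101329446

#' Spin-system constants for backbone amide 15N relaxation
#'
#' Bundles the physical constants entering the dipolar (1H-15N) and
#' chemical-shift-anisotropy relaxation mechanisms of a protonated 15N
#' spin, together with the static-field-dependent Larmor frequencies.
#' Defaults are the standard backbone-amide values; every one can be
#' overridden.
#'
#' The derived quantities stored in the result are the dipolar coupling
#' constant \eqn{d = \mu_0 h \gamma_H |\gamma_N| / (8 \pi^2 r_{NH}^3)}
#' (rad/s) and the squared CSA constant \eqn{c^2 = (\omega_N
#' \Delta\sigma)^2 / 3}.
#'
#' @param field_mhz spectrometer 1H frequency in MHz (e.g. 500, 800).
#' @param gamma_h 1H gyromagnetic ratio, rad s^-1 T^-1.
#' @param gamma_n 15N gyromagnetic ratio, rad s^-1 T^-1 (negative).
#' @param r_nh N-H bond length in Angstrom.
#' @param delta_sigma 15N chemical shift anisotropy in ppm.
#' @param n_freq_ratio 15N/1H Larmor frequency magnitude ratio.
#' @return an object of class `spin_constants`.
#' @examples
#' sc <- spin_constants(500)
#' sc$omega_n / (2 * pi) / 1e6  # 15N Larmor frequency, MHz
#' @export
spin_constants <- function(field_mhz,
                           gamma_h = 2.6752218744e8,
                           gamma_n = -2.7116e7,
                           r_nh = 1.02,
                           delta_sigma = -160,
                           n_freq_ratio = .N15_FREQ_RATIO) {
  if (!is.numeric(field_mhz) || length(field_mhz) != 1L || field_mhz <= 0)
    nmr_error("'field_mhz' must be a single positive number", "domain_error")
  if (!(gamma_n < 0 && 0 < gamma_h))
    nmr_error("expected gamma_n < 0 < gamma_h", "domain_error")
  if (r_nh < 0.9 || r_nh > 1.1)
    nmr_error("'r_nh' outside the plausible 0.9-1.1 Angstrom range",
              "domain_error")
  r_m <- r_nh * 1e-10
  omega_h <- 2 * pi * field_mhz * 1e6
  omega_n <- 2 * pi * field_mhz * n_freq_ratio * 1e6
  d <- .MU0 * .PLANCK * gamma_h * abs(gamma_n) / (8 * pi^2 * r_m^3)
  structure(list(
    field_mhz = field_mhz,
    gamma_h = gamma_h, gamma_n = gamma_n,
    r_nh = r_nh, delta_sigma = delta_sigma,
    n_freq_ratio = n_freq_ratio,
    omega_h = omega_h, omega_n = omega_n,
    d = d,
    c2 = (omega_n * delta_sigma * 1e-6)^2 / 3
  ), class = "spin_constants")
}

#' @export
print.spin_constants <- function(x, ...) {
  cat(sprintf("15N spin system at %.1f MHz (1H)\n", x$field_mhz))
  cat(sprintf("  omega_N = 2*pi * %.3f MHz, r_NH = %.2f A, d_sigma = %.0f ppm\n",
              x$omega_n / 2 / pi / 1e6, x$r_nh, x$delta_sigma))
  invisible(x)
}

#' Convert a 15N shift difference from ppm to rad/s
#'
#' @param ppm shift difference in ppm.
#' @param field_mhz spectrometer 1H frequency in MHz.
#' @param n_freq_ratio 15N/1H Larmor ratio.
#' @return angular frequency difference in rad/s.
#' @export
ppm_to_rads <- function(ppm, field_mhz, n_freq_ratio = .N15_FREQ_RATIO) {
  ppm * 2 * pi * field_mhz * n_freq_ratio
}
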