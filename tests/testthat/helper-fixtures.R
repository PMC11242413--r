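# Shared fixtures: published parameter sets and small generator wrappers.

# exchange-parameter triplets (minor population, dw ppm, kex s^-1) from the
# two-field dispersion analysis of the WW4 study
published_exchange <- list(
  T30_none  = c(p_b = 0.100, dw = 0.33, kex = 166.1),
  T28_nascn = c(p_b = 0.101, dw = 0.23, kex = 1064.2),
  G17_gdmcl = c(p_b = 0.024, dw = 0.25, kex = 612.4)
)

# published per-residue dissociation constants (mM, NaSCN titration)
published_kd <- c(R27 = 95.6, T28 = 62.4, T29 = 74.8, T30 = 108.6)

# published melting temperatures (Celsius)
published_tm <- c(no_denaturant = 63.5, gdmcl_200mM = 54.5,
                  nascn_200mM = 60.3)

cpmg_nu <- c(40, 80, 120, 160, 200, 240, 280, 320, 400, 480, 560, 640,
             720, 800, 960)

# noiseless two-field SQ dispersion curves for one parameter triplet
make_two_field_curves <- function(triplet, fields = c(500, 800), r20 = 8,
                                  t_cp = 0.05, nu = cpmg_nu) {
  ep <- exchange_params(p_b = triplet[["p_b"]],
                        delta_omega_n = triplet[["dw"]],
                        kex = triplet[["kex"]], r20 = r20)
  do.call(rbind, lapply(fields, function(f)
    data.frame(field_mhz = f, nu_cpmg_hz = nu,
               r2eff = cr_dispersion(ep, nu, f, t_cp))))
}

# noiseless relaxation record for given model-free parameters
make_record <- function(s2, tau_m = 4, tau_loc = 0, rex = 0,
                        constants = spin_constants(500), id = "X1",
                        rel_err = NA) {
  model <- if (rex > 0 && tau_loc > 0) 4 else if (rex > 0) 3 else
    if (tau_loc > 0) 2 else 1
  p <- model_free_params(model = model, s2 = s2, tau_m = tau_m,
                         tau_loc = tau_loc, rex = rex)
  r <- rates_from_model(p, constants)
  rec <- data.frame(residue_id = id, field_mhz = constants$field_mhz,
                    r1 = r$r1, r2 = r$r2, noe = r$noe,
                    stringsAsFactors = FALSE)
  if (is.finite(rel_err)) {
    rec$r1_err <- rel_err * r$r1
    rec$r2_err <- rel_err * r$r2
    rec$noe_err <- rel_err
  }
  rec
}

# set of rigid (S2 = 1) records across residues, for tau_m estimation
make_rigid_records <- function(n = 10, tau_m = 4,
                               constants = spin_constants(500)) {
  do.call(rbind, lapply(seq_len(n), function(i)
    make_record(1, tau_m = tau_m, constants = constants,
                id = paste0("R", i))))
}

# Luz-Meiboom fast-exchange dispersion closed form (independent oracle)
luz_meiboom <- function(p_b, dw_rads, kex, r20, nu) {
  r20 + (1 - p_b) * p_b * dw_rads^2 / kex *
    (1 - 4 * nu / kex * tanh(kex / (4 * nu)))
}
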