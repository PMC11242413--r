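#' HSQC peak position
#'
#' @param residue_id residue label (e.g. "T28").
#' @param h_ppm 1H chemical shift, ppm.
#' @param n_ppm 15N chemical shift, ppm.
#' @return object of class `peak_position`. Positions outside the usual
#'   backbone-amide windows (1H 5-12 ppm, 15N 100-135 ppm) raise a
#'   warning, not an error.
#' @export
peak_position <- function(residue_id, h_ppm, n_ppm) {
  if (h_ppm < 5 || h_ppm > 12)
    nmr_warn(sprintf("%s: 1H shift %.2f ppm outside the 5-12 ppm amide window",
                     residue_id, h_ppm), "range_warning")
  if (n_ppm < 100 || n_ppm > 135)
    nmr_warn(sprintf("%s: 15N shift %.2f ppm outside the 100-135 ppm amide window",
                     residue_id, n_ppm), "range_warning")
  structure(list(residue_id = as.character(residue_id),
                 h_ppm = h_ppm, n_ppm = n_ppm),
            class = "peak_position")
}

#' Weighted amide chemical shift difference (CSD)
#'
#' The standard integrated 1H/15N index
#' \deqn{CSD = \sqrt{(\Delta^1H)^2 + (\Delta^{15}N/4)^2}}
#' in ppm. `compute_csd` takes two [peak_position()]s of the same residue;
#' `csd_index` is the vectorized low-level form on shift deltas.
#'
#' @param reference,shifted [peak_position()] objects for the same residue.
#' @return CSD in ppm.
#' @examples
#' csd_index(0.06, 0.4)  # sqrt(0.0036 + 0.01)
#' @export
compute_csd <- function(reference, shifted) {
  stopifnot(inherits(reference, "peak_position"),
            inherits(shifted, "peak_position"))
  if (!identical(reference$residue_id, shifted$residue_id))
    nmr_error(sprintf("residue mismatch: '%s' vs '%s'",
                      reference$residue_id, shifted$residue_id),
              "identity_error")
  csd_index(shifted$h_ppm - reference$h_ppm, shifted$n_ppm - reference$n_ppm)
}

#' @rdname compute_csd
#' @param delta_h,delta_n 1H and 15N shift differences in ppm.
#' @export
csd_index <- function(delta_h, delta_n) {
  sqrt(delta_h^2 + (delta_n / 4)^2)
}

#' Titration series of HSQC peak positions
#'
#' @param peaks long-format data.frame with columns `residue_id`,
#'   `concentration_mM`, `h_ppm`, `n_ppm`. The lowest concentration
#'   (typically 0) is the reference point; every residue must be present
#'   there. Missing (exchange-broadened) peaks at other concentrations are
#'   simply absent rows.
#' @param p_total_mM total protein concentration in mM.
#' @return object of class `titration_series`.
#' @export
titration_series <- function(peaks, p_total_mM) {
  req <- c("residue_id", "concentration_mM", "h_ppm", "n_ppm")
  miss <- setdiff(req, names(peaks))
  if (length(miss))
    nmr_error(paste("peak table missing column(s):",
                    paste(miss, collapse = ", ")), "schema_error")
  if (p_total_mM <= 0)
    nmr_error("protein concentration must be positive", "domain_error")
  conc <- sort(unique(peaks$concentration_mM))
  if (any(conc < 0))
    nmr_error("ligand concentrations must be nonnegative", "schedule_error")
  ref_conc <- conc[1]
  ids <- unique(peaks$residue_id)
  at_ref <- unique(peaks$residue_id[peaks$concentration_mM == ref_conc])
  missing_ref <- setdiff(ids, at_ref)
  if (length(missing_ref))
    nmr_error(paste("residue(s) without a reference-point position:",
                    paste(missing_ref, collapse = ", ")), "schema_error")
  structure(list(peaks = peaks, ligand_mM = conc, p_total_mM = p_total_mM,
                 reference_mM = ref_conc),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("HSQC titration: %d residues, %d concentrations (%g-%g mM), [P] = %g mM\n",
              length(unique(x$peaks$residue_id)), length(x$ligand_mM),
              min(x$ligand_mM), max(x$ligand_mM), x$p_total_mM))
  invisible(x)
}

#' Per-residue CSD profile of a titration
#'
#' Computes the weighted shift difference of every residue at every
#' concentration relative to its reference-point position.
#'
#' @param series [titration_series()].
#' @return data.frame (residue_id, concentration_mM, csd) with csd = 0 at
#'   the reference concentration.
#' @export
csd_profile <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  p <- series$peaks
  ref <- p[p$concentration_mM == series$reference_mM, ]
  ref_h <- setNames(ref$h_ppm, ref$residue_id)
  ref_n <- setNames(ref$n_ppm, ref$residue_id)
  out <- data.frame(
    residue_id = p$residue_id,
    concentration_mM = p$concentration_mM,
    csd = csd_index(p$h_ppm - ref_h[p$residue_id],
                    p$n_ppm - ref_n[p$residue_id]),
    stringsAsFactors = FALSE)
  out[order(out$residue_id, out$concentration_mM), , drop = FALSE]
}

#' Flag residues with significant chemical shift perturbation
#'
#' Threshold is mean + 1 SD of the CSDs across residues at the chosen
#' concentration; residues strictly above it are flagged. The SD
#' convention (population n-denominator vs sample n-1) is switchable.
#'
#' @param profile data.frame from [csd_profile()].
#' @param at_concentration concentration (mM) at which to threshold.
#' @param sd_type "population" (default) or "sample".
#' @param exclude residue ids to leave out of the mean/SD (e.g. termini).
#' @return list with `residues` (flagged ids), `threshold`, `csd` (named
#'   vector used).
#' @export
flag_significant <- function(profile, at_concentration,
                             sd_type = c("population", "sample"),
                             exclude = NULL) {
  sd_type <- match.arg(sd_type)
  sub <- profile[profile$concentration_mM == at_concentration, ]
  if (nrow(sub) == 0L)
    nmr_error(sprintf("concentration %g mM not present in profile",
                      at_concentration), "schedule_error")
  sub <- sub[!sub$residue_id %in% exclude, ]
  x <- setNames(sub$csd, sub$residue_id)
  x <- x[is.finite(x)]
  if (length(x) < 3L)
    nmr_error("need >= 3 residues to form a significance threshold",
              "insufficient_data_error")
  s <- if (sd_type == "population")
    sqrt(mean((x - mean(x))^2)) else sd(x)
  thr <- mean(x) + s
  list(residues = names(x)[x > thr], threshold = thr, csd = x)
}

#' One-site quadratic binding isotherm
#'
#' Observed CSD as a function of total ligand concentration under the
#' single-site model, without the free-ligand approximation:
#' \deqn{CSD_{obs} = CSD_{max}\,\frac{([P]+[L]+K_d) -
#'   \sqrt{([P]+[L]+K_d)^2 - 4[P][L]}}{2[P]}}
#'
#' @param ligand_mM total ligand concentration(s), mM.
#' @param p_total_mM total protein concentration, mM.
#' @param kd_mM dissociation constant, mM.
#' @param csd_max_ppm CSD at saturation, ppm.
#' @return CSD in ppm (vectorized over `ligand_mM`).
#' @export
binding_isotherm <- function(ligand_mM, p_total_mM, kd_mM, csd_max_ppm) {
  if (kd_mM <= 0) nmr_error("Kd must be positive", "domain_error")
  if (p_total_mM <= 0) nmr_error("[P] must be positive", "domain_error")
  s <- p_total_mM + ligand_mM + kd_mM
  csd_max_ppm * (s - sqrt(s^2 - 4 * p_total_mM * ligand_mM)) /
    (2 * p_total_mM)
}

#' Fit a per-residue dissociation constant from a CSD titration
#'
#' Least-squares fit of the one-site quadratic isotherm
#' ([binding_isotherm()]) to a residue's CSD-versus-concentration trace,
#' with the protein concentration fixed to the series value. Multi-start:
#' Kd initialized at 10, 50, 100 and 500 mM with CSD_max at 1.2x the
#' largest observed CSD; the best residual wins, ties broken toward the
#' smaller Kd.
#'
#' @param series [titration_series()].
#' @param residue_id residue to fit.
#' @param noise_sd optional per-point noise estimate (ppm) used only for
#'   the reliability flag; defaults to the fit's residual SD.
#' @return object of class `binding_fit`: list with `residue_id`, `kd_mM`,
#'   `kd_se`, `csd_max_ppm`, `csd_max_se`, `rss`, `n`, `reliable`.
#' @export
fit_kd <- function(series, residue_id, noise_sd = NULL) {
  stopifnot(inherits(series, "titration_series"))
  prof <- csd_profile(series)
  sub <- prof[prof$residue_id == residue_id & is.finite(prof$csd), ]
  if (nrow(sub) < 5L)
    nmr_error(sprintf("residue %s: need >= 5 concentration points with CSD",
                      residue_id), "insufficient_data_error")
  conc <- sub$concentration_mM
  y <- sub$csd
  if (suppressWarnings(stats::cor(conc, y)) < 0)
    nmr_warn(sprintf("residue %s: CSD does not increase with concentration",
                     residue_id), "trend_warning")
  p <- series$p_total_mM
  cmax0 <- 1.2 * max(y)
  best <- NULL
  for (kd0 in c(10, 50, 100, 500)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ binding_isotherm(conc, p, kd, cmax),
        start = list(kd = kd0, cmax = max(cmax0, 1e-4)),
        lower = c(kd = 1e-6, cmax = 0),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15 ||
        (abs(rss - best$rss) <= 1e-15 && coef(fit)[["kd"]] < best$kd)) {
      se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
      best <- list(kd = coef(fit)[["kd"]], cmax = coef(fit)[["cmax"]],
                   kd_se = se[[1]], cmax_se = se[[2]], rss = rss)
    }
  }
  if (is.null(best))
    nmr_error(sprintf("residue %s: binding fit failed to converge", residue_id),
              "fit_error")
  if (is.null(noise_sd))
    noise_sd <- sqrt(best$rss / max(1, nrow(sub) - 2))
  if (best$cmax < 0.5 * max(y))
    nmr_warn(sprintf("residue %s: fitted CSD_max below half the largest observed CSD",
                     residue_id), "sanity_warning")
  structure(list(residue_id = residue_id,
                 kd_mM = best$kd, kd_se = best$kd_se,
                 csd_max_ppm = best$cmax, csd_max_se = best$cmax_se,
                 rss = best$rss, n = nrow(sub),
                 reliable = best$cmax >= 3 * noise_sd),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("%s: Kd = %.1f +/- %.1f mM, CSD_max = %.3f +/- %.3f ppm%s\n",
              x$residue_id, x$kd_mM, x$kd_se, x$csd_max_ppm, x$csd_max_se,
              if (x$reliable) "" else "  [flagged unreliable]"))
  invisible(x)
}

#' Fit dissociation constants for every residue in a series
#'
#' @param series [titration_series()].
#' @param residues residue ids to fit (default: all with enough points).
#' @return data.frame (residue_id, kd_mM, kd_se, csd_max_ppm,
#'   csd_max_se, rss, n, reliable); residues whose fit fails are dropped
#'   with a warning.
#' @export
fit_kd_all <- function(series, residues = NULL) {
  if (is.null(residues)) residues <- unique(series$peaks$residue_id)
  rows <- lapply(residues, function(id) {
    f <- tryCatch(suppressWarnings(fit_kd(series, id)), error = function(e) {
      nmr_warn(sprintf("residue %s skipped: %s", id, conditionMessage(e)),
               "fit_skip_warning")
      NULL
    })
    if (is.null(f)) return(NULL)
    data.frame(residue_id = f$residue_id, kd_mM = f$kd_mM, kd_se = f$kd_se,
               csd_max_ppm = f$csd_max_ppm, csd_max_se = f$csd_max_se,
               rss = f$rss, n = f$n, reliable = f$reliable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
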