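# rigid-limit R2/R1 ratio as a function of tau_m (ns); monotone increasing
.rigid_ratio <- function(tau_m, constants) {
  p <- model_free_params(model = 1, s2 = 1, tau_m = tau_m)
  r <- rates_from_model(p, constants)
  r$r2 / r$r1
}

#' Estimate the overall rotational correlation time
#'
#' Estimates the isotropic tumbling time tau_m from the trimmed mean of
#' per-residue R2/R1 ratios over residues passing a rigidity filter
#' (NOE above `noe_min`), by numerically inverting the rigid-limit
#' (S2 = 1, Rex = 0) ratio. Trimming removes residues whose ratio is
#' inflated by exchange or depressed by internal motion.
#'
#' @param records data.frame in the relaxation-record schema (residue_id,
#'   field_mhz, r1, r2, noe, ...).
#' @param constants [spin_constants()] at the records' field.
#' @param noe_min rigidity filter on the heteronuclear NOE.
#' @param trim fraction trimmed from each tail of the R2/R1 distribution.
#' @param dispersion_warn warn when the ratio spread (CV) exceeds this.
#' @return tau_m in ns.
#' @export
estimate_tau_m <- function(records, constants, noe_min = 0.65, trim = 0.1,
                           dispersion_warn = 0.2) {
  ok <- is.finite(records$r1) & is.finite(records$r2) &
    is.finite(records$noe) & records$noe > noe_min &
    records$r1 > 0 & records$r2 > 0
  if (sum(ok) < 5L)
    nmr_error("fewer than 5 residues pass the rigidity filter",
              "estimation_error")
  ratio <- records$r2[ok] / records$r1[ok]
  if (sd(ratio) / mean(ratio) > dispersion_warn)
    nmr_warn("large spread in R2/R1 ratios: heterogeneous tumbling or pervasive exchange?",
             "heterogeneity_warning")
  target <- mean(ratio, trim = trim)
  f <- function(tm) .rigid_ratio(tm, constants) - target
  lo <- 0.5; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    nmr_error("trimmed R2/R1 ratio outside the invertible 0.5-50 ns range",
              "estimation_error")
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# parameter layout per model: named start/lower/upper vectors
.mf_model_pars <- function(model, tau_m) {
  tl_hi <- min(0.999 * tau_m * 1e3, 3000)  # ps
  switch(as.character(model),
    "1" = list(start = list(c(s2 = 0.8)),
               lower = c(s2 = 0), upper = c(s2 = 1)),
    "2" = list(start = list(c(s2 = 0.8, tau_loc = 30),
                            c(s2 = 0.5, tau_loc = 300)),
               lower = c(s2 = 0, tau_loc = 1e-3),
               upper = c(s2 = 1, tau_loc = tl_hi)),
    "3" = list(start = list(c(s2 = 0.8, rex = 1),
                            c(s2 = 0.8, rex = 6)),
               lower = c(s2 = 0, rex = 0),
               upper = c(s2 = 1, rex = 50)),
    "4" = list(start = list(c(s2 = 0.8, tau_loc = 30, rex = 1),
                            c(s2 = 0.6, tau_loc = 300, rex = 4)),
               lower = c(s2 = 0, tau_loc = 1e-3, rex = 0),
               upper = c(s2 = 1, tau_loc = tl_hi, rex = 50)),
    "5" = list(start = list(c(s2f = 0.9, s2s = 0.8, tau_loc = 500),
                            c(s2f = 0.8, s2s = 0.5, tau_loc = 1500)),
               lower = c(s2f = 0, s2s = 0, tau_loc = 1e-3),
               upper = c(s2f = 1, s2s = 1, tau_loc = tl_hi)))
}

.mf_params_from_vec <- function(model, par, tau_m) {
  if (model == 5L)
    model_free_params(model = 5, s2f = par[["s2f"]], s2s = par[["s2s"]],
                      tau_m = tau_m, tau_loc = par[["tau_loc"]])
  else
    model_free_params(model = model, s2 = par[["s2"]], tau_m = tau_m,
                      tau_loc = if ("tau_loc" %in% names(par)) par[["tau_loc"]] else 0,
                      rex = if ("rex" %in% names(par)) par[["rex"]] else 0)
}

# weighted chi-square of one record against one parameter vector; total
# function (large finite penalty on any invalid/non-finite evaluation) so
# box-constrained optimizers never see NaN
.mf_chi2 <- function(par, model, record, tau_m, constants, w) {
  val <- tryCatch({
    p <- .mf_params_from_vec(model, par, tau_m)
    r <- rates_from_model(p, constants)
    sum(w * (c(record$r1, record$r2, record$noe) -
               c(r$r1, r$r2, r$noe))^2)
  }, error = function(e) 1e12)
  if (!is.finite(val)) 1e12 else val
}

#' Model-free fit of one residue's relaxation record
#'
#' Fits the (R1, R2, NOE) triple of one residue at one field over the
#' five-model Lipari-Szabo catalogue (see [model_free_params()]) by
#' weighted least squares (weights 1/SE^2), with the overall correlation
#' time fixed, and selects among converged models by an information
#' criterion: chi2 + 2k ("aic", default) or ascending F-test acceptance
#' ("ftest"). Rex is reported only when a model containing it is
#' selected.
#'
#' Parameter uncertainties, when `n_mc > 0`, come from Monte-Carlo
#' resampling of the observables within their stated errors.
#'
#' @param record one-row data.frame (or list) with r1, r2, noe and
#'   optionally r1_err, r2_err, noe_err.
#' @param tau_m overall correlation time, ns.
#' @param constants [spin_constants()].
#' @param criterion "aic" or "ftest".
#' @param models candidate model ids (subset of 1:5).
#' @param n_mc Monte-Carlo draws for SEs (0 = none).
#' @param seed seed for the Monte-Carlo resampling.
#' @return object of class `model_free_result`: selected `model`,
#'   `params` ([model_free_params()]), per-parameter SEs, `chi2`, and the
#'   per-model score table.
#' @export
fit_residue <- function(record, tau_m, constants,
                        criterion = c("aic", "ftest"), models = 1:5,
                        n_mc = 0, seed = NULL) {
  criterion <- match.arg(criterion)
  obs <- c(record$r1, record$r2, record$noe)
  if (any(!is.finite(obs)))
    nmr_error("record incomplete: R1, R2 and NOE must all be present",
              "insufficient_data_error")
  err <- c(if (!is.null(record$r1_err)) record$r1_err else NA,
           if (!is.null(record$r2_err)) record$r2_err else NA,
           if (!is.null(record$noe_err)) record$noe_err else NA)
  # fall back to 2% (rates) / 0.02 (NOE) weights when errors are absent
  def <- c(0.02 * abs(record$r1), 0.02 * abs(record$r2), 0.02)
  err <- ifelse(is.finite(err) & err > 0, err, def)
  w <- 1 / err^2
  n_obs <- 3L

  fits <- lapply(models, function(m) {
    spec_m <- .mf_model_pars(m, tau_m)
    best <- NULL
    for (st in spec_m$start) {
      o <- tryCatch(
        nlminb(st, .mf_chi2, model = m, record = record, tau_m = tau_m,
               constants = constants, w = w,
               lower = spec_m$lower, upper = spec_m$upper,
               control = list(iter.max = 500, abs.tol = 0,
                              rel.tol = 1e-14, x.tol = 1e-12)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$objective < best$objective) best <- o
    }
    if (is.null(best)) return(NULL)
    k <- length(spec_m$start[[1]])
    list(model = m, par = best$par, chi2 = best$objective, k = k)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    nmr_error("no model-free model converged", "fit_error")

  scores <- vapply(fits, function(f) f$chi2 + 2 * f$k, numeric(1))
  score_tab <- data.frame(
    model = vapply(fits, `[[`, numeric(1), "model"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
    aic = scores)
  if (criterion == "aic") {
    sel <- fits[[which.min(scores)]]
  } else {
    # ascending F-test: start from the simplest model, accept a larger one
    # only when the residual drop is significant at alpha = 0.2
    ord <- order(score_tab$k, score_tab$chi2)
    sel <- fits[[ord[1]]]
    for (j in ord[-1]) {
      f2 <- fits[[j]]
      df1 <- n_obs - sel$k; df2 <- n_obs - f2$k
      if (df2 <= 0 || f2$chi2 >= sel$chi2) next
      fstat <- ((sel$chi2 - f2$chi2) / (df1 - df2)) / (f2$chi2 / df2)
      if (is.finite(fstat) &&
          stats::pf(fstat, df1 - df2, df2, lower.tail = FALSE) < 0.2)
        sel <- f2
    }
  }
  params <- .mf_params_from_vec(sel$model, sel$par, tau_m)

  ses <- setNames(rep(NA_real_, length(sel$par)), names(sel$par))
  if (n_mc > 0) {
    if (!is.null(seed)) set.seed(seed)
    spec_m <- .mf_model_pars(sel$model, tau_m)
    draws <- replicate(n_mc, {
      rec_mc <- record
      rec_mc$r1 <- record$r1 + rnorm(1, 0, err[1])
      rec_mc$r2 <- record$r2 + rnorm(1, 0, err[2])
      rec_mc$noe <- record$noe + rnorm(1, 0, err[3])
      o <- tryCatch(
        nlminb(sel$par, .mf_chi2, model = sel$model, record = rec_mc,
               tau_m = tau_m, constants = constants, w = w,
               lower = spec_m$lower, upper = spec_m$upper),
        error = function(e) NULL)
      if (is.null(o)) rep(NA_real_, length(sel$par)) else o$par
    })
    ses <- apply(matrix(draws, nrow = length(sel$par)), 1, sd, na.rm = TRUE)
    names(ses) <- names(sel$par)
  }
  structure(list(residue_id = record$residue_id, model = sel$model,
                 params = params, par = sel$par, par_se = ses,
                 chi2 = sel$chi2, scores = score_tab),
            class = "model_free_result")
}

#' @export
print.model_free_result <- function(x, ...) {
  cat(sprintf("%s: model %d, S2 = %.3f, tau_loc = %.1f ps, Rex = %.2f s^-1, chi2 = %.3g\n",
              if (is.null(x$residue_id)) "residue" else x$residue_id,
              x$model, x$params$s2, x$params$tau_loc, x$params$rex, x$chi2))
  invisible(x)
}

#' Model-free analysis of one or more conditions
#'
#' Runs [estimate_tau_m()] (unless `tau_m` is supplied) and
#' [fit_residue()] for every residue of every condition, and summarizes:
#' per-condition mean S2 with its standard error, residues carrying Rex,
#' and per-residue S2 differences from the reference condition.
#'
#' @param records_by_condition named list of relaxation-record
#'   data.frames (one per condition), sharing residue numbering.
#' @param constants [spin_constants()].
#' @param reference name of the reference condition (default: first).
#' @param tau_m fixed tau_m in ns, or "auto" to estimate per condition.
#' @param exclude residue ids to drop (prolines, overlapped peaks, ...).
#' @param ... passed to [fit_residue()].
#' @return list with `results` (per-residue table: condition, residue_id,
#'   model, s2, tau_loc, rex, chi2, delta_s2), `summary` (per-condition:
#'   tau_m_ns, mean_s2, se_s2, n, rex_residues), `excluded`.
#' @export
fit_dataset <- function(records_by_condition, constants, reference = NULL,
                        tau_m = "auto", exclude = NULL, ...) {
  stopifnot(is.list(records_by_condition), length(records_by_condition) > 0)
  conds <- names(records_by_condition)
  if (is.null(conds) || any(!nzchar(conds)))
    nmr_error("records_by_condition must be a named list", "domain_error")
  if (is.null(reference)) reference <- conds[1]
  if (!reference %in% conds)
    nmr_warn(sprintf("reference condition '%s' absent: differences not computed",
                     reference), "summary_warning")

  per_cond <- lapply(conds, function(cn) {
    rec <- records_by_condition[[cn]]
    dropped <- unique(c(
      intersect(rec$residue_id, exclude),
      rec$residue_id[!stats::complete.cases(rec[, c("r1", "r2", "noe")])]))
    rec <- rec[!rec$residue_id %in% dropped, ]
    tm <- if (identical(tau_m, "auto"))
      estimate_tau_m(rec, constants) else tau_m
    rows <- lapply(seq_len(nrow(rec)), function(i) {
      fr <- tryCatch(fit_residue(rec[i, ], tm, constants, ...),
                     error = function(e) NULL)
      if (is.null(fr)) return(NULL)
      data.frame(condition = cn, residue_id = rec$residue_id[i],
                 model = fr$model, s2 = fr$params$s2,
                 tau_loc = fr$params$tau_loc, rex = fr$params$rex,
                 chi2 = fr$chi2, stringsAsFactors = FALSE)
    })
    list(tab = do.call(rbind, rows), tau_m = tm, excluded = dropped)
  })
  names(per_cond) <- conds

  results <- do.call(rbind, lapply(per_cond, `[[`, "tab"))
  ref_tab <- per_cond[[reference]]$tab
  if (!is.null(ref_tab)) {
    ref_s2 <- setNames(ref_tab$s2, ref_tab$residue_id)
    results$delta_s2 <- results$s2 - ref_s2[results$residue_id]
  }
  summary <- do.call(rbind, lapply(conds, function(cn) {
    tab <- per_cond[[cn]]$tab
    data.frame(condition = cn, tau_m_ns = per_cond[[cn]]$tau_m,
               mean_s2 = mean(tab$s2), se_s2 = sd(tab$s2) / sqrt(nrow(tab)),
               n = nrow(tab),
               rex_residues = paste(tab$residue_id[tab$rex > 0],
                                    collapse = ","),
               stringsAsFactors = FALSE)
  }))
  list(results = results, summary = summary,
       excluded = lapply(per_cond, `[[`, "excluded"))
}
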