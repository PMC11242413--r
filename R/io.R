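# Tabular schemas: one tab-delimited dialect, mandatory headers, fixed
# units (ppm, s^-1, mM, Celsius). No positional columns, no unit
# auto-detection.
.SCHEMAS <- list(
  peaks = list(cols = c(residue_id = "character", concentration_mM = "numeric",
                        h_ppm = "numeric", n_ppm = "numeric")),
  relaxation = list(cols = c(residue_id = "character", field_mhz = "numeric",
                             r1 = "numeric", r1_err = "numeric",
                             r2 = "numeric", r2_err = "numeric",
                             noe = "numeric", noe_err = "numeric")),
  decays = list(cols = c(residue_id = "character", delay_ms = "numeric",
                         intensity = "numeric", replicate = "numeric")),
  noe_pairs = list(cols = c(residue_id = "character", i_sat = "numeric",
                            i_unsat = "numeric", noe_err = "numeric")),
  dispersion = list(cols = c(residue_id = "character", field_mhz = "numeric",
                             nu_cpmg_hz = "numeric", r2eff = "numeric",
                             r2eff_err = "numeric")),
  dispersion_intensity = list(cols = c(residue_id = "character",
                                       field_mhz = "numeric",
                                       nu_cpmg_hz = "numeric",
                                       intensity = "numeric", i0 = "numeric")),
  melt = list(cols = c(condition = "character", temperature_c = "numeric",
                       ellipticity = "numeric"))
)

#' Table schemas understood by the readers/writers
#'
#' @return named list: for each schema id, the ordered column-name/type
#'   map of the tab-delimited dialect.
#' @export
nmr_schemas <- function() lapply(.SCHEMAS, `[[`, "cols")

#' Read a validated tab-delimited analysis table
#'
#' Reads one of the package's tabular formats (see [nmr_schemas()]),
#' checks the header against the schema and coerces/validates every
#' column; unparseable cells are reported with their row number.
#'
#' @param path file path.
#' @param schema_id one of `names(nmr_schemas())`.
#' @return data.frame with the schema's columns and types.
#' @export
read_nmr_table <- function(path, schema_id) {
  if (!schema_id %in% names(.SCHEMAS))
    nmr_error(paste0("unknown schema '", schema_id, "'; valid: ",
                     paste(names(.SCHEMAS), collapse = ", ")), "schema_error")
  if (!file.exists(path))
    nmr_error(paste("file not found:", path), "io_error")
  cols <- .SCHEMAS[[schema_id]]$cols
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  miss <- setdiff(names(cols), names(raw))
  if (length(miss))
    nmr_error(paste0("table ", path, " missing column(s): ",
                     paste(miss, collapse = ", ")), "schema_error")
  if (nrow(raw) == 0L)
    nmr_error(paste("table has no data rows:", path), "empty_table_error")
  out <- raw[names(cols)]
  for (cn in names(cols)) {
    if (cols[[cn]] == "numeric") {
      v <- suppressWarnings(as.numeric(out[[cn]]))
      bad <- which(is.na(v) & !(out[[cn]] %in% c("NA", "", "NaN")))
      if (length(bad))
        nmr_error(sprintf("column '%s': unparseable value '%s' at data row %d",
                          cn, out[[cn]][bad[1]], bad[1]), "parse_error")
      out[[cn]] <- v
    }
  }
  out
}

#' Write an analysis table in the package's tab-delimited dialect
#'
#' @param x data.frame carrying at least the schema's columns.
#' @param path output path.
#' @param schema_id one of `names(nmr_schemas())`, or `NULL` to write the
#'   data.frame as-is (used for derived result tables).
#' @return `path`, invisibly.
#' @export
write_nmr_table <- function(x, path, schema_id = NULL) {
  if (!is.null(schema_id)) {
    if (!schema_id %in% names(.SCHEMAS))
      nmr_error(paste0("unknown schema '", schema_id, "'"), "schema_error")
    cols <- names(.SCHEMAS[[schema_id]]$cols)
    miss <- setdiff(cols, names(x))
    if (length(miss))
      nmr_error(paste0("data missing column(s): ",
                       paste(miss, collapse = ", ")), "schema_error")
    x <- x[cols]
  }
  # full double precision so read/write round-trips are lossless
  for (cn in names(x))
    if (is.numeric(x[[cn]])) x[[cn]] <- sprintf("%.17g", x[[cn]])
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
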