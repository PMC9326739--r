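## Delimited-text input/output. One long-format table carries any number
## of titration series; concentrations are accepted in mol/L only (the
## column name states the unit), so reports from different assays stay
## comparable without molecular-weight guesswork.

.REQ_COLS <- c("conc_mol_per_L", "signal")
.META_COLS <- c("antigen", "isotype", "dilution", "replicate")

## %.17g survives a write/read round trip bit-exactly for doubles.
.fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Read titration series from a delimited text file
#'
#' Expects a header with at least `conc_mol_per_L` and `signal`;
#' optional `antigen`, `isotype`, `dilution` (grouping columns: one
#' series per combination) and `replicate` (spread into signal
#' columns). Rows with zero or negative concentration are split out as
#' blanks: their count and mean signal are recorded in the series
#' metadata (`blankCount`, `blankMean`) and reported via `message()`,
#' and they never enter the log-concentration fit.
#'
#' @param path file path.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @return list of [TitrationSeries-class], named by group.
#' @export
readTitration <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  for (col in .REQ_COLS)
    if (!col %in% names(df))
      stop("missing required column '", col, "'", call. = FALSE)
  for (col in .REQ_COLS) {
    bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(
      as.numeric(df[[col]]))))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ",
           bad[1], call. = FALSE)
    df[[col]] <- as.numeric(df[[col]])
  }
  if (!"antigen" %in% names(df)) df$antigen <- "antigen1"
  if (!"isotype" %in% names(df)) df$isotype <- "IgG"
  if (!"dilution" %in% names(df)) df$dilution <- 1
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  key <- interaction(df$antigen, df$isotype, df$dilution, drop = TRUE,
                     sep = "|")
  out <- list()
  for (g in levels(key)) {
    sub <- df[key == g, , drop = FALSE]
    blanks <- sub$conc_mol_per_L <= 0
    meta <- list(antigen = sub$antigen[1], isotype = sub$isotype[1],
                 dilution = sub$dilution[1])
    if (any(blanks)) {
      meta$blankCount <- sum(blanks)
      meta$blankMean <- mean(sub$signal[blanks])
      message("series ", g, ": ", sum(blanks),
              " blank (conc <= 0) row(s) split out of the fit")
      sub <- sub[!blanks, , drop = FALSE]
    }
    if (nrow(sub) == 0L) next
    reps <- sort(unique(sub$replicate))
    concs <- sort(unique(sub$conc_mol_per_L))
    sig <- matrix(NA_real_, length(concs), length(reps),
                  dimnames = list(NULL, paste0("rep", reps)))
    for (j in seq_along(reps)) {
      rj <- sub[sub$replicate == reps[j], , drop = FALSE]
      sig[match(rj$conc_mol_per_L, concs), j] <- rj$signal
    }
    if (anyNA(sig)) {
      ## unbalanced replicates: fall back to one long pseudo-replicate
      ord <- order(sub$conc_mol_per_L)
      concs <- sub$conc_mol_per_L[ord]
      if (anyDuplicated(concs))
        stop("series ", g, ": unbalanced replicates with duplicate ",
             "concentrations are not representable", call. = FALSE)
      sig <- matrix(sub$signal[ord], ncol = 1L)
    }
    out[[g]] <- TitrationSeries(concs, sig, meta)
  }
  if (length(out) == 0L) stop("no usable titration rows in ", path,
                              call. = FALSE)
  out
}

#' Write titration series to a delimited text file
#'
#' Long format, readable back by [readTitration()]; numbers are written
#' with 17 significant digits so a write/read round trip is bit-exact.
#'
#' @param series a [TitrationSeries] or list of them.
#' @param path output path.
#' @param sep field separator.
#' @export
writeTitration <- function(series, path, sep = ",") {
  if (is(series, "TitrationSeries")) series <- list(series)
  rows <- lapply(series, function(s) {
    m <- s@meta
    nr <- ncol(s@signal)
    data.frame(
      antigen = m$antigen, isotype = m$isotype,
      dilution = .fmtNum(as.numeric(m$dilution)),
      replicate = rep(seq_len(nr), each = length(s@conc)),
      conc_mol_per_L = .fmtNum(rep(s@conc, times = nr)),
      signal = .fmtNum(as.vector(s@signal)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.reportParamCols <- c("sFloor", "sSpan", "rate", "logInfl", "nu",
                      "slopeB", "cMid", "asymG")

#' Assemble a fit report table
#'
#' One row per fit: series metadata, model, convergence, fit statistics,
#' every fitted parameter with its standard error (and bootstrap CI when
#' supplied), and — for converged GL fits — the derived thermodynamic
#' columns `ag_infl_mol_per_L`, `kd_apparent_mol_per_L`,
#' `delta_mu_standard_kJ_per_mol`, `gamma_inf`.
#'
#' @param fits list of [FitResult].
#' @param temperature K, for the derived quantities.
#' @param cis optional list (parallel to `fits`) of [bootstrapCI()]
#'   data.frames, or `NULL` entries.
#' @return data.frame with a deterministic column order.
#' @export
fitReport <- function(fits, temperature = 298.15, cis = NULL) {
  if (is(fits, "FitResult")) fits <- list(fits)
  if (length(fits) == 0L) stop("fits must be non-empty", call. = FALSE)
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    m <- f@series@meta
    row <- data.frame(
      antigen = m$antigen, isotype = m$isotype,
      dilution = as.numeric(m$dilution), model = f@model,
      converged = f@converged, n_obs = f@nObs, rss = f@rss,
      aic = f@aic, bic = f@bic, r_squared = f@rSquared,
      stringsAsFactors = FALSE)
    est <- coef(f); se <- paramSE(f)
    for (p in .reportParamCols) {
      row[[paste0("est_", p)]] <- if (p %in% names(est)) est[[p]] else NA_real_
      row[[paste0("se_", p)]] <- if (p %in% names(se)) se[[p]] else NA_real_
    }
    ci <- if (!is.null(cis)) cis[[i]] else NULL
    for (p in .reportParamCols) {
      hit <- if (is.null(ci)) integer(0) else which(ci$parameter == p)
      row[[paste0("ci_lo_", p)]] <-
        if (length(hit)) ci$lower[hit[1]] else NA_real_
      row[[paste0("ci_hi_", p)]] <-
        if (length(hit)) ci$upper[hit[1]] else NA_real_
    }
    dq <- if (f@model == "GL" && f@converged)
      deriveQuantities(f, temperature) else NULL
    row$ag_infl_mol_per_L <- if (is.null(dq)) NA_real_ else agInfl(dq)
    row$kd_apparent_mol_per_L <- if (is.null(dq)) NA_real_ else kdApparent(dq)
    row$delta_mu_standard_kJ_per_mol <-
      if (is.null(dq)) NA_real_ else deltaMu(dq) / 1000
    row$gamma_inf <- if (is.null(dq)) NA_real_ else gammaInf(dq)
    row$temperature_K <- temperature
    row
  })
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, logical(1))
  for (i in seq_len(nrow(out))) {
    v <- unlist(out[i, num])
    nf <- names(v)[is.nan(v) | is.infinite(v)]
    if (length(nf))
      warning("non-finite value(s) in report row for series '",
              out$antigen[i], "/", out$isotype[i], "': ",
              paste(nf, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a fit report to CSV or JSON
#'
#' CSV numbers carry 17 significant digits; JSON is written losslessly
#' with a `schema_version` field. The same values appear under both
#' formats.
#'
#' @param report data.frame from [fitReport()].
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @export
writeReport <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (nrow(report) == 0L) stop("report must be non-empty", call. = FALSE)
  if (format == "csv") {
    out <- report
    for (nm in names(out))
      if (is.numeric(out[[nm]])) out[[nm]] <- .fmtNum(out[[nm]])
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(
      list(schema_version = "1.0", report = report), path,
      auto_unbox = TRUE, digits = I(17), na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a fit report
#'
#' @param path file written by [writeReport()].
#' @param format `"csv"` or `"json"`.
#' @return data.frame.
#' @export
readReport <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.table(path, header = TRUE, sep = ",",
                      stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path)$report)
  }
}
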