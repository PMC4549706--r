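# CSV schemas. Units are encoded in the column names (time_s, S_uM, I_nM);
# readers convert to the internal molar/second convention, writers convert
# back. RFC 4180 CSV, '.' decimal, UTF-8.

#' Read progress curves from CSV
#'
#' Expected columns: `time_s`, `signal`, `S_uM`, `I_nM`, `curve_id`. Rows
#' are grouped by `curve_id` and sorted by time, so shuffled files load
#' identically.
#'
#' @param path CSV file path.
#' @return list of [progress_curve()] objects (concentrations in molar).
#' @export
read_progress_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "signal", "S_uM", "I_nM", "curve_id")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop_input("schema error: missing column(s) %s", paste(miss, collapse = ", "))
  }
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad) > 0) {
    stop_input("malformed rows at lines %s",
               paste(utils::head(bad + 1L, 10), collapse = ", "))
  }
  curves <- lapply(split(df, df$curve_id), function(sub) {
    sub <- sub[order(sub$time_s), ]
    if (any(duplicated(sub$time_s))) {
      stop_input("validation error: non-increasing times within curve '%s'",
                 sub$curve_id[1])
    }
    if (length(unique(sub$S_uM)) != 1 || length(unique(sub$I_nM)) != 1) {
      stop_input("validation error: curve '%s' mixes concentrations",
                 sub$curve_id[1])
    }
    progress_curve(sub$time_s, sub$signal,
                   S = sub$S_uM[1] * 1e-6, I = sub$I_nM[1] * 1e-9,
                   curve_id = sub$curve_id[1])
  })
  unname(curves)
}

#' Write progress curves to CSV
#'
#' @param curves list of [progress_curve()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_progress_csv <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(time_s = cv$times, signal = cv$signal,
               S_uM = cv$S * 1e6, I_nM = cv$I * 1e9, curve_id = cv$curve_id)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an initial-rate table from CSV
#'
#' Expected columns: `S_uM`, `I_nM`, `v`; optional `replicate`.
#'
#' @param path CSV file path.
#' @return a [rate_table()] in molar units.
#' @export
read_rate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("S_uM", "I_nM", "v")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop_input("schema error: missing column(s) %s", paste(miss, collapse = ", "))
  }
  rate_table(df$S_uM * 1e-6, df$I_nM * 1e-9, df$v,
             replicate = if ("replicate" %in% names(df)) df$replicate else 1L)
}

#' Write an initial-rate table to CSV
#'
#' @param table a [rate_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rate_csv <- function(table, path) {
  df <- data.frame(S_uM = table$S * 1e6, I_nM = table$I * 1e9,
                   v = table$v, replicate = table$replicate)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a candidate table from CSV
#'
#' Expected columns: `compound`, `series`, `site`, `group`; optional
#' `ddG_cal` (kcal/mol), `ki_nM`, descriptor columns (MW, ClogP, HBA, HBD,
#' ROB, ARB) and `synthesizable`.
#'
#' @param path CSV file path.
#' @return data frame; `ki_nM` is additionally converted to a molar `ki`
#'   column when present.
#' @export
read_candidates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("compound", "series", "site", "group")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop_input("schema error: missing column(s) %s", paste(miss, collapse = ", "))
  }
  if ("ki_nM" %in% names(df)) df$ki <- df$ki_nM * 1e-9
  df
}

#' Run configuration defaults
#'
#' Collects the tunable analysis settings with defaults that reproduce the
#' reference criteria: RT at 300 K (so the triage threshold -1.37 kcal/mol
#' is a 10-fold Ki improvement) and the six pesticide-likeness limits.
#' Serialises losslessly through JSON.
#'
#' @param thermo a [thermo_context()].
#' @param triage_threshold kcal/mol.
#' @param likeness_limits named numeric vector of rule limits.
#' @param alpha significance level for trend tests.
#' @param weighting rate-fit weighting scheme.
#' @param seed default generator seed.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(thermo = thermo_context(), triage_threshold = -1.37,
                       likeness_limits = NULL, alpha = 0.05,
                       weighting = "proportional", seed = 1L) {
  if (is.null(likeness_limits)) likeness_limits <- .likeness_limits
  structure(list(thermo = list(R = thermo$R, T = thermo$T),
                 triage_threshold = triage_threshold,
                 likeness_limits = as.list(likeness_limits),
                 alpha = alpha, weighting = weighting, seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> T = %g K, triage threshold %.2f kcal/mol, alpha = %g, seed = %d\n",
              x$thermo$T, x$triage_threshold, x$alpha, x$seed))
  invisible(x)
}
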