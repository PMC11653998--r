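# Long-format CSV input, report rendering, and fit sidecar output.
#
# Interchange schema (schema version 1): one row per reading, columns
#   condition (text), replicate (text), time_h (hours),
#   h2_ml_per_l (cumulative biohydrogen, mL per L working volume)
# and optional columns si_g_per_l, sf_g_per_l, final_ph. Times are hours and
# volumes mL/L throughout; no unit conversion is performed.

required_gas_columns <- c("condition", "replicate", "time_h", "h2_ml_per_l")

#' Read a long-format cumulative gas table
#'
#' Parses a UTF-8 CSV with header columns `condition`, `replicate`, `time_h`,
#' `h2_ml_per_l` (optional: `si_g_per_l`, `sf_g_per_l`, `final_ph`) into one
#' [gas_series()] per (condition, replicate) group, sorted by time within each
#' group. A leading comment line starting with `#` (the schema header written
#' by [write_gas_table()]) is skipped.
#'
#' @param path Path to the CSV file.
#' @param monotonicity Policy for decreasing cumulative readings, passed to
#'   [gas_series()]: `"reject"` (default) or `"clip_to_running_max"`.
#'
#' @return A named list of conditions; each element is a list with `series`
#'   (list of [gas_series()]), `s_initial`, `s_final`, `final_ph` (NA when
#'   the optional columns are absent).
#' @export
read_gas_table <- function(path, monotonicity = c("reject", "clip_to_running_max")) {
  monotonicity <- match.arg(monotonicity)
  if (!file.exists(path))
    stop("input file does not exist: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(required_gas_columns, names(df))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$time_h) | !is.finite(df$h2_ml_per_l))
  if (length(bad) > 0)
    stop("malformed rows (non-numeric time or volume) at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  key <- interaction(df$condition, df$replicate, drop = TRUE)
  if (anyDuplicated(paste(key, df$time_h)))
    stop("duplicate (condition, replicate, time_h) rows", call. = FALSE)

  out <- list()
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond, , drop = FALSE]
    series <- lapply(unique(sub$replicate), function(rep) {
      g <- sub[sub$replicate == rep, , drop = FALSE]
      g <- g[order(g$time_h), , drop = FALSE]
      gas_series(cond, rep, g$time_h, g$h2_ml_per_l,
                 monotonicity = monotonicity)
    })
    first <- function(col) if (col %in% names(sub)) sub[[col]][1] else NA_real_
    out[[cond]] <- list(series = series,
                        s_initial = first("si_g_per_l"),
                        s_final = first("sf_g_per_l"),
                        final_ph = first("final_ph"))
  }
  out
}

#' Write a long-format gas table
#'
#' Writes the schema-versioned CSV consumed by [read_gas_table()], with a
#' `#` comment line identifying the schema.
#'
#' @param panel A data.frame as produced by [generate_screening_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gas_table <- function(panel, path) {
  stopifnot(is.data.frame(panel),
            all(required_gas_columns %in% names(panel)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# h2kinetics gas table schema v1; time_h in hours, h2_ml_per_l in mL per L working volume", con)
  utils::write.csv(panel, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt2 <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 2))
fmt3 <- function(x) ifelse(is.na(x), "", formatC(x, format = "f", digits = 3))

report_frame <- function(rows) {
  data.frame(
    condition = vapply(rows, `[[`, character(1), "condition"),
    h_max_exp = fmt2(vapply(rows, `[[`, numeric(1), "h_max_exp")),
    h_max_se = fmt2(vapply(rows, `[[`, numeric(1), "h_max_se")),
    r_emax_exp = fmt2(vapply(rows, `[[`, numeric(1), "r_emax_exp")),
    r_emax_se = fmt2(vapply(rows, `[[`, numeric(1), "r_emax_se")),
    lag_h = fmt2(vapply(rows, `[[`, numeric(1), "lag")),
    r_max = fmt2(vapply(rows, `[[`, numeric(1), "r_max")),
    t_95 = fmt2(vapply(rows, `[[`, numeric(1), "t95")),
    r_squared = fmt3(vapply(rows, `[[`, numeric(1), "r_squared")),
    y_hp_s = fmt2(vapply(rows, `[[`, numeric(1), "yield_hp_s")),
    q_p = fmt2(vapply(rows, `[[`, numeric(1), "q_p")),
    q_s = fmt3(vapply(rows, `[[`, numeric(1), "q_s")),
    final_ph = fmt2(vapply(rows, `[[`, numeric(1), "final_ph")),
    stringsAsFactors = FALSE)
}

#' Render a kinetic report table
#'
#' Writes a collection of [build_report_row()] results as a screening-style
#' kinetic table: experimental columns (Hmax, R_Emax with standard errors),
#' fitted modified Gompertz columns (lag, Rmax, t95, R^2) and derived metrics
#' (yield, Qp, Qs, final pH). Numbers are rendered at 2 decimal places
#' (3 for R^2 and Qs); absent metrics render as empty fields, not zeros.
#' Output bytes are deterministic for identical input.
#'
#' @param rows A list of `kinetic_report_row` objects.
#' @param path Output path; with `format = "markdown"` and `path = NULL` the
#'   table is returned as a character vector instead.
#' @param format `"csv"` or `"markdown"`.
#' @return `path` (or the markdown lines when `path = NULL`), invisibly.
#' @export
write_report <- function(rows, path = NULL, format = c("csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(
    "rows must be a non-empty list of kinetic_report_row" =
      is.list(rows) && length(rows) >= 1L &&
      all(vapply(rows, inherits, logical(1), "kinetic_report_row"))
  )
  df <- report_frame(rows)
  if (format == "csv") {
    if (is.null(path)) stop("path required for csv output", call. = FALSE)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  lines <- c(header, sep, body)
  if (is.null(path)) return(invisible(lines))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a fitted-parameter JSON sidecar
#'
#' Serializes fit results (parameters, R^2, t95, convergence, options used,
#' package version) to JSON for reproducibility alongside the rendered
#' report.
#'
#' @param fits A named list of `gompertz_fit` objects (names are condition
#'   labels) or a single fit.
#' @param path Output path.
#' @param options The [fit_options()] used, recorded verbatim.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fits, path, options = fit_options()) {
  if (inherits(fits, "gompertz_fit")) fits <- list(fits)
  payload <- list(
    package = "h2kinetics",
    version = as.character(utils::packageVersion("h2kinetics")),
    options = list(replicate_policy = options$replicate_policy,
                   max_iterations = options$max_iterations,
                   tolerance = options$tolerance),
    fits = lapply(fits, function(f) list(
      condition = f$condition,
      h_max = f$params$h_max, r_max = f$params$r_max, lag = f$params$lag,
      t95 = f$t95, r_squared = f$r_squared, converged = f$converged,
      n_points = f$n_points, replicate_policy = f$replicate_policy_used)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
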