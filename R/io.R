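#' Thermal melting curve container
#'
#' A validated two-column melting dataset: temperatures in kelvin (strictly
#' increasing; duplicates collapsed by averaging) paired with either a
#' dimensionless helicity degree (`kind = "cd"`) or a molar heat capacity in
#' J mol-1 K-1 (`kind = "dsc"`). CD values may stray slightly outside
#' `[0, 1]` from noise (tolerance `[-0.05, 1.05]`); anything grossly outside
#' that range indicates an un-normalized signal and is rejected.
#'
#' @param temperatures Numeric vector (K), length >= 10 after duplicate
#'   collapsing.
#' @param values Numeric vector, same length.
#' @param kind `"cd"` or `"dsc"`.
#' @param source_units Optional record of the units the data arrived in,
#'   e.g. `list(temperature = "C", value = "kcal/(mol K)")`.
#' @return An object of class `"zb_thermal_curve"`.
#' @export
thermal_curve <- function(temperatures, values, kind = c("cd", "dsc"),
                          source_units = NULL) {
  kind <- match.arg(kind)
  if (length(temperatures) != length(values))
    stop("`temperatures` and `values` must have the same length.",
         call. = FALSE)
  if (any(!is.finite(temperatures)) || any(!is.finite(values)))
    stop("All temperatures and values must be finite numbers.",
         call. = FALSE)
  ord <- order(temperatures)
  temperatures <- temperatures[ord]
  values <- values[ord]
  if (anyDuplicated(temperatures)) {
    values <- as.numeric(tapply(values, temperatures, mean))
    temperatures <- sort(unique(temperatures))
  }
  if (length(temperatures) < 10L)
    stop("Insufficient data: need at least 10 distinct temperature points, ",
         "got ", length(temperatures), ".", call. = FALSE)
  if (kind == "cd" && (min(values) < -0.05 || max(values) > 1.05))
    stop("CD values must be a normalized helicity degree in [0, 1] ",
         "(observed range [", signif(min(values), 4), ", ",
         signif(max(values), 4), "]); they should be normalized before ",
         "fitting.", call. = FALSE)
  structure(list(temperatures = temperatures, values = values, kind = kind,
                 source_units = source_units),
            class = "zb_thermal_curve")
}

#' @export
print.zb_thermal_curve <- function(x, ...) {
  cat(sprintf("Thermal curve (%s): %d points, T in [%.2f, %.2f] K, values in [%.4g, %.4g]\n",
              x$kind, length(x$temperatures), min(x$temperatures),
              max(x$temperatures), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.zb_thermal_curve <- function(x, ...) {
  data.frame(temperature = x$temperatures, value = x$values)
}

#' Convert dependent-variable units to the package's canonical units
#'
#' DSC heat capacities are converted multiplicatively to J mol-1 K-1
#' (`1 cal = 4.184 J` exactly); CD helicity degrees are dimensionless and
#' pass through after a normalization range check.
#'
#' @param values Numeric vector.
#' @param from_unit For `kind = "dsc"`: one of `"J/(mol K)"`, `"kJ/(mol K)"`,
#'   `"cal/(mol K)"`, `"kcal/(mol K)"` (short forms `"J"`, `"kJ"`, `"cal"`,
#'   `"kcal"` accepted). For `kind = "cd"`: `"1"`, `"dimensionless"`, or
#'   `NULL`.
#' @param kind `"cd"` or `"dsc"`.
#' @return Values in canonical units.
#' @examples
#' convert_value_units(1, "kcal/(mol K)", "dsc")  # 4184
#' @export
convert_value_units <- function(values, from_unit, kind = c("cd", "dsc")) {
  kind <- match.arg(kind)
  if (kind == "cd") {
    if (!is.null(from_unit) &&
        !(from_unit %in% c("1", "dimensionless", "helicity")))
      stop("CD input must already be a dimensionless, normalized helicity ",
           "degree; unsupported unit '", from_unit, "'.", call. = FALSE)
    if (length(values) && (min(values) < -0.05 || max(values) > 1.05))
      stop("CD values are not a normalized helicity degree (range [",
           signif(min(values), 4), ", ", signif(max(values), 4),
           "]); they should be normalized before fitting.", call. = FALSE)
    return(values)
  }
  key <- sub("/\\(mol.?K\\)$", "", from_unit)
  factors <- c(J = 1, kJ = 1000, cal = 4.184, kcal = 4184)
  if (!(key %in% names(factors)))
    stop("Unsupported DSC unit '", from_unit, "'; supported: J/(mol K), ",
         "kJ/(mol K), cal/(mol K), kcal/(mol K).", call. = FALSE)
  values * unname(factors[key])
}

# Split one line under a candidate delimiter; returns character fields.
split_fields <- function(line, delim) {
  line <- sub("^\\s+", "", sub("\\s+$", "", line))
  if (delim == "whitespace") strsplit(line, "\\s+")[[1]]
  else strsplit(line, delim, fixed = TRUE)[[1]]
}

#' Read a two-column melting data file
#'
#' Parses headerless two-column numeric files (CSV, TXT, DAT). The delimiter
#' is sniffed in the order comma, tab, whitespace: the first that yields two
#' numeric fields on the first data line wins. Temperatures are converted to
#' kelvin, values to canonical units, the rows sorted by temperature and
#' duplicate temperatures averaged.
#'
#' A non-numeric first row is rejected as a header (input files must not
#' have headers); any row with a field count other than two is a format
#' error; fewer than 10 usable rows is an insufficient-data error.
#'
#' @param path Path to the file.
#' @param kind `"cd"` or `"dsc"`.
#' @param temp_unit `"K"` or `"C"`.
#' @param value_unit Unit of the second column (see
#'   [convert_value_units()]); defaults to dimensionless for CD and
#'   `"J/(mol K)"` for DSC.
#' @param decimal_comma Accept decimal commas (`"3,14"`); forces
#'   semicolon/whitespace delimiters. Off by default: silent locale guessing
#'   corrupts data.
#' @return A [thermal_curve()].
#' @export
read_two_column <- function(path, kind = c("cd", "dsc"),
                            temp_unit = c("K", "C"), value_unit = NULL,
                            decimal_comma = FALSE) {
  kind <- match.arg(kind)
  temp_unit <- match.arg(temp_unit)
  if (is.null(value_unit))
    value_unit <- if (kind == "cd") "1" else "J/(mol K)"
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("File is empty: ", path, call. = FALSE)

  delims <- if (decimal_comma) c(";", "whitespace") else
    c(",", "\t", "whitespace")
  to_num <- function(x) {
    if (decimal_comma) x <- gsub(",", ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(x))
  }
  delim <- NULL
  for (d in delims) {
    fields <- split_fields(lines[1], d)
    if (length(fields) == 2L && !anyNA(to_num(fields))) { delim <- d; break }
  }
  if (is.null(delim)) {
    # diagnose: header row vs malformed
    for (d in delims) {
      fields <- split_fields(lines[1], d)
      if (length(fields) == 2L)
        stop("Header detected: first row '", lines[1], "' is not numeric. ",
             "Input files must not have headers.", call. = FALSE)
    }
    stop("Format error: first row '", lines[1],
         "' does not contain two delimited fields.", call. = FALSE)
  }

  parsed <- lapply(seq_along(lines), function(i) {
    fields <- split_fields(lines[i], delim)
    if (length(fields) != 2L)
      stop("Format error at row ", i, ": expected 2 fields, found ",
           length(fields), ".", call. = FALSE)
    vals <- to_num(fields)
    if (anyNA(vals)) {
      if (i == 1L)
        stop("Header detected: first row '", lines[i], "' is not numeric. ",
             "Input files must not have headers.", call. = FALSE)
      stop("Format error at row ", i, ": non-numeric field in '",
           lines[i], "'.", call. = FALSE)
    }
    vals
  })
  m <- do.call(rbind, parsed)
  temps <- if (temp_unit == "C") m[, 1] + 273.15 else m[, 1]
  vals <- convert_value_units(m[, 2], value_unit, kind)
  if (nrow(m) < 10L)
    stop("Insufficient data: need at least 10 rows, got ", nrow(m), ".",
         call. = FALSE)
  thermal_curve(temps, vals, kind = kind,
                source_units = list(temperature = temp_unit,
                                    value = value_unit))
}

#' Write a melting curve as canonical two-column CSV
#'
#' Kelvin and canonical value units, no header; the output is itself a
#' valid [read_two_column()] input, making parsing idempotent.
#'
#' @param curve A [thermal_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_two_column <- function(curve, path) {
  stopifnot(inherits(curve, "zb_thermal_curve"))
  lines <- sprintf("%.10g,%.10g", curve$temperatures, curve$values)
  writeLines(lines, path)
  invisible(path)
}

fit_result_list <- function(result) {
  list(mode = result$mode,
       params = list(t0 = result$params$t0, h = result$params$h,
                     hps = result$params$hps, Q = result$params$Q,
                     q = result$params$q, N = result$params$N),
       units = list(t0 = "K", h = "J/mol", hps = "J/mol", Q = "1"),
       percent_errors = as.list(result$percent_errors),
       r_squared = result$r_squared,
       melting_temperature = result$melting_temperature,
       warnings = as.list(result$warnings),
       n_obs = result$n_obs,
       ssr = result$ssr)
}

#' Export a fit result table
#'
#' JSON export carries the full result (parameters with units, percent
#' errors, `R^2`, warnings, melting temperature) and round-trips losslessly
#' through [read_result_table()]. CSV export writes one row per parameter
#' with columns `name`, `value`, `unit`, `percent_error`, followed by
#' summary rows for `r_squared` and the melting temperature.
#'
#' @param result A [fit_curve()] result.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "zb_fit"))
  if (format == "json") {
    jsonlite::write_json(fit_result_list(result), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  } else {
    est <- unlist(result$params[c("t0", "h", "hps", "Q")])
    df <- data.frame(name = names(est), value = unname(est),
                     unit = c("K", "J/mol", "J/mol", "1"),
                     percent_error = unname(result$percent_errors))
    extra <- data.frame(name = c("r_squared", "melting_temperature"),
                        value = c(result$r_squared,
                                  result$melting_temperature),
                        unit = c("1", "K"),
                        percent_error = c(NA_real_, NA_real_))
    utils::write.csv(rbind(df, extra), path, row.names = FALSE)
  }
  invisible(path)
}

#' Reload an exported JSON fit-result table
#'
#' @param path Path to a JSON file written by [write_result_table()].
#' @return A list mirroring the exported fields.
#' @export
read_result_table <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
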