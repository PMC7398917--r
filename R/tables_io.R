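#' Spectrometer / sample context
#'
#' Bundles the acquisition metadata every record is keyed by: the 1H Larmor
#' frequency, the temperature, the CPMG constant relaxation time and a free-text
#' condition label (e.g. `"free"`, `"pep2.1mM"`, `"dilute120uM"`).
#'
#' @param proton_frequency_MHz 1H frequency in MHz (e.g. 600.03, 800.4).
#' @param temperature_K Sample temperature in Kelvin; must lie in [250, 350]
#'   so Celsius values are rejected early.
#' @param t_relax_s Constant relaxation time of the CPMG element in seconds
#'   (default 0.030).
#' @param field_T Static field in Tesla; informational, derived from the 1H
#'   frequency when omitted.
#' @param condition Free-text sample-condition label.
#' @return Object of class `spectrometer_context`.
#' @export
spectrometer_context <- function(proton_frequency_MHz, temperature_K,
                                 t_relax_s = 0.030, field_T = NULL,
                                 condition = "free") {
  stopifnot(is.numeric(proton_frequency_MHz), length(proton_frequency_MHz) == 1)
  if (!(proton_frequency_MHz > 0)) stop("proton_frequency_MHz must be > 0")
  if (!(t_relax_s > 0)) stop("t_relax_s must be > 0")
  if (temperature_K < 250 || temperature_K > 350)
    stop("temperature_K must be in [250, 350] K (got ", temperature_K,
         "; Celsius input?)")
  if (is.null(field_T)) field_T <- proton_frequency_MHz / 42.577478518
  structure(list(proton_frequency_MHz = proton_frequency_MHz,
                 field_T = field_T,
                 temperature_K = temperature_K,
                 t_relax_s = t_relax_s,
                 condition = condition),
            class = "spectrometer_context")
}

#' @export
format.spectrometer_context <- function(x, ...) {
  sprintf("<context %.6g MHz, %.6g K, T_relax %.4g s, %s>",
          x$proton_frequency_MHz, x$temperature_K, x$t_relax_s, x$condition)
}

#' @export
print.spectrometer_context <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' @rdname spectrometer_context
#' @param ctx A `spectrometer_context`.
#' @return `context_key()`: a deterministic string key for grouping.
#' @export
context_key <- function(ctx) {
  sprintf("%.6gMHz_%.6gK_%s", ctx$proton_frequency_MHz, ctx$temperature_K,
          ctx$condition)
}

# residue ids come as "86", "86R" or "R86"; comparisons use the integer only
parse_residue_id <- function(x) {
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", x)))
  if (any(is.na(num))) {
    bad <- which(is.na(num))[1]
    stop("cannot parse residue identifier '", x[bad], "'")
  }
  num
}

detect_delim <- function(path) {
  first <- readLines(path, n = 25L)
  first <- first[!grepl("^\\s*#", first) & nzchar(first)]
  if (length(first) == 0) return("\t")
  if (sum(grepl(",", first)) >= sum(grepl("\t", first))) "," else "\t"
}

read_delim_checked <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_delim(path)
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", what, " table '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & nzchar(trimws(df[[cc]])))
    if (any(is.na(v))) {
      row <- which(is.na(v))[1]
      stop("parse error in '", path, "' column '", cc, "' row ", row,
           ": non-numeric value '", df[[cc]][row], "'")
    }
    df[[cc]] <- v
  }
  df
}

#' Read a CPMG intensity table
#'
#' Expects a delimited file (comma or tab, auto-detected) with header columns
#' `residue`, `nu_cpmg`, `intensity`, `noise`. A row with `nu_cpmg == 0` is the
#' reference experiment recorded at zero relaxation time; every residue must
#' have exactly one. Optional columns `frequency_MHz`, `temperature_K`,
#' `condition` override the defaults per row.
#'
#' @param path Path to the table.
#' @param context_defaults A [spectrometer_context] supplying metadata for rows
#'   without explicit context columns.
#' @return A list of class `intensity_groups`; each element has `residue_id`,
#'   `context` and a data frame `data` (sorted by `nu_cpmg`) whose first row is
#'   the reference.
#' @export
read_intensity_table <- function(path, context_defaults) {
  stopifnot(inherits(context_defaults, "spectrometer_context"))
  df <- read_delim_checked(path,
                           required = c("residue", "nu_cpmg", "intensity", "noise"),
                           numeric_cols = c("nu_cpmg", "intensity", "noise",
                                            "frequency_MHz", "temperature_K"),
                           what = "intensity")
  if (nrow(df) == 0) { warning("empty intensity table: ", path); return(structure(list(), class = "intensity_groups")) }
  if (any(df$noise <= 0)) {
    row <- which(df$noise <= 0)[1]
    stop("validation error: noise must be > 0 (row ", row, ")")
  }
  df$residue_id <- parse_residue_id(df$residue)
  ctx_of_row <- function(i) {
    f <- if ("frequency_MHz" %in% names(df)) df$frequency_MHz[i] else context_defaults$proton_frequency_MHz
    tK <- if ("temperature_K" %in% names(df)) df$temperature_K[i] else context_defaults$temperature_K
    cd <- if ("condition" %in% names(df)) df$condition[i] else context_defaults$condition
    spectrometer_context(f, tK, t_relax_s = context_defaults$t_relax_s,
                         condition = cd)
  }
  keys <- vapply(seq_len(nrow(df)), function(i) {
    sprintf("%06d|%s", df$residue_id[i], context_key(ctx_of_row(i)))
  }, character(1))
  groups <- lapply(sort(unique(keys)), function(k) {
    idx <- which(keys == k)
    sub <- df[idx[order(df$nu_cpmg[idx])], , drop = FALSE]
    n_ref <- sum(sub$nu_cpmg == 0)
    if (n_ref != 1)
      stop("validation error: residue ", sub$residue_id[1],
           if (n_ref == 0) " has no reference record (nu_cpmg = 0)"
           else " has multiple reference records")
    rownames(sub) <- NULL
    list(residue_id = sub$residue_id[1], context = ctx_of_row(idx[1]),
         data = sub[, c("residue_id", "nu_cpmg", "intensity", "noise")])
  })
  structure(groups, class = "intensity_groups")
}

#' Read a 15N relaxation-parameter table
#'
#' Columns: `residue`, `R1`, `R1_err`, `R2`, `R2_err`, `NOE`, `NOE_err`.
#' Rates and all errors must be positive.
#'
#' @param path Path to the table.
#' @param context A [spectrometer_context] attached to the records.
#' @return Data frame of relaxation records with the context as attribute
#'   `"context"`.
#' @export
read_relaxation_table <- function(path, context) {
  cols <- c("residue", "R1", "R1_err", "R2", "R2_err", "NOE", "NOE_err")
  df <- read_delim_checked(path, required = cols, numeric_cols = cols[-1],
                           what = "relaxation")
  if (any(df$R1 <= 0) || any(df$R2 <= 0))
    stop("validation error: R1 and R2 must be positive")
  if (any(df$R1_err <= 0 | df$R2_err <= 0 | df$NOE_err <= 0))
    stop("validation error: errors must be positive")
  df$residue_id <- parse_residue_id(df$residue)
  out <- df[, c("residue_id", "R1", "R1_err", "R2", "R2_err", "NOE", "NOE_err")]
  attr(out, "context") <- context
  out
}

#' Read a chemical-shift table
#'
#' Columns: `residue`, `delta_H`, `delta_N` (ppm). One row per residue.
#'
#' @param path Path to the table.
#' @param context A [spectrometer_context]; its `condition` distinguishes e.g.
#'   free vs peptide-bound tables.
#' @return Data frame of shift records with attribute `"context"`.
#' @export
read_shift_table <- function(path, context) {
  df <- read_delim_checked(path, required = c("residue", "delta_H", "delta_N"),
                           numeric_cols = c("delta_H", "delta_N"),
                           what = "shift")
  if (nrow(df) == 0) {
    warning("empty shift table: ", path)
    out <- data.frame(residue_id = integer(0), delta_H = numeric(0),
                      delta_N = numeric(0))
    attr(out, "context") <- context
    return(out)
  }
  if (any(!is.finite(df$delta_H)) || any(!is.finite(df$delta_N)))
    stop("validation error: shifts must be finite")
  df$residue_id <- parse_residue_id(df$residue)
  if (anyDuplicated(df$residue_id))
    stop("validation error: duplicated residue ",
         df$residue_id[duplicated(df$residue_id)][1], " in ", path)
  out <- df[, c("residue_id", "delta_H", "delta_N")]
  attr(out, "context") <- context
  out
}

# small deterministic content hash for the report header (no digest
# dependency); 31-bit rolling polynomial hash, overflow-safe in doubles
content_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a result table with a provenance header
#'
#' Writes any of the pipeline's result data frames as delimited text. Header
#' comment lines record the package version, a hash of the content and the
#' column names/units; numbers are written at full (17 significant digit)
#' precision so that [read_report()] round-trips to 1e-12 relative.
#'
#' @param results A data frame.
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param units Optional character vector of column units for the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "csv"), units = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  sep <- if (format == "tsv") "\t" else ","
  fmt <- results
  for (cc in names(fmt)) {
    if (is.numeric(fmt[[cc]]))
      fmt[[cc]] <- formatC(fmt[[cc]], digits = 17, format = "g")
  }
  body <- c(paste(names(results), collapse = sep),
            if (nrow(fmt)) apply(fmt, 1, paste, collapse = sep))
  header <- c(
    sprintf("# cpmgrd %s", as.character(packageVersion("cpmgrd"))),
    sprintf("# content-hash %s", content_hash(body)),
    sprintf("# columns %s", paste(names(results), collapse = " ")),
    if (!is.null(units)) sprintf("# units %s", paste(units, collapse = " ")))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("I/O error: cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()`: the data frame written by [write_report()].
#' @export
read_report <- function(path) {
  sep <- detect_delim(path)
  df <- read.table(path, header = TRUE, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, check.names = FALSE)
  df
}

#' Read a JSON configuration file
#'
#' Configuration (context defaults, physical constants overrides, fit bounds
#' and start grids, seeds) is stored as JSON.
#'
#' @param path Path to a JSON file.
#' @return Named list.
#' @export
read_config <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
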