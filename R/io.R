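#' Run configuration
#'
#' Default analysis conditions: 80 uM initial peptide, hours at the I/O
#' boundary (converted to seconds internally, once), and the default
#' noise, fitting and classification settings.
#'
#' @param a Initial monomer concentration, mol L^-1. Default 80e-6.
#' @param time_unit `"h"` or `"s"` for tabular I/O.
#' @param noise A [noise_spec()].
#' @param fit A [fit_options()].
#' @param rules A morphology rule set.
#' @param seed Integer master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(a = 80e-6, time_unit = c("h", "s"),
                       noise = noise_spec(), fit = fit_options(),
                       rules = default_rules(), seed = 1L) {
  time_unit <- match.arg(time_unit)
  stopifnot(a > 0)
  structure(list(a = a, time_unit = time_unit, noise = noise, fit = fit,
                 rules = rules, seed = as.integer(seed)),
            class = "run_config")
}

.read_strict_csv <- function(path, required, numeric_cols, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(required, numeric_cols,
                                c("condition", "replicate")))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[setdiff(names(df), extra)]
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    bad <- union(bad, which(df[[col]] %in% c("NA", "")))
    if (length(bad)) {
      if (!lenient)
        stop("non-numeric value in column '", col, "' at data row ",
             bad[1], ": '", df[[col]][bad[1]], "'")
      v <- v[-bad]
      df <- df[-bad, , drop = FALSE]
      warning("dropped ", length(bad), " malformed row(s) in lenient mode")
      v <- suppressWarnings(as.numeric(df[[col]]))
    }
    df[[col]] <- v
  }
  df
}

#' Read ThT time courses from CSV
#'
#' Expects a header with `time_h` (hours) or `time_s` (seconds) and
#' `intensity`, plus optional `condition` and `replicate` columns. Times
#' are converted to seconds and each (condition, replicate) series is
#' sorted by time. Parsing is strict: malformed rows and duplicate time
#' points within a series are errors unless `lenient = TRUE` (malformed
#' rows are then dropped with a warning; duplicates are always errors).
#'
#' @param path CSV file path.
#' @param lenient Drop malformed rows instead of erroring. Default FALSE.
#' @return List of [tht_timecourse()] objects, one per
#'   (condition, replicate) series.
#' @export
read_timecourse_csv <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df0 <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  time_col <- intersect(c("time_h", "time_s"), names(df0))
  if (length(time_col) == 0L)
    stop("missing required column(s): time_h or time_s")
  time_col <- time_col[1]
  df <- .read_strict_csv(path, required = c(time_col, "intensity"),
                         numeric_cols = c(time_col, "intensity"),
                         lenient = lenient)
  if (nrow(df) == 0L) stop("no data rows after parsing")
  if (any(df$intensity < 0)) stop("intensities must be >= 0")
  df$time_s <- if (time_col == "time_h") hours_to_seconds(df[[time_col]]) else df[[time_col]]
  if (is.null(df$condition)) df$condition <- "unspecified"
  if (is.null(df$replicate)) df$replicate <- "mean"
  key <- interaction(df$condition, df$replicate, drop = TRUE)
  out <- lapply(split(df, key), function(s) {
    s <- s[order(s$time_s), ]
    if (anyDuplicated(s$time_s))
      stop("duplicate time point for condition '", s$condition[1],
           "', replicate '", s$replicate[1], "'")
    tht_timecourse(s$time_s, s$intensity,
                   condition = s$condition[1], replicate = s$replicate[1])
  })
  names(out) <- levels(key)
  out
}

#' Write ThT time courses to CSV
#'
#' Inverse of [read_timecourse_csv()]; times are written in the requested
#' unit.
#'
#' @param tc_list List of [tht_timecourse()] objects (or a single one).
#' @param path Output CSV path.
#' @param time_unit `"h"` or `"s"`.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc_list, path, time_unit = c("h", "s")) {
  time_unit <- match.arg(time_unit)
  if (inherits(tc_list, "tht_timecourse")) tc_list <- list(tc_list)
  rows <- do.call(rbind, lapply(tc_list, function(tc) {
    data.frame(time = if (time_unit == "h") tc$time_s / 3600 else tc$time_s,
               intensity = tc$intensity,
               condition = attr(tc, "condition"),
               replicate = attr(tc, "replicate"))
  }))
  names(rows)[1] <- paste0("time_", time_unit)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an AFM particle table from CSV
#'
#' Expects header columns `length_nm` and `height_nm` (optional
#' `condition`); unknown columns are dropped with a warning. Row order is
#' preserved. Non-positive measurements are errors that name the row.
#'
#' @param path CSV file path.
#' @param lenient Drop malformed rows instead of erroring. Default FALSE.
#' @return data.frame of class `particle_table` with columns `length_nm`,
#'   `height_nm` (and `condition` if present).
#' @export
read_particle_csv <- function(path, lenient = FALSE) {
  df <- .read_strict_csv(path, required = c("length_nm", "height_nm"),
                         numeric_cols = c("length_nm", "height_nm"),
                         lenient = lenient)
  bad <- which(df$length_nm <= 0 | df$height_nm <= 0)
  if (length(bad))
    stop("non-positive measurement at data row ", bad[1])
  class(df) <- c("particle_table", "data.frame")
  df
}

#' Write a particle table to CSV
#' @param particles data.frame with `length_nm`, `height_nm` (extra
#'   columns are kept).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_particle_csv <- function(particles, path) {
  stopifnot(all(c("length_nm", "height_nm") %in% names(particles)))
  utils::write.csv(as.data.frame(particles), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a rate-constants table from CSV
#'
#' Expects header columns `condition`, `kn_per_s`, `ke_per_mol_s` with
#' unique condition labels and positive constants.
#'
#' @param path CSV file path.
#' @return data.frame with the three columns.
#' @export
read_constants_csv <- function(path) {
  df <- .read_strict_csv(path, required = c("condition", "kn_per_s", "ke_per_mol_s"),
                         numeric_cols = c("kn_per_s", "ke_per_mol_s"))
  if (any(df$kn_per_s <= 0) || any(df$ke_per_mol_s <= 0))
    stop("rate constants must be positive")
  if (anyDuplicated(df$condition)) stop("condition labels must be unique")
  df
}
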