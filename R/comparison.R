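#' Published nucleation and elongation rate constants
#'
#' The packaged per-condition constants for amyloid-beta(1-42) aggregation
#' alone and with DOPC, cholesterol-containing, and 7-ketocholesterol-
#' containing vesicles, at 80 uM peptide: `kn` in s^-1 and `ke` in
#' L mol^-1 s^-1. These printed constants are fixture inputs for
#' fold-change comparison, not quantities the package re-derives.
#'
#' @return data.frame with columns `condition`, `kn_per_s`, `ke_per_mol_s`.
#' @export
#' @examples
#' abeta_rate_constants()
abeta_rate_constants <- function() {
  path <- system.file("extdata", "abeta42_rate_constants.csv",
                      package = "aggkin", mustWork = TRUE)
  read_constants_csv(path)
}

# round half away from zero (the presentation convention of the source
# constants); base round() rounds half to even. The 1e-9 nudge keeps
# decimal halves (stored in binary just below .5) rounding upward.
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Fold change between two rate constants
#'
#' The fold is always reported as a ratio >= 1 (`max/min`); the direction
#' states whether `x` is increased, decreased or unchanged relative to
#' `y`. `ratio_rounded` applies half-away-from-zero rounding at 2
#' decimals.
#'
#' @param x,y Positive rate constants (same parameter, two conditions).
#' @param parameter Optional label, `"kn"` or `"ke"`.
#' @param condition_a,condition_b Optional condition labels for `x`, `y`.
#' @return One-row data.frame with `parameter`, `condition_a`,
#'   `condition_b`, `ratio`, `direction`, `ratio_rounded`.
#' @export
#' @examples
#' fold_change(5.573, 3.378, "ke", "Chol", "alone") # 1.65, increased
fold_change <- function(x, y, parameter = NA_character_,
                        condition_a = NA_character_,
                        condition_b = NA_character_) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L)
  if (!is.finite(x) || x <= 0 || !is.finite(y) || y <= 0)
    stop("rate constants must be finite and positive")
  ratio <- max(x, y) / min(x, y)
  direction <- if (x > y) "increased" else if (x < y) "decreased" else "unchanged"
  data.frame(parameter = parameter, condition_a = condition_a,
             condition_b = condition_b, ratio = ratio,
             direction = direction,
             ratio_rounded = round_half_away(ratio, 2L))
}

#' Pairwise fold-change comparison across conditions
#'
#' For every requested condition pair, computes the fold change of both
#' constants (kn then ke), preserving pair order.
#'
#' @param constants data.frame with columns `condition`, `kn_per_s`,
#'   `ke_per_mol_s` and unique condition labels (see
#'   [abeta_rate_constants()]).
#' @param pairs List of length-2 character vectors `c(condition_a,
#'   condition_b)`; defaults to the four study comparisons (Chol vs alone,
#'   Chol vs DOPC, 7keto vs alone, 7keto vs Chol).
#' @return data.frame of stacked [fold_change()] rows, one per
#'   pair-parameter combination.
#' @export
#' @examples
#' compare_conditions(abeta_rate_constants())
compare_conditions <- function(constants,
                               pairs = list(c("Chol", "alone"),
                                            c("Chol", "DOPC"),
                                            c("7keto", "alone"),
                                            c("7keto", "Chol"))) {
  stopifnot(is.data.frame(constants),
            all(c("condition", "kn_per_s", "ke_per_mol_s") %in% names(constants)))
  if (anyDuplicated(constants$condition))
    stop("condition labels must be unique")
  if (!is.list(pairs) || length(pairs) == 0L)
    stop("'pairs' must be a non-empty list of condition pairs")
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2L)
    for (lab in pr)
      if (!lab %in% constants$condition)
        stop("unknown condition label: '", lab, "'")
    ca <- constants[constants$condition == pr[1], ]
    cb <- constants[constants$condition == pr[2], ]
    rbind(
      fold_change(ca$kn_per_s, cb$kn_per_s, "kn", pr[1], pr[2]),
      fold_change(ca$ke_per_mol_s, cb$ke_per_mol_s, "ke", pr[1], pr[2]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a structured analysis report
#'
#' Bundles fit results, fold-change comparisons and morphology summaries
#' into one machine-readable structure, stamped with the package version
#' and the seeds/options in force, and optionally writes JSON.
#'
#' @param fits Optional named list of `fit_result` objects.
#' @param comparisons Optional data.frame from [compare_conditions()].
#' @param morphology Optional named list of `species_summary` data.frames.
#' @param seed Optional seed to record.
#' @param file Optional path; when given, the JSON rendering is written
#'   there.
#' @return List of class `aggkin_report`. Sections without input are
#'   omitted.
#' @export
render_report <- function(fits = NULL, comparisons = NULL, morphology = NULL,
                          seed = NULL, file = NULL) {
  if (is.null(fits) && is.null(comparisons) && is.null(morphology))
    stop("at least one report section must be supplied")
  report <- list(
    package = "aggkin",
    version = as.character(utils::packageVersion("aggkin")),
    schema = "aggkin-report/1",
    seed = seed,
    flags = list(
      intensity_normalization = "F0 and dF fitted jointly, not endpoint-normalized",
      fold_convention = "ratio = max/min, rounded half away from zero at 2 decimals",
      rule_precedence = "fibril (priority 1) before protofibril in overlap"))
  if (!is.null(fits)) {
    report$fits <- lapply(fits, function(f) list(
      k = f$params$k, rho = f$params$rho,
      kn = f$rates$kn, ke = f$rates$ke, a = f$rates$a,
      F0 = f$F0, dF = f$dF, sse = f$sse, r_squared = f$r_squared,
      converged = f$converged, sigmoidal = f$sigmoidal))
  }
  if (!is.null(comparisons)) report$comparisons <- comparisons
  if (!is.null(morphology))
    report$morphology <- lapply(morphology, as.data.frame)
  class(report) <- "aggkin_report"
  if (!is.null(file))
    jsonlite::write_json(unclass(report), file, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
  report
}

#' @export
print.aggkin_report <- function(x, ...) {
  cat(sprintf("aggkin report (schema %s, version %s)\n", x$schema, x$version))
  if (!is.null(x$seed)) cat("seed:", x$seed, "\n")
  if (!is.null(x$fits)) {
    cat("\nfits:\n")
    for (nm in names(x$fits)) {
      f <- x$fits[[nm]]
      cat(sprintf("  %-12s kn = %.4g /s, ke = %.4g L/mol/s, R^2 = %.4f%s\n",
                  nm, f$kn, f$ke, f$r_squared,
                  if (isTRUE(f$sigmoidal)) "" else " [non-sigmoidal]"))
    }
  }
  if (!is.null(x$comparisons)) {
    cat("\nfold changes:\n")
    cc <- x$comparisons
    for (i in seq_len(nrow(cc)))
      cat(sprintf("  %s: %s vs %s = %.2f-fold %s\n", cc$parameter[i],
                  cc$condition_a[i], cc$condition_b[i],
                  cc$ratio_rounded[i], cc$direction[i]))
  }
  if (!is.null(x$morphology)) {
    cat("\nmorphology:\n")
    for (nm in names(x$morphology)) {
      s <- x$morphology[[nm]]
      cat(sprintf("  %s: %s\n", nm,
                  paste(sprintf("%s %.1f%%", s$species, 100 * s$fraction),
                        collapse = ", ")))
    }
  }
  invisible(x)
}
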