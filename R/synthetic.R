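#' Measurement-noise specification for synthetic ThT curves
#'
#' @param sigma_rel Noise standard deviation as a fraction of the curve
#'   amplitude `dF`; must be in `[0, 0.5)`.
#' @param seed Integer RNG seed.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sigma_rel = 0.02, seed = 1L) {
  stopifnot(is.numeric(sigma_rel), length(sigma_rel) == 1L)
  if (sigma_rel < 0 || sigma_rel >= 0.5)
    stop("'sigma_rel' must be in [0, 0.5)")
  structure(list(sigma_rel = sigma_rel, seed = as.integer(seed)),
            class = "noise_spec")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' The study's sampling schedule, in seconds
#'
#' The default incubation read-out times 0, 6, 12, 24, 36 and 48 h.
#' @return Numeric vector of 6 times in seconds.
#' @export
default_schedule <- function() hours_to_seconds(c(0, 6, 12, 24, 36, 48))

#' Simulate noisy ThT fluorescence time courses
#'
#' Generates `intensity(t) = F0 + dF * f(t; k, rho) + eps` with
#' `eps ~ Normal(0, sigma_rel * dF)`, truncated below at 0. Replicate `r`
#' draws from the substream seeded with `seed + r` so replicates are
#' independent yet individually reproducible.
#'
#' @param rates A [kinetic_rates()] object.
#' @param times Sampling times in seconds; default [default_schedule()].
#' @param noise A [noise_spec()].
#' @param n_replicates Number of replicates, >= 1. Default 3.
#' @param F0 Baseline intensity. Default 0.
#' @param dF Amplitude (plateau minus baseline). Default 1. Must be > 0.
#' @param condition Condition label attached to each series.
#' @return List of `n_replicates` [tht_timecourse()] objects.
#' @export
#' @examples
#' r <- kinetic_rates(3.73e-6, 3.378, 80e-6)
#' sims <- simulate_tht(r, noise = noise_spec(0.02, seed = 7))
#' sims[[1]]
simulate_tht <- function(rates, times = default_schedule(),
                         noise = noise_spec(), n_replicates = 3L,
                         F0 = 0, dF = 1, condition = "synthetic") {
  stopifnot(inherits(rates, "kinetic_rates"), inherits(noise, "noise_spec"))
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  if (dF <= 0) stop("'dF' must be > 0")
  if (F0 < 0) stop("'F0' must be >= 0")
  if (is.unsorted(times, strictly = TRUE) || any(times < 0))
    stop("'times' must be strictly increasing and >= 0")
  params <- reduce_rates(rates)
  mean_int <- F0 + dF * fibril_fraction(params, times)
  lapply(seq_len(n_replicates), function(r) {
    eps <- if (noise$sigma_rel == 0) 0 else
      .with_seed(noise$seed + r,
                 stats::rnorm(length(times), 0, noise$sigma_rel * dF))
    tht_timecourse(times, pmax(0, mean_int + eps),
                   condition = condition, replicate = as.character(r))
  })
}

#' Particle-population mixture specification
#'
#' Describes an AFM particle population as a weighted mixture of aggregate
#' species. Within a species, lengths are log-normal (strictly positive
#' and right-skewed, as typical of AFM length measurements) and heights
#' are normal truncated at 0 (narrow and near-symmetric); length and
#' height are independent within a species.
#'
#' @param species data.frame with columns `species`, `weight`,
#'   `length_median_nm`, `length_sdlog`, `height_mean_nm`, `height_sd_nm`.
#'   Weights must be >= 0 and sum to 1; medians must be > 0.
#' @param seed Integer RNG seed used by [simulate_particles()].
#' @return A list of class `morph_mixture_spec`.
#' @export
morph_mixture_spec <- function(species, seed = 1L) {
  need <- c("species", "weight", "length_median_nm", "length_sdlog",
            "height_mean_nm", "height_sd_nm")
  stopifnot(is.data.frame(species))
  missing <- setdiff(need, names(species))
  if (length(missing))
    stop("missing mixture columns: ", paste(missing, collapse = ", "))
  if (any(species$weight < 0) || abs(sum(species$weight) - 1) > 1e-9)
    stop("species weights must be >= 0 and sum to 1")
  if (any(species$length_median_nm <= 0))
    stop("length medians must be > 0")
  if (any(species$length_sdlog <= 0) || any(species$height_sd_nm < 0))
    stop("dispersion parameters must be positive")
  structure(list(species = species[need], seed = as.integer(seed)),
            class = "morph_mixture_spec")
}

#' Draw a synthetic AFM particle table from a mixture
#'
#' Species-first sampling: each particle's species is drawn categorically
#' by weight, then its length (log-normal) and height (truncated normal,
#' redrawn while non-positive) from that species' distributions.
#' Bit-reproducible under the mixture's seed.
#'
#' @param mix A [morph_mixture_spec()].
#' @param n Number of particles, >= 1.
#' @return data.frame of class `particle_table` with columns `length_nm`,
#'   `height_nm`, `species_true`.
#' @export
simulate_particles <- function(mix, n) {
  stopifnot(inherits(mix, "morph_mixture_spec"), n >= 1L)
  sp <- mix$species
  .with_seed(mix$seed, {
    idx <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$weight)
    len <- stats::rlnorm(n, log(sp$length_median_nm[idx]), sp$length_sdlog[idx])
    ht <- stats::rnorm(n, sp$height_mean_nm[idx], sp$height_sd_nm[idx])
    bad <- which(ht <= 0)
    while (length(bad)) {
      ht[bad] <- stats::rnorm(length(bad), sp$height_mean_nm[idx[bad]],
                              sp$height_sd_nm[idx[bad]])
      bad <- bad[ht[bad] <= 0]
    }
    out <- data.frame(length_nm = len, height_nm = ht,
                      species_true = sp$species[idx])
    class(out) <- c("particle_table", "data.frame")
    out
  })
}

#' Preset particle mixtures emulating the reported AFM morphologies
#'
#' Returns a frozen mixture whose analytic bin masses reproduce, within
#' about 3 percentage points, the percentages reported for each imaging
#' condition: protofibril-dominated populations at 12 h alone and 24 h
#' with 7-ketocholesterol vesicles, a fibril-dominated population at 24 h
#' alone, long-but-thin aggregates with DOPC vesicles, and fibrils with
#' cholesterol vesicles. The constants are documented package fixtures,
#' not fitted values; see [mixture_bin_mass()] for the analytic masses.
#'
#' @param condition One of `"alone_12h"`, `"alone_24h"`, `"dopc_24h"`,
#'   `"chol_12h"`, `"chol_24h"`, `"7keto_24h"`.
#' @param seed Integer RNG seed for subsequent sampling.
#' @return A [morph_mixture_spec()].
#' @export
#' @examples
#' mix <- preset_mixture("alone_12h")
#' mix$species
preset_mixture <- function(condition, seed = 1L) {
  path <- system.file("extdata", "morphology_presets.csv", package = "aggkin",
                      mustWork = TRUE)
  presets <- utils::read.csv(path, stringsAsFactors = FALSE)
  valid <- unique(presets$condition)
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% valid)
    stop("unknown condition; valid labels: ", paste(valid, collapse = ", "))
  rows <- presets[presets$condition == condition,
                  setdiff(names(presets), "condition")]
  rownames(rows) <- NULL
  morph_mixture_spec(rows, seed = seed)
}

#' Analytic bin mass of a particle mixture
#'
#' Exact population probability that a particle falls in `[lo, hi]` on one
#' axis, computed from the mixture's distribution functions (no sampling).
#'
#' @param mix A [morph_mixture_spec()].
#' @param axis `"length"` or `"height"`.
#' @param lo,hi Bin bounds in nm.
#' @return Probability in `[0, 1]`.
#' @export
mixture_bin_mass <- function(mix, axis = c("length", "height"), lo, hi) {
  stopifnot(inherits(mix, "morph_mixture_spec"), lo < hi)
  axis <- match.arg(axis)
  sp <- mix$species
  per <- if (axis == "length") {
    stats::plnorm(hi, log(sp$length_median_nm), sp$length_sdlog) -
      stats::plnorm(lo, log(sp$length_median_nm), sp$length_sdlog)
  } else {
    trunc_norm <- 1 - stats::pnorm(0, sp$height_mean_nm, sp$height_sd_nm)
    (stats::pnorm(hi, sp$height_mean_nm, sp$height_sd_nm) -
       stats::pnorm(pmax(lo, 0), sp$height_mean_nm, sp$height_sd_nm)) / trunc_norm
  }
  sum(sp$weight * per)
}

#' Analytic species-class mass of a particle mixture
#'
#' Population probability of each classification label under a rule set,
#' computed from the mixture's distribution functions with the same
#' priority semantics as [classify_particles()] (inclusion-exclusion over
#' higher-priority rule boxes; length and height independent within a
#' species).
#'
#' @param mix A [morph_mixture_spec()].
#' @param rules A rule set from [default_rules()] (or compatible).
#' @return Named numeric vector of class probabilities, including
#'   `unclassified`, summing to 1.
#' @export
mixture_class_mass <- function(mix, rules = default_rules()) {
  stopifnot(inherits(mix, "morph_mixture_spec"))
  rules <- rules[order(rules$priority), ]
  sp <- mix$species
  pL <- function(lo, hi) stats::plnorm(hi, log(sp$length_median_nm), sp$length_sdlog) -
    stats::plnorm(lo, log(sp$length_median_nm), sp$length_sdlog)
  pH <- function(lo, hi) {
    tn <- 1 - stats::pnorm(0, sp$height_mean_nm, sp$height_sd_nm)
    (stats::pnorm(hi, sp$height_mean_nm, sp$height_sd_nm) -
       stats::pnorm(pmax(lo, 0), sp$height_mean_nm, sp$height_sd_nm)) / tn
  }
  out <- numeric(0)
  for (i in seq_len(nrow(rules))) {
    box <- pL(rules$length_min[i], rules$length_max[i]) *
      pH(rules$height_min[i], rules$height_max[i])
    # subtract intersections with all higher-priority boxes (rules here are
    # few; pairwise inclusion-exclusion suffices for <= 2 overlapping rules)
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        lmin <- max(rules$length_min[i], rules$length_min[j])
        lmax <- min(rules$length_max[i], rules$length_max[j])
        hmin <- max(rules$height_min[i], rules$height_min[j])
        hmax <- min(rules$height_max[i], rules$height_max[j])
        if (lmin < lmax && hmin < hmax)
          box <- box - pL(lmin, lmax) * pH(hmin, hmax)
      }
    }
    out[rules$species[i]] <- sum(sp$weight * box)
  }
  c(out, unclassified = 1 - sum(out))
}
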