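#' Default species classification rules
#'
#' Two joint length-height rules derived from the reported AFM
#' morphometry: mature fibrils are 200-1000 nm long and 2-6 nm high;
#' protofibrils are 50-250 nm long and 1-4 nm high. Intervals are closed
#' at both ends. The fibril rule has priority 1, so particles in the
#' overlapping 200-250 nm / 2-4 nm region are called fibril (the more
#' mature species); anything matching no rule is `"unclassified"`.
#'
#' @return data.frame of class `morphology_rules` with columns `species`,
#'   `length_min`, `length_max`, `height_min`, `height_max`, `priority`.
#' @export
default_rules <- function() {
  out <- data.frame(
    species = c("fibril", "protofibril"),
    length_min = c(200, 50), length_max = c(1000, 250),
    height_min = c(2, 1), height_max = c(6, 4),
    priority = c(1L, 2L))
  class(out) <- c("morphology_rules", "data.frame")
  out
}

.validate_rules <- function(rules) {
  need <- c("species", "length_min", "length_max", "height_min",
            "height_max", "priority")
  stopifnot(is.data.frame(rules))
  missing <- setdiff(need, names(rules))
  if (length(missing))
    stop("missing rule columns: ", paste(missing, collapse = ", "))
  if (any(rules$length_min > rules$length_max) ||
      any(rules$height_min > rules$height_max))
    stop("rule interval minima must not exceed maxima")
  if (anyDuplicated(rules$priority))
    stop("rule priorities must be unique")
  rules
}

#' Classify particles into aggregate species
#'
#' Evaluates rules in priority order (lowest number first); the first rule
#' whose length AND height intervals (closed) both contain the particle
#' wins. Particles matching no rule are labelled `"unclassified"`.
#'
#' @param particles data.frame with columns `length_nm`, `height_nm`
#'   (positive).
#' @param rules A rule set from [default_rules()] or compatible.
#' @return Character vector of species labels, one per particle.
#' @export
#' @examples
#' classify_particles(data.frame(length_nm = c(120, 600, 220),
#'                               height_nm = c(2.5, 4.5, 3)))
classify_particles <- function(particles, rules = default_rules()) {
  stopifnot(is.data.frame(particles),
            all(c("length_nm", "height_nm") %in% names(particles)))
  if (any(particles$length_nm <= 0) || any(particles$height_nm <= 0))
    stop("particle lengths and heights must be positive")
  rules <- .validate_rules(rules)
  rules <- rules[order(rules$priority), ]
  labels <- rep("unclassified", nrow(particles))
  open <- rep(TRUE, nrow(particles))
  for (i in seq_len(nrow(rules))) {
    hit <- open &
      particles$length_nm >= rules$length_min[i] &
      particles$length_nm <= rules$length_max[i] &
      particles$height_nm >= rules$height_min[i] &
      particles$height_nm <= rules$height_max[i]
    labels[hit] <- rules$species[i]
    open <- open & !hit
  }
  labels
}

#' Summarize species composition of a particle table
#'
#' @param particles Non-empty data.frame with `length_nm`, `height_nm`.
#' @param rules A rule set (see [default_rules()]).
#' @return An object of class `species_summary`: data.frame with columns
#'   `species`, `count`, `fraction` covering every rule species plus
#'   `unclassified`; fractions sum to 1.
#' @export
summarize_species <- function(particles, rules = default_rules()) {
  if (!is.data.frame(particles) || nrow(particles) == 0L)
    stop("particle table must be non-empty")
  rules <- .validate_rules(rules)
  labels <- classify_particles(particles, rules)
  lvls <- c(rules$species[order(rules$priority)], "unclassified")
  counts <- table(factor(labels, levels = lvls))
  out <- data.frame(species = lvls, count = as.integer(counts),
                    fraction = as.numeric(counts) / nrow(particles))
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Histogram of particle lengths or heights
#'
#' Bins are half-open `[e_i, e_{i+1})` except the last, which is closed so
#' the upper edge is counted. Particles outside the edge range are tallied
#' separately, never silently dropped.
#'
#' @param particles data.frame with `length_nm`, `height_nm`.
#' @param axis `"length"` or `"height"`.
#' @param bin_edges Strictly increasing numeric vector of >= 2 edges, nm.
#' @return List with `counts` (length `length(bin_edges) - 1`),
#'   `bin_edges`, and `out_of_range`.
#' @export
distribution_histogram <- function(particles, axis = c("length", "height"),
                                   bin_edges) {
  stopifnot(is.data.frame(particles))
  axis <- match.arg(axis)
  if (!is.numeric(bin_edges) || length(bin_edges) < 2L ||
      is.unsorted(bin_edges, strictly = TRUE))
    stop("'bin_edges' must be >= 2 strictly increasing numbers")
  x <- if (axis == "length") particles$length_nm else particles$height_nm
  nb <- length(bin_edges) - 1L
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  in_range <- idx >= 1L & idx <= nb
  counts <- tabulate(idx[in_range], nbins = nb)
  list(counts = counts, bin_edges = bin_edges,
       out_of_range = sum(!in_range))
}
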