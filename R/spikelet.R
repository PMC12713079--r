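# Spikelet trajectory geometry: spikes carry different spikelet counts, so
# per-line ordered measurements (angle to the rachis, gap along it) are put
# on a common [0, 20] axis, summarised by a least-squares quartic, sampled
# at the 21 integer nodes, averaged over four regions (bottom 3, lower-
# middle 8, upper-middle 8, top 2 nodes) and typed I/N/D against the
# population per-region means.

#' Normalised spikelet positions on [0, 20]
#'
#' Spikelet i of n (bottom to top) maps to `20 * (i - 1) / (n - 1)`, so the
#' first spikelet sits at 0 and the last at 20 for any count.
#'
#' @param n_spikelets Number of spikelets (>= 5; a quartic needs 5 points).
#' @return Numeric vector of length `n_spikelets`.
#' @export
normalize_positions <- function(n_spikelets) {
  if (n_spikelets < 5) {
    stop("need at least 5 spikelets for a quartic fit", call. = FALSE)
  }
  20 * (seq_len(n_spikelets) - 1) / (n_spikelets - 1)
}

#' Least-squares quartic fit
#'
#' Degree-4 polynomial fit of `values` on `positions`; interpolates exactly
#' when given 5 distinct points.
#'
#' @param positions,values Numeric vectors of equal length (>= 5 distinct
#'   positions).
#' @return Coefficients `c0..c4` (intercept first).
#' @export
fit_quartic <- function(positions, values) {
  stopifnot(length(positions) == length(values))
  if (length(unique(positions)) < 5) {
    stop("quartic fit needs at least 5 distinct positions", call. = FALSE)
  }
  V <- outer(positions, 0:4, `^`)
  fit <- stats::lm.fit(V, values)
  if (fit$rank < 5) stop("rank-deficient quartic design", call. = FALSE)
  coefs <- fit$coefficients
  names(coefs) <- paste0("c", 0:4)
  coefs
}

eval_quartic <- function(coefs, x) {
  # Horner evaluation
  ((((coefs[5] * x + coefs[4]) * x + coefs[3]) * x + coefs[2]) * x) + coefs[1]
}

#' Evaluate a fitted trajectory at the 21 integer nodes
#'
#' The fitted curve is divided into 20 equal segments, i.e. evaluated at
#' positions 0, 1, ..., 20.
#'
#' @param coefficients Quartic coefficients `c0..c4`.
#' @return Numeric vector of exactly 21 node values.
#' @export
interpolate_nodes <- function(coefficients) {
  stopifnot(length(coefficients) == 5)
  unname(eval_quartic(coefficients, 0:20))
}

#' Partition the 21 nodes into four spike regions
#'
#' Sequential groups of 3, 8, 8 and 2 nodes (bottom, lower-middle,
#' upper-middle, top), returning the group means.
#'
#' @param node_values 21 node values.
#' @param sizes Group sizes summing to 21.
#' @return Named numeric vector of 4 region means.
#' @export
partition_regions <- function(node_values, sizes = c(3L, 8L, 8L, 2L)) {
  if (length(node_values) != 21) stop("expected 21 node values", call. = FALSE)
  if (length(sizes) != 4 || sum(sizes) != 21) {
    stop("region sizes must be 4 groups summing to 21", call. = FALSE)
  }
  grp <- rep(seq_len(4), sizes)
  means <- tapply(node_values, grp, mean)
  stats::setNames(as.numeric(means),
                  c("bottom", "lower_middle", "upper_middle", "top"))
}

#' Classify a line's spike regions as Increased / uNchanged / Decreased
#'
#' Per region: `I` if the line mean exceeds the population mean by more than
#' `rel_tolerance` (relative), `D` if below by more, else `N`. A zero
#' population mean falls back to an absolute band of `rel_tolerance`.
#'
#' @param region_means Line's 4 region means.
#' @param population_means Population's 4 region means.
#' @param rel_tolerance Relative "approximately equal" band (default 2.5%).
#' @return Single 4-character code over \{I, N, D\}, bottom to top.
#' @export
classify_ind <- function(region_means, population_means, rel_tolerance = 0.025) {
  stopifnot(length(region_means) == 4, length(population_means) == 4)
  letters3 <- vapply(seq_len(4), function(i) {
    p <- population_means[i]
    band <- if (p == 0) rel_tolerance else abs(p) * rel_tolerance
    d <- region_means[i] - p
    if (d > band) "I" else if (d < -band) "D" else "N"
  }, character(1))
  paste(letters3, collapse = "")
}

#' Enumerate the full I/N/D spike-type code space
#'
#' @return Character vector of all 81 (= 3^4) codes, lexicographic.
#' @export
spike_code_space <- function() {
  g <- expand.grid(r4 = c("D", "I", "N"), r3 = c("D", "I", "N"),
                   r2 = c("D", "I", "N"), r1 = c("D", "I", "N"),
                   stringsAsFactors = FALSE)
  sort(paste0(g$r1, g$r2, g$r3, g$r4))
}

#' Spike-type code frequencies
#'
#' @param codes Character vector of 4-letter I/N/D codes.
#' @return `data.frame` `code`, `count`, `proportion` over the observed
#'   codes (proportions sum to 1).
#' @export
type_frequencies <- function(codes) {
  if (!all(grepl("^[IND]{4}$", codes))) {
    stop("invalid spike-type code(s)", call. = FALSE)
  }
  cnt <- table(codes)
  out <- data.frame(code = names(cnt), count = as.integer(cnt),
                    proportion = as.numeric(cnt) / length(codes),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$code), , drop = FALSE]
}

#' Fit per-line spike profiles from a spikelet measurement table
#'
#' For every line with >= 5 spikelets: normalise positions to [0, 20], fit
#' the quartic, evaluate the 21 nodes and the 4 region means. Lines with too
#' few spikelets are excluded and listed in the result.
#'
#' @param spikelets `data.frame` with `line_id`, `spikelet_index` and the
#'   measurement column `trait` (values ordered bottom to top by index).
#' @param trait Measurement column (e.g. `"angle"` or `"gap"`).
#' @param sizes Region sizes (see [partition_regions()]).
#' @return Object of class `spike_profiles`: `nodes` (lines x 21 matrix),
#'   `regions` (lines x 4), `coefficients` (lines x 5), `trait`,
#'   `excluded` (line ids with < 5 spikelets).
#' @export
spike_profiles <- function(spikelets, trait = "angle",
                           sizes = c(3L, 8L, 8L, 2L)) {
  stopifnot(all(c("line_id", "spikelet_index", trait) %in% names(spikelets)))
  by_line <- split(spikelets, spikelets$line_id)
  ok <- vapply(by_line, nrow, integer(1)) >= 5
  if (any(!ok)) {
    warning(sum(!ok), " line(s) with fewer than 5 spikelets excluded")
  }
  fits <- lapply(by_line[ok], function(d) {
    d <- d[order(d$spikelet_index), , drop = FALSE]
    co <- fit_quartic(normalize_positions(nrow(d)), d[[trait]])
    nodes <- interpolate_nodes(co)
    list(co = co, nodes = nodes, regions = partition_regions(nodes, sizes))
  })
  nodes <- do.call(rbind, lapply(fits, `[[`, "nodes"))
  regions <- do.call(rbind, lapply(fits, `[[`, "regions"))
  coefs <- do.call(rbind, lapply(fits, `[[`, "co"))
  colnames(nodes) <- paste0("node", 0:20)
  structure(list(nodes = nodes, regions = regions, coefficients = coefs,
                 trait = trait, sizes = sizes,
                 excluded = names(by_line)[!ok]),
            class = "spike_profiles")
}

#' @export
print.spike_profiles <- function(x, ...) {
  cat("Spike profiles (", x$trait, "): ", nrow(x$nodes), " lines, 21 nodes, ",
      "regions ", paste(x$sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Assign I/N/D spike-type codes to every line
#'
#' Compares each line's region means with the population per-region means
#' (column means over all lines by default; a whole-spike grand mean can be
#' used instead).
#'
#' @param profiles A [spike_profiles()] object.
#' @param rel_tolerance Relative "approximately equal" band.
#' @param population One of `"per_region"` (default) or `"whole_spike"`.
#' @return Named character vector of codes, one per line.
#' @export
spike_type_codes <- function(profiles, rel_tolerance = 0.025,
                             population = c("per_region", "whole_spike")) {
  population <- match.arg(population)
  pop <- if (population == "per_region") colMeans(profiles$regions) else
    rep(mean(profiles$nodes), 4)
  codes <- apply(profiles$regions, 1, classify_ind, population_means = pop,
                 rel_tolerance = rel_tolerance)
  stats::setNames(codes, rownames(profiles$regions))
}

#' Cluster lines by their 21-node trajectory profiles
#'
#' Hierarchical agglomerative clustering (Ward linkage on Euclidean
#' distance) of the node-value matrix; deterministic.
#'
#' @param nodes Lines x 21 node matrix (or a `spike_profiles` object).
#' @param k Number of clusters.
#' @param h Alternatively, a cut height.
#' @return Named integer cluster labels.
#' @export
cluster_profiles <- function(nodes, k = NULL, h = NULL) {
  if (inherits(nodes, "spike_profiles")) nodes <- nodes$nodes
  if (nrow(nodes) < 2) stop("need at least 2 lines to cluster", call. = FALSE)
  if (!is.null(k) && k > nrow(nodes)) {
    stop("fewer lines than requested clusters", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(nodes), method = "ward.D2")
  stats::cutree(hc, k = k, h = h)
}
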