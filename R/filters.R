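#' Quality-filter a mutation table
#'
#' Retains records with `qual >= min_qual` and `depth >= min_depth` (the
#' usual bcftools-style exclusion `QUAL < 50 || DP < 5` inverted). Records
#' with missing QUAL or depth fail the filter and are counted in a message.
#'
#' @param table Mutation table.
#' @param min_qual Minimum Phred-scaled site quality.
#' @param min_depth Minimum read depth.
#' @return Filtered mutation table.
#' @export
filter_by_quality <- function(table, min_qual = 50, min_depth = 5) {
  assert_mutation_table(table)
  if (!nrow(table)) return(table)
  keep <- !is.na(table$qual) & !is.na(table$depth) &
    table$qual >= min_qual & table$depth >= min_depth
  n_na <- sum(is.na(table$qual) | is.na(table$depth))
  if (n_na) message(n_na, " records with missing qual/depth removed")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "line_ids") <- attr(table, "line_ids")
  out
}

#' Per-site population mutation frequency
#'
#' For each distinct site (chrom, pos, alt), the fraction of lines carrying
#' it: distinct carrier lines / `n_lines`.
#'
#' @param table Mutation table.
#' @param n_lines Total number of lines in the population.
#' @return `data.frame` with `chrom`, `pos`, `alt`, `n_carriers`, `freq`.
#' @export
site_mutation_frequency <- function(table, n_lines) {
  assert_mutation_table(table)
  stopifnot_scalar_number(n_lines, "n_lines", min = 1)
  if (!nrow(table)) {
    return(data.frame(chrom = character(), pos = integer(), alt = character(),
                      n_carriers = integer(), freq = numeric()))
  }
  key <- site_key(table)
  # (line, site) pairs are unique by the table invariant, so carrier count
  # per site is the key count
  cnt <- table(key)
  first <- !duplicated(key)
  out <- data.frame(chrom = table$chrom[first], pos = table$pos[first],
                    alt = table$alt[first], stringsAsFactors = FALSE)
  out$n_carriers <- as.integer(cnt[key[first]])
  out$freq <- out$n_carriers / n_lines
  rownames(out) <- NULL
  out
}

# One permutation step: reassign each line's mutations uniformly at random
# (without replacement within the line) over the site catalogue, preserving
# the line's mutation count.
permute_line_sites <- function(counts_per_line, n_sites) {
  lapply(counts_per_line, function(k) sample.int(n_sites, min(k, n_sites)))
}

#' Null population-frequency threshold by genotype permutation
#'
#' Calibrates how often a site is expected to be shared across lines purely
#' by chance. In each permutation every line's mutations are reassigned
#' uniformly at random (without replacement within a line) over the site
#' catalogue, preserving the line's mutation count; per-site carrier
#' frequencies are recomputed over the full catalogue (unhit sites count as
#' zero), and the upper-tail boundary — the `per_perm_tail`-th largest
#' frequency — is retained as that permutation's summary. The threshold is
#' the `rank`-th largest summary across `n_perm` permutations; the tail size
#' and rank are deliberately exposed as parameters since they set the
#' stringency of the calibration.
#'
#' @param table Mutation table (post quality filter).
#' @param n_lines Population size.
#' @param n_perm Number of permutations.
#' @param per_perm_tail Size of the retained upper tail per permutation.
#' @param rank Rank (1 = most extreme) of the cross-permutation summary used
#'   as the threshold.
#' @param seed Integer seed.
#' @return An object of class `freq_threshold` with fields `threshold`,
#'   `n_perm`, `per_perm_tail`, `rank`, `null_samples`, `seed`.
#' @export
null_frequency_threshold <- function(table, n_lines, n_perm = 1000,
                                     per_perm_tail = 500, rank = 5,
                                     seed = 1L) {
  assert_mutation_table(table)
  stopifnot_scalar_number(n_lines, "n_lines", min = 1)
  if (rank > n_perm) stop("rank cannot exceed n_perm", call. = FALSE)
  if (!nrow(table)) {
    return(structure(list(threshold = 0, n_perm = n_perm,
                          per_perm_tail = per_perm_tail, rank = rank,
                          null_samples = rep(0, n_perm), seed = seed),
                     class = "freq_threshold"))
  }
  n_sites <- length(unique(site_key(table)))
  counts_per_line <- table(table$line_id)
  tail_idx <- min(per_perm_tail, n_sites)
  with_seed(seed, {
    null_samples <- vapply(seq_len(n_perm), function(p) {
      hits <- unlist(permute_line_sites(counts_per_line, n_sites),
                     use.names = FALSE)
      carriers <- tabulate(hits, nbins = n_sites)
      # per_perm_tail-th largest carrier frequency over the whole catalogue
      sort(carriers, decreasing = TRUE)[tail_idx] / n_lines
    }, numeric(1))
    structure(list(threshold = sort(null_samples, decreasing = TRUE)[rank],
                   n_perm = n_perm, per_perm_tail = per_perm_tail,
                   rank = rank, null_samples = null_samples, seed = seed),
              class = "freq_threshold")
  })
}

#' @export
print.freq_threshold <- function(x, ...) {
  cat(sprintf(paste0("Permutation null frequency threshold: %.4g\n",
                     "  (%d permutations, per-permutation tail %d, rank %d)\n"),
              x$threshold, x$n_perm, x$per_perm_tail, x$rank))
  invisible(x)
}

#' Remove sites shared by implausibly many lines
#'
#' Drops all records at sites whose population frequency strictly exceeds
#' `threshold` (a site in 8 of 1000 lines is removed at threshold 0.007; a
#' site in 7 is kept). All lines' records at a removed site go together.
#'
#' @param table Mutation table.
#' @param threshold Frequency cutoff in `[0, 1]` (or a `freq_threshold`).
#' @param n_lines Population size used to convert carrier counts to
#'   frequencies.
#' @return Filtered mutation table.
#' @export
filter_by_population_frequency <- function(table, threshold, n_lines) {
  assert_mutation_table(table)
  if (inherits(threshold, "freq_threshold")) threshold <- threshold$threshold
  stopifnot_scalar_number(threshold, "threshold", 0, 1)
  if (!nrow(table)) return(table)
  key <- site_key(table)
  carriers <- table(key)
  drop <- names(carriers)[as.numeric(carriers) / n_lines > threshold]
  out <- table[!(key %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "line_ids") <- attr(table, "line_ids")
  out
}

#' Fraction of sites that are canonical EMS transitions
#'
#' Over distinct sites, the fraction whose (ref, alt) is one of G>A, A>G,
#' C>T, T>C. Sites with non-ACGT alleles are skipped with a warning.
#'
#' @param table Mutation table.
#' @return A proportion in `[0, 1]` (NA for an empty table).
#' @export
ems_transition_fraction <- function(table) {
  assert_mutation_table(table)
  key <- site_key(table)
  first <- !duplicated(key)
  ref <- table$ref[first]
  alt <- table$alt[first]
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!ok)) warning(sum(!ok), " sites with non-ACGT alleles skipped")
  if (!any(ok)) return(NA_real_)
  pair <- paste(ref[ok], alt[ok], sep = ">")
  mean(pair %in% c("G>A", "A>G", "C>T", "T>C"))
}
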