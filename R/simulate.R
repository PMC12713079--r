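#' Configuration for a synthetic EMS mutant population
#'
#' Bundles and validates every parameter of the synthetic EMS population
#' generator. Defaults reproduce the headline features of a sequenced wheat
#' EMS library: ~4072 mutations per line, 88.9% canonical EMS transitions
#' (G>A / C>T), and a SnpEff impact mixture dominated by MODERATE variants
#' (59.7%, remainder split equally over HIGH/LOW/MODIFIER).
#'
#' @param n_lines Number of mutant lines (>= 2).
#' @param genes Gene catalogue: a `data.frame` with columns `gene_id`,
#'   `n_sites`, `chrom`, `start`, `end` (1-based inclusive bp). Each gene
#'   contributes `n_sites` mutable positions `start, start+1, ...`; the span
#'   `end - start + 1` must be at least `n_sites`.
#' @param mean_mutations_per_line Mean mutation count per line. Per-line
#'   counts are Poisson by default (`count_model = "poisson"`) or exactly
#'   this value (`count_model = "fixed"`).
#' @param transition_fraction Probability that a site is a canonical EMS
#'   transition (G>A or C>T); the complement gives transversions.
#' @param impact_mixture Named proportions over HIGH/MODERATE/LOW/MODIFIER,
#'   summing to 1.
#' @param causal_effects Named numeric vector, gene_id -> additive phenotype
#'   effect per mutation carried in the gene.
#' @param epistatic_pairs `data.frame` with columns `gene_i`, `gene_j`,
#'   `effect`: pairwise interaction effects on carrier presence.
#' @param noise_sd,baseline Gaussian phenotype noise SD and intercept.
#' @param count_model `"poisson"` or `"fixed"` per-line mutation counts.
#' @param seed Integer seed; all generators are bitwise reproducible under a
#'   fixed seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_lines,
                       genes,
                       mean_mutations_per_line = 4072,
                       transition_fraction = 0.889,
                       impact_mixture = c(HIGH = (1 - 0.597) / 3,
                                          MODERATE = 0.597,
                                          LOW = (1 - 0.597) / 3,
                                          MODIFIER = (1 - 0.597) / 3),
                       causal_effects = numeric(),
                       epistatic_pairs = NULL,
                       noise_sd = 1,
                       baseline = 0,
                       count_model = c("poisson", "fixed"),
                       seed = 1L) {
  stopifnot_scalar_number(n_lines, "n_lines", min = 2)
  stopifnot_scalar_number(mean_mutations_per_line, "mean_mutations_per_line", min = 0)
  stopifnot_scalar_number(transition_fraction, "transition_fraction", 0, 1)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(baseline, "baseline")
  count_model <- match.arg(count_model)

  if (!is.data.frame(genes) || nrow(genes) == 0L) {
    stop("`genes` must be a non-empty data.frame (gene catalogue)", call. = FALSE)
  }
  needed <- c("gene_id", "n_sites", "chrom", "start", "end")
  if (length(setdiff(needed, names(genes)))) {
    stop("`genes` needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in catalogue", call. = FALSE)
  if (any(genes$n_sites < 1)) stop("every gene needs n_sites >= 1", call. = FALSE)
  if (any(genes$end - genes$start + 1 < genes$n_sites)) {
    stop("gene span shorter than n_sites for some gene", call. = FALSE)
  }

  impact_mixture <- impact_mixture[IMPACT_LEVELS]
  if (anyNA(impact_mixture)) {
    stop("impact_mixture must name all of ", paste(IMPACT_LEVELS, collapse = "/"),
         call. = FALSE)
  }
  if (any(impact_mixture < 0) || any(impact_mixture > 1) ||
      abs(sum(impact_mixture) - 1) > 1e-9) {
    stop("impact_mixture proportions must lie in [0,1] and sum to 1", call. = FALSE)
  }

  if (length(causal_effects)) {
    if (is.null(names(causal_effects)) ||
        !all(names(causal_effects) %in% genes$gene_id)) {
      stop("causal_effects must be named by gene ids present in the catalogue",
           call. = FALSE)
    }
  }
  if (!is.null(epistatic_pairs)) {
    stopifnot(is.data.frame(epistatic_pairs),
              all(c("gene_i", "gene_j", "effect") %in% names(epistatic_pairs)))
    if (!all(c(epistatic_pairs$gene_i, epistatic_pairs$gene_j) %in% genes$gene_id)) {
      stop("epistatic_pairs reference genes absent from the catalogue", call. = FALSE)
    }
  }

  total_sites <- sum(genes$n_sites)
  if (mean_mutations_per_line > total_sites) {
    stop("mean_mutations_per_line exceeds the total number of available sites (",
         total_sites, ")", call. = FALSE)
  }

  structure(list(n_lines = as.integer(n_lines), genes = genes,
                 mean_mutations_per_line = mean_mutations_per_line,
                 transition_fraction = transition_fraction,
                 impact_mixture = impact_mixture,
                 causal_effects = causal_effects,
                 epistatic_pairs = epistatic_pairs,
                 noise_sd = noise_sd, baseline = baseline,
                 count_model = count_model, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("EMS population simulation config\n",
      "  lines: ", x$n_lines, "; genes: ", nrow(x$genes),
      " (", sum(x$genes$n_sites), " sites)\n",
      "  mean mutations/line: ", x$mean_mutations_per_line,
      " (", x$count_model, ")\n",
      "  transition fraction: ", x$transition_fraction,
      "; MODERATE share: ", x$impact_mixture[["MODERATE"]], "\n",
      "  causal genes: ", length(x$causal_effects),
      "; epistatic pairs: ",
      if (is.null(x$epistatic_pairs)) 0L else nrow(x$epistatic_pairs), "\n",
      sep = "")
  invisible(x)
}

# Build the site catalogue: one row per mutable site with fixed ref/alt,
# impact, qual and depth. Site-level properties are drawn once so that the
# same site shared by several lines has one consistent VCF record.
build_site_catalogue <- function(config) {
  genes <- config$genes
  n_sites <- sum(genes$n_sites)
  gene_idx <- rep(seq_len(nrow(genes)), genes$n_sites)
  offset <- unlist(lapply(genes$n_sites, function(k) seq_len(k) - 1L),
                   use.names = FALSE)
  sites <- data.frame(
    chrom = genes$chrom[gene_idx],
    pos = genes$start[gene_idx] + offset,
    gene_id = genes$gene_id[gene_idx],
    stringsAsFactors = FALSE
  )

  is_transition <- stats::runif(n_sites) < config$transition_fraction
  # Canonical EMS events: G>A or C>T (equivalently C>T on the other strand).
  ems_ref <- sample(c("G", "C"), n_sites, replace = TRUE)
  ems_alt <- ifelse(ems_ref == "G", "A", "T")
  tv_ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  tv_alt <- vapply(tv_ref, function(r) {
    # transversions only: exclude the ref and its transition partner
    partner <- c(A = "G", G = "A", C = "T", T = "C")[[r]]
    sample(setdiff(c("A", "C", "G", "T"), c(r, partner)), 1L)
  }, character(1), USE.NAMES = FALSE)
  sites$ref <- ifelse(is_transition, ems_ref, tv_ref)
  sites$alt <- ifelse(is_transition, ems_alt, tv_alt)
  sites$impact <- sample(IMPACT_LEVELS, n_sites, replace = TRUE,
                         prob = config$impact_mixture)
  sites$qual <- round(stats::runif(n_sites, 30, 500), 1)
  sites$depth <- stats::rpois(n_sites, 15) + 1L
  sites
}

#' Simulate genotypes for an EMS mutant population
#'
#' Draws a per-line mutation count (Poisson with the configured mean, or
#' fixed), places mutations uniformly without replacement over the site
#' catalogue, and returns the long-form mutation table. Sites carry fixed
#' ref/alt (EMS transition with probability `transition_fraction`), a SnpEff
#' impact class from `impact_mixture`, and simulated QUAL / read depth.
#'
#' @param config A [sim_config()].
#' @return A mutation table `data.frame` with columns `line_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene_id`, `impact`, `qual`, `depth`, ordered
#'   site-major. The site catalogue is attached as attribute `"sites"` and
#'   the line ids as `"line_ids"`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    sites <- build_site_catalogue(config)
    n_sites <- nrow(sites)
    n_mut <- switch(config$count_model,
      poisson = stats::rpois(config$n_lines, config$mean_mutations_per_line),
      fixed = rep(as.integer(round(config$mean_mutations_per_line)), config$n_lines)
    )
    n_mut <- pmin(n_mut, n_sites)
    line_ids <- sprintf("L%04d", seq_len(config$n_lines))
    picks <- lapply(n_mut, function(k) sort(sample.int(n_sites, k)))
    idx <- unlist(picks, use.names = FALSE)
    tab <- sites[idx, , drop = FALSE]
    tab$line_id <- rep(line_ids, lengths(picks))
    tab <- tab[, c("line_id", "chrom", "pos", "ref", "alt", "gene_id",
                   "impact", "qual", "depth")]
    tab <- order_mutation_table(tab)
    attr(tab, "sites") <- sites
    attr(tab, "line_ids") <- line_ids
    tab
  })
}

#' Simulate phenotypes from a mutation table
#'
#' Additive gene-burden model with optional pairwise epistasis:
#' `y = baseline + sum_g effect_g * count_g + sum_(i,j) eps_ij * pres_i *
#' pres_j + N(0, noise_sd^2)`, where `count_g` is the line's mutation count
#' in gene g and `pres` its 0/1 carrier status. Wild-type reference rows
#' (zero mutations by construction) are appended and flagged.
#'
#' @param mutations Mutation table from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @param trait Name of the trait column.
#' @param n_wt Number of wild-type reference rows to append.
#' @return `data.frame` with columns `line_id`, `is_wt` and one trait column.
#' @export
simulate_phenotypes <- function(mutations, config, trait = "trait", n_wt = 10L) {
  stopifnot(inherits(config, "sim_config"))
  assert_mutation_table(mutations)
  line_ids <- attr(mutations, "line_ids")
  if (is.null(line_ids)) line_ids <- sort(unique(mutations$line_id))
  bad <- setdiff(names(config$causal_effects), config$genes$gene_id)
  if (length(bad)) stop("unknown gene in causal_effects: ",
                        paste(bad, collapse = ", "), call. = FALSE)

  with_seed(config$seed + 1L, {
    y <- rep(config$baseline, length(line_ids))
    names(y) <- line_ids
    if (length(config$causal_effects)) {
      for (g in names(config$causal_effects)) {
        cnt <- table(mutations$line_id[mutations$gene_id == g])
        y[names(cnt)] <- y[names(cnt)] +
          config$causal_effects[[g]] * as.numeric(cnt)
      }
    }
    if (!is.null(config$epistatic_pairs) && nrow(config$epistatic_pairs)) {
      for (r in seq_len(nrow(config$epistatic_pairs))) {
        gi <- config$epistatic_pairs$gene_i[r]
        gj <- config$epistatic_pairs$gene_j[r]
        pres_i <- line_ids %in% mutations$line_id[mutations$gene_id == gi]
        pres_j <- line_ids %in% mutations$line_id[mutations$gene_id == gj]
        y <- y + config$epistatic_pairs$effect[r] * (pres_i & pres_j)
      }
    }
    if (config$noise_sd > 0) y <- y + stats::rnorm(length(y), 0, config$noise_sd)
    wt <- if (n_wt > 0) {
      rep(config$baseline, n_wt) +
        (if (config$noise_sd > 0) stats::rnorm(n_wt, 0, config$noise_sd) else 0)
    } else numeric()
    out <- data.frame(
      line_id = c(line_ids, if (n_wt > 0) sprintf("WT%03d", seq_len(n_wt))),
      is_wt = c(rep(FALSE, length(line_ids)), rep(TRUE, n_wt)),
      stringsAsFactors = FALSE
    )
    out[[trait]] <- c(unname(y), wt)
    out
  })
}

#' Simulate per-line ordered spikelet measurement tables
#'
#' Each line is assigned a template trajectory (21 node values on positions
#' 0..20); its spikelet count is drawn from `n_spikelets_range`, and the
#' measurement at each spikelet is the template's least-squares quartic
#' evaluated at the line's normalised positions, plus Gaussian noise.
#' Ground-truth template labels are returned.
#'
#' @param n_lines Number of lines.
#' @param templates List of numeric vectors of length 21 (node values at
#'   positions 0..20, bottom to top).
#' @param proportions Assignment proportions over templates (sum to 1).
#' @param noise_sd Measurement noise SD.
#' @param seed Integer seed.
#' @param n_spikelets_range Integer range (min, max) of spikelets per line.
#' @param trait Measurement column name (e.g. `"angle"` or `"gap"`).
#' @return List with `data` (`line_id`, `spikelet_index`, trait column) and
#'   `labels` (named template index per line).
#' @export
simulate_spikelet_profiles <- function(n_lines, templates,
                                       proportions = rep(1 / length(templates),
                                                         length(templates)),
                                       noise_sd = 0, seed = 1L,
                                       n_spikelets_range = c(15L, 25L),
                                       trait = "angle") {
  if (!length(templates)) stop("need at least one template", call. = FALSE)
  if (!all(lengths(templates) == 21L)) {
    stop("every template must have exactly 21 node values", call. = FALSE)
  }
  if (length(proportions) != length(templates) ||
      abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must match templates and sum to 1", call. = FALSE)
  }
  if (min(n_spikelets_range) < 5) {
    stop("spikelet counts below 5 cannot support a quartic fit", call. = FALSE)
  }
  coefs <- lapply(templates, function(v) fit_quartic(0:20, v))
  with_seed(seed, {
    labels <- sample.int(length(templates), n_lines, replace = TRUE,
                         prob = proportions)
    line_ids <- sprintf("L%04d", seq_len(n_lines))
    names(labels) <- line_ids
    rows <- lapply(seq_len(n_lines), function(i) {
      n <- sample(seq(min(n_spikelets_range), max(n_spikelets_range)), 1L)
      pos <- normalize_positions(n)
      v <- eval_quartic(coefs[[labels[i]]], pos)
      if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)
      data.frame(line_id = line_ids[i], spikelet_index = seq_len(n),
                 value = v, stringsAsFactors = FALSE)
    })
    data <- do.call(rbind, rows)
    names(data)[names(data) == "value"] <- trait
    rownames(data) <- NULL
    list(data = data, labels = labels)
  })
}
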