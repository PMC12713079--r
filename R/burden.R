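#' Default impact weights for the weighted burden
#'
#' Numeric mutational-effect weights per SnpEff impact class used by the
#' weighted burden (the per-line, per-gene sum of effects). These defaults
#' are a package choice — impact classes are categorical upstream — and are
#' fully configurable; every burden object records the weights used.
#'
#' @return Named numeric vector over HIGH/MODERATE/LOW/MODIFIER.
#' @export
default_impact_weights <- function() {
  c(HIGH = 1.0, MODERATE = 0.66, LOW = 0.33, MODIFIER = 0.1)
}

#' Collapse per-site mutations into gene-level burden matrices
#'
#' The key move for rare EMS variants: site-level MAF is far too low for
#' association, but collapsing all mutations in a gene raises the gene-level
#' carrier frequency several-fold. Produces a raw count matrix, an
#' impact-weighted burden matrix and a 0/1 presence matrix (genes x lines).
#' Records without a gene assignment contribute to no gene and are counted
#' in a message.
#'
#' @param table Mutation table.
#' @param genes Gene catalogue (`data.frame` with `gene_id`) or a character
#'   vector of gene ids. Duplicated ids are an error.
#' @param line_ids Columns of the matrices; defaults to the table's attached
#'   line ids (lines with zero mutations keep all-zero columns).
#' @param weights Impact weights, see [default_impact_weights()].
#' @return An object of class `gene_burden`: list with `genes`, `lines`,
#'   `count`, `weighted`, `binary`, `impact_counts` (per-class count
#'   matrices) and `weights`.
#' @export
aggregate_by_gene <- function(table, genes, line_ids = NULL,
                              weights = default_impact_weights()) {
  assert_mutation_table(table)
  gene_ids <- if (is.data.frame(genes)) genes$gene_id else genes
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in catalogue", call. = FALSE)
  if (is.null(line_ids)) line_ids <- attr(table, "line_ids")
  if (is.null(line_ids)) line_ids <- sort(unique(table$line_id))

  unassigned <- is.na(table$gene_id)
  if (any(unassigned)) {
    message(sum(unassigned), " records without gene assignment excluded from burden")
  }
  tab <- table[!unassigned, , drop = FALSE]
  unknown <- setdiff(unique(tab$gene_id), gene_ids)
  if (length(unknown)) {
    stop("records reference genes absent from the catalogue: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  g <- factor(tab$gene_id, levels = gene_ids)
  l <- factor(tab$line_id, levels = line_ids)
  impact_counts <- lapply(IMPACT_LEVELS, function(cl) {
    sel <- tab$impact == cl
    unclass(table(g[sel], l[sel]))
  })
  names(impact_counts) <- IMPACT_LEVELS
  count <- Reduce(`+`, impact_counts)
  dimnames(count) <- list(gene_ids, line_ids)
  impact_counts <- lapply(impact_counts, function(m) {
    dimnames(m) <- dimnames(count); m
  })
  gb <- structure(list(genes = gene_ids, lines = line_ids, count = count,
                       weighted = NULL, binary = (count > 0) * 1L,
                       impact_counts = impact_counts, weights = NULL),
                  class = "gene_burden")
  gb$weighted <- weighted_burden(gb, weights)
  gb$weights <- weights
  gb
}

#' @export
print.gene_burden <- function(x, ...) {
  cat("Gene burden matrices: ", length(x$genes), " genes x ", length(x$lines),
      " lines\n  total mutations: ", sum(x$count),
      "; mean gene-level carrier frequency: ",
      signif(mean(gene_mutation_frequency(x)), 3), "\n", sep = "")
  invisible(x)
}

#' Impact-weighted burden matrix
#'
#' `weighted[g, l]` is the sum over line l's mutations in gene g of the
#' weight of their impact class (no per-gene cap).
#'
#' @param burden A `gene_burden` object.
#' @param weights Named non-negative weights for all four impact classes.
#' @return Numeric matrix genes x lines.
#' @export
weighted_burden <- function(burden, weights = default_impact_weights()) {
  stopifnot(inherits(burden, "gene_burden"))
  weights <- weights[IMPACT_LEVELS]
  if (anyNA(weights)) {
    stop("weights must be defined for all four impact classes", call. = FALSE)
  }
  if (any(weights < 0)) stop("impact weights must be non-negative", call. = FALSE)
  w <- Reduce(`+`, Map(function(m, wt) m * wt, burden$impact_counts,
                       as.list(weights)))
  dimnames(w) <- dimnames(burden$count)
  w
}

#' Gene-level mutation frequency
#'
#' Fraction of lines carrying at least one mutation in each gene — the
#' quantity that makes gene-level association feasible where site-level
#' MAF is not.
#'
#' @param burden A `gene_burden` object.
#' @return Named numeric vector, one proportion per gene.
#' @export
gene_mutation_frequency <- function(burden) {
  stopifnot(inherits(burden, "gene_burden"))
  rowMeans(burden$binary)
}

#' Write burden matrices as TSV
#'
#' Genes as rows, lines as columns; a header comment records the impact
#' weights used.
#'
#' @param burden A `gene_burden` object.
#' @param path Output file.
#' @param which One of `"count"`, `"weighted"`, `"binary"`.
#' @return `path`, invisibly.
#' @export
write_burden_tsv <- function(burden, path, which = c("count", "weighted", "binary")) {
  which <- match.arg(which)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# impact weights: ",
                    paste(names(burden$weights), burden$weights,
                          sep = "=", collapse = ", ")), con)
  m <- burden[[which]]
  utils::write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
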