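#' Write a mutation table as a multi-sample VCF 4.2
#'
#' One sample column per line (GT 0/1 for carriers, 0/0 otherwise), site-level
#' QUAL, INFO/DP, and a SnpEff-style `ANN=alt|.|IMPACT|gene` annotation.
#'
#' @param table Mutation table (see [simulate_genotypes()] /
#'   [read_annotated_vcf()] for the column contract).
#' @param path Output file path.
#' @param line_ids Sample columns to write; defaults to the table's attached
#'   line ids or, failing that, the lines observed in the table.
#' @return `path`, invisibly.
#' @export
write_mutation_vcf <- function(table, path, line_ids = NULL) {
  assert_mutation_table(table)
  if (is.null(line_ids)) line_ids <- attr(table, "line_ids")
  if (is.null(line_ids)) line_ids <- sort(unique(table$line_id))
  table <- order_mutation_table(table)

  key <- site_key(table)
  first <- !duplicated(key)
  sites <- table[first, , drop = FALSE]
  gt <- matrix("0/0", nrow = nrow(sites), ncol = length(line_ids),
               dimnames = list(NULL, line_ids))
  gt[cbind(match(key, key[first]), match(table$line_id, line_ids))] <- "0/1"

  gene <- ifelse(is.na(sites$gene_id), "", sites$gene_id)
  info <- sprintf("DP=%d;ANN=%s|.|%s|%s", sites$depth, sites$alt,
                  sites$impact, gene)
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                format(sites$qual, trim = TRUE, scientific = FALSE),
                "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste0("##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional ",
           "annotations: 'Allele|Annotation|Impact|Gene'\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", line_ids), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

impact_rank <- function(impact) match(impact, IMPACT_LEVELS)

# Parse a SnpEff ANN INFO value, keeping the most severe annotation
# (HIGH > MODERATE > LOW > MODIFIER); returns c(impact, gene).
parse_ann <- function(ann) {
  if (is.na(ann) || !nzchar(ann)) return(c(NA_character_, NA_character_))
  parts <- strsplit(strsplit(ann, ",", fixed = TRUE)[[1]], "|", fixed = TRUE)
  imp <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                character(1))
  gene <- vapply(parts, function(p) if (length(p) >= 4) p[4] else NA_character_,
                 character(1))
  ok <- imp %in% IMPACT_LEVELS
  if (!any(ok)) return(c(NA_character_, NA_character_))
  best <- which(ok)[which.min(impact_rank(imp[ok]))]
  g <- gene[best]
  if (is.na(g) || !nzchar(g) || g == ".") g <- NA_character_
  c(imp[best], g)
}

#' Read a SnpEff-annotated multi-sample VCF into a mutation table
#'
#' Emits one record per (line, variant) with a non-reference genotype. Gene
#' and impact are taken from the INFO/ANN field, keeping the most severe
#' annotation per variant; an external site-to-gene map can supplement or
#' replace missing gene assignments.
#'
#' @param path VCF file (uncompressed or bgzipped; parsed with \pkg{vcfR}).
#' @param site_gene_map Optional `data.frame` with columns `chrom`, `pos`,
#'   `gene_id` used where ANN carries no gene.
#' @return Mutation table `data.frame` (site-major order) with the sample
#'   names attached as attribute `"line_ids"`.
#' @export
read_annotated_vcf <- function(path, site_gene_map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_var <- nrow(fix)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  line_ids <- colnames(gt)

  info <- fix[, "INFO"]
  dp <- suppressWarnings(as.integer(sub(".*DP=([0-9]+).*", "\\1",
                                        paste0(";", info, ";"))))
  dp[!grepl("DP=", info)] <- NA_integer_
  ann <- rep(NA_character_, n_var)
  has_ann <- grepl("ANN=", info)
  ann[has_ann] <- sub(".*ANN=([^;]*).*", "\\1", info[has_ann])
  parsed <- vapply(ann, parse_ann, character(2), USE.NAMES = FALSE)
  impact <- parsed[1, ]
  gene <- parsed[2, ]

  if (!is.null(site_gene_map)) {
    stopifnot(all(c("chrom", "pos", "gene_id") %in% names(site_gene_map)))
    mkey <- paste(site_gene_map$chrom, site_gene_map$pos, sep = ":")
    vkey <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
    hit <- match(vkey, mkey)
    fill <- is.na(gene) & !is.na(hit)
    gene[fill] <- site_gene_map$gene_id[hit[fill]]
  }
  if (all(is.na(gene)) && is.null(site_gene_map) && n_var > 0) {
    stop("VCF carries no ANN gene annotations and no site_gene_map was supplied",
         call. = FALSE)
  }

  nonref <- !is.na(gt) & gt != "0/0" & gt != "0|0" & gt != "./."
  idx <- which(nonref, arr.ind = TRUE)
  tab <- data.frame(
    line_id = line_ids[idx[, 2]],
    chrom = fix[idx[, 1], "CHROM"],
    pos = as.integer(fix[idx[, 1], "POS"]),
    ref = fix[idx[, 1], "REF"],
    # multi-allelic records keep the first ALT only
    alt = sub(",.*", "", fix[idx[, 1], "ALT"]),
    gene_id = gene[idx[, 1]],
    impact = impact[idx[, 1]],
    qual = suppressWarnings(as.numeric(fix[idx[, 1], "QUAL"])),
    depth = dp[idx[, 1]],
    stringsAsFactors = FALSE
  )
  tab <- order_mutation_table(tab)
  attr(tab, "line_ids") <- line_ids
  tab
}

#' Load a gene catalogue from GFF3 or a TSV table
#'
#' GFF3 files are parsed with \pkg{rtracklayer} (gene features, 1-based
#' inclusive coordinates); TSV files must already carry the catalogue
#' columns `gene_id`, `chrom`, `start`, `end` (and optionally `n_sites`,
#' defaulting to the full span).
#'
#' @param path A `.gff3`/`.gff` or `.tsv` file.
#' @return `data.frame` with columns `gene_id`, `n_sites`, `chrom`, `start`,
#'   `end`.
#' @export
read_gene_catalogue <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
    }
    gr <- as.data.frame(rtracklayer::import(path))
    gr <- gr[gr$type == "gene", , drop = FALSE]
    id <- if (!is.null(gr$ID)) gr$ID else gr$Name
    cat_df <- data.frame(gene_id = as.character(id),
                         n_sites = gr$width,
                         chrom = as.character(gr$seqnames),
                         start = gr$start,
                         end = gr$end,
                         stringsAsFactors = FALSE)
  } else {
    cat_df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(cat_df)))
    if (is.null(cat_df$n_sites)) cat_df$n_sites <- cat_df$end - cat_df$start + 1L
    cat_df <- cat_df[, c("gene_id", "n_sites", "chrom", "start", "end")]
  }
  if (anyDuplicated(cat_df$gene_id)) stop("duplicate gene ids in catalogue", call. = FALSE)
  cat_df
}
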