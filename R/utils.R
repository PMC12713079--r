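# Internal helpers shared across modules.

IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}

# Canonical record order for mutation tables: site-major, then line,
# so that VCF round-trips compare equal.
order_mutation_table <- function(tab) {
  tab <- tab[order(tab$chrom, tab$pos, tab$alt, tab$line_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

assert_mutation_table <- function(tab) {
  needed <- c("line_id", "chrom", "pos", "ref", "alt", "gene_id", "impact",
              "qual", "depth")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("mutation table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(tab)
}

empty_mutation_table <- function() {
  data.frame(line_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gene_id = character(),
             impact = character(), qual = numeric(), depth = integer(),
             stringsAsFactors = FALSE)
}

site_key <- function(tab) paste(tab$chrom, tab$pos, tab$alt, sep = ":")
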