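# Dual-pathway gene-level association:
#  - reverse pathway: are gene carriers enriched among phenotypically
#    deviant lines? (chi-square, literal single-cell form or 2x2 contingency)
#  - forward pathway: does per-line gene burden predict the phenotype?
#    (OLS burden regression)
# Both pathways get family-wise permutation thresholds; candidates are the
# top-K intersection filtered by both thresholds.

#' Split a population into phenotypically deviant and non-deviant lines
#'
#' Lines whose trait value lies at least `z_threshold` reference standard
#' deviations from the reference centre are labelled deviant. The centre is
#' the population mean (non-wild-type lines) or the wild-type mean; the SD
#' is always the population SD.
#'
#' @param phenotypes `data.frame` with `line_id`, logical `is_wt` and trait
#'   columns.
#' @param trait Trait column name.
#' @param center_mode `"population"` or `"wild_type"`.
#' @param z_threshold Deviation cutoff in SD units (>= `z_threshold` is
#'   deviant, so 0 marks every line deviant).
#' @return Object of class `deviant_split`: `trait`, `center`, `sd`,
#'   `z_threshold`, `deviant`, `non_deviant`, `lines` (all non-reference
#'   line ids).
#' @export
deviant_lines <- function(phenotypes, trait,
                          center_mode = c("population", "wild_type"),
                          z_threshold = 1.5) {
  center_mode <- match.arg(center_mode)
  stopifnot(trait %in% names(phenotypes))
  is_wt <- if ("is_wt" %in% names(phenotypes)) phenotypes$is_wt else
    rep(FALSE, nrow(phenotypes))
  pop <- phenotypes[!is_wt & !is.na(phenotypes[[trait]]), , drop = FALSE]
  v <- pop[[trait]]
  if (!is.numeric(v)) stop("trait column must be numeric", call. = FALSE)
  center <- if (center_mode == "wild_type") {
    wt <- phenotypes[[trait]][is_wt]
    if (!length(wt)) stop("center_mode = 'wild_type' but no wild-type rows",
                          call. = FALSE)
    mean(wt, na.rm = TRUE)
  } else mean(v)
  s <- stats::sd(v)
  if (is.na(s) || s == 0) {
    if (z_threshold > 0) {
      warning("constant trait: deviant set is empty")
      dev <- logical(length(v))
    } else dev <- rep(TRUE, length(v))
  } else {
    dev <- abs(v - center) / s >= z_threshold
  }
  structure(list(trait = trait, center = center, sd = s,
                 z_threshold = z_threshold, center_mode = center_mode,
                 deviant = pop$line_id[dev], non_deviant = pop$line_id[!dev],
                 lines = pop$line_id),
            class = "deviant_split")
}

# Vectorised chi-square given, per gene, carriers m and carriers-among-
# deviant a, with D deviant lines of N total.
chi2_from_counts <- function(m, a, D, N, mode) {
  if (mode == "literal") {
    expd <- m * D / N
    stat <- (a - expd)^2 / expd
    stat[expd == 0] <- NA_real_
    list(stat = stat, obs = a, exp = expd)
  } else {
    b <- m - a
    cc <- D - a
    d <- N - m - D + a
    denom <- m * (N - m) * D * (N - D)
    stat <- N * (a * d - b * cc)^2 / denom
    stat[denom == 0] <- NA_real_
    list(stat = stat, obs = a, exp = m * D / N)
  }
}

#' Chi-square enrichment of gene carriers among deviant lines
#'
#' For each gene, `Obs` is the number of carrier lines among the deviant
#' set and `Exp` the carrier count expected under independence
#' (`carriers * deviant / N`). `mode = "literal"` evaluates the single-cell
#' statistic `(Obs - Exp)^2 / Exp`; `mode = "contingency"` (default) the
#' standard 1-df 2x2 Pearson chi-square on carrier x deviant, which has a
#' calibrated null. Genes with `Exp = 0` (or a degenerate margin) are
#' flagged as skipped.
#'
#' @param burden A `gene_burden` object.
#' @param split A [deviant_lines()] result.
#' @param mode `"contingency"` or `"literal"`.
#' @return `data.frame` per gene: `gene_id`, `n_carriers`, `obs`, `exp`,
#'   `chi2`, `p`, `skipped`.
#' @export
enrichment_chi2 <- function(burden, split, mode = c("contingency", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(burden, "gene_burden"), inherits(split, "deviant_split"))
  lines <- intersect(split$lines, burden$lines)
  if (!length(lines)) stop("no overlap between split lines and burden lines",
                           call. = FALSE)
  B <- burden$binary[, lines, drop = FALSE]
  d <- as.numeric(lines %in% split$deviant)
  m <- rowSums(B)
  a <- as.numeric(B %*% d)
  res <- chi2_from_counts(m, a, sum(d), length(lines), mode)
  out <- data.frame(gene_id = burden$genes, n_carriers = m, obs = res$obs,
                    exp = res$exp, chi2 = res$stat,
                    p = stats::pchisq(res$stat, df = 1, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  out$skipped <- is.na(out$chi2)
  rownames(out) <- NULL
  out
}

# Align a burden predictor matrix with a phenotype table. Wild-type lines
# absent from the matrix get zero burden columns (reference background).
align_burden_phenotype <- function(burden, phenotypes, trait,
                                   predictor = "weighted",
                                   include_wt = TRUE) {
  stopifnot(trait %in% names(phenotypes))
  X <- switch(predictor, weighted = burden$weighted, count = burden$count,
              binary = burden$binary,
              stop("unknown predictor: ", predictor, call. = FALSE))
  is_wt <- if ("is_wt" %in% names(phenotypes)) phenotypes$is_wt else
    rep(FALSE, nrow(phenotypes))
  ph <- phenotypes[!is.na(phenotypes[[trait]]), , drop = FALSE]
  is_wt <- is_wt[!is.na(phenotypes[[trait]])]
  in_mat <- ph$line_id %in% burden$lines
  keep <- in_mat | (include_wt & is_wt)
  ph <- ph[keep, , drop = FALSE]
  in_mat <- in_mat[keep]
  Xa <- matrix(0, nrow = nrow(X), ncol = nrow(ph),
               dimnames = list(rownames(X), ph$line_id))
  Xa[, in_mat] <- X[, ph$line_id[in_mat], drop = FALSE]
  list(X = Xa, y = ph[[trait]], lines = ph$line_id)
}

#' Per-gene burden regression (forward pathway)
#'
#' Ordinary least squares of the trait on the per-line gene predictor
#' (impact-weighted burden by default; raw count or 0/1 presence
#' optionally), with intercept, and a two-sided t-test on the slope.
#' Wild-type lines enter with zero burden. Genes whose predictor has zero
#' variance are skipped with a flag.
#'
#' @param burden A `gene_burden` object.
#' @param phenotypes Phenotype table (`line_id`, `is_wt`, trait columns).
#' @param trait Trait column name.
#' @param predictor `"weighted"`, `"count"` or `"binary"`.
#' @param include_wt Include wild-type reference rows at zero burden.
#' @return `data.frame` per gene: `gene_id`, `n_carriers`, `slope`, `se`,
#'   `t`, `p`, `skipped`.
#' @export
burden_regression <- function(burden, phenotypes, trait,
                              predictor = c("weighted", "count", "binary"),
                              include_wt = TRUE) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(burden, "gene_burden"))
  al <- align_burden_phenotype(burden, phenotypes, trait, predictor, include_wt)
  n <- length(al$y)
  if (n < 3) stop("need at least 3 lines with phenotype", call. = FALSE)
  X <- al$X
  y <- al$y
  xbar <- rowMeans(X)
  Sxx <- rowSums(X^2) - n * xbar^2
  Sxy <- as.numeric(X %*% y) - n * xbar * mean(y)
  Syy <- sum(y^2) - n * mean(y)^2
  slope <- Sxy / Sxx
  sigma2 <- pmax(Syy - slope * Sxy, 0) / (n - 2)
  se <- sqrt(sigma2 / Sxx)
  t <- slope / se
  p <- 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
  skip <- Sxx <= 0 | !is.finite(slope)
  out <- data.frame(gene_id = burden$genes,
                    n_carriers = rowSums(burden$binary[, intersect(al$lines, burden$lines), drop = FALSE]),
                    slope = slope, se = se, t = t, p = p,
                    skipped = skip, stringsAsFactors = FALSE)
  out$slope[skip] <- NA_real_; out$se[skip] <- NA_real_
  out$t[skip] <- NA_real_; out$p[skip] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Family-wise permutation significance threshold for a pathway
#'
#' Permutes trait values across lines `n_perm` times; per permutation the
#' most extreme per-gene statistic is recorded (chi-square value for the
#' enrichment pathway, |t| for the regression pathway), and the threshold
#' is the k-th largest of these maxima with `k = ceiling(alpha * n_perm)`,
#' so that exceeding it (strictly) has family-wise probability ~alpha under
#' the null. `statistic = "pointwise"` instead returns per-gene thresholds
#' from each gene's own permutation distribution.
#'
#' @param burden A `gene_burden` object.
#' @param phenotypes,trait Phenotype table and trait column.
#' @param pathway `"regression"` or `"chi2"`.
#' @param n_perm Number of permutations.
#' @param alpha Family-wise level.
#' @param seed Integer seed (deterministic thresholds under a fixed seed).
#' @param statistic `"max"` (family-wise) or `"pointwise"` (per gene).
#' @param predictor Regression predictor (forward pathway).
#' @param mode Chi-square mode (reverse pathway).
#' @param z_threshold,center_mode Deviant-split parameters (reverse pathway).
#' @param include_wt Include wild-type rows in the regression.
#' @return Object of class `perm_threshold`: `threshold` (scalar for
#'   `"max"`, per-gene vector for `"pointwise"`), `maxima`, `pathway`,
#'   `alpha`, `n_perm`, `seed`.
#' @export
permutation_threshold <- function(burden, phenotypes, trait,
                                  pathway = c("regression", "chi2"),
                                  n_perm = 1000, alpha = 0.05, seed = 1L,
                                  statistic = c("max", "pointwise"),
                                  predictor = "weighted",
                                  mode = "contingency",
                                  z_threshold = 1.5,
                                  center_mode = "population",
                                  include_wt = TRUE) {
  pathway <- match.arg(pathway)
  statistic <- match.arg(statistic)
  if (n_perm < 1 / alpha) {
    warning("n_perm < 1/alpha: the threshold quantile is poorly resolved")
  }
  k <- max(1L, ceiling(alpha * n_perm))

  if (pathway == "chi2") {
    split <- deviant_lines(phenotypes, trait, center_mode, z_threshold)
    lines <- intersect(split$lines, burden$lines)
    B <- burden$binary[, lines, drop = FALSE]
    d <- as.numeric(lines %in% split$deviant)
    m <- rowSums(B)
    N <- length(lines); D <- sum(d)
    stats_mat <- with_seed(seed, {
      # permuting trait values across lines permutes deviant membership
      Dmat <- vapply(seq_len(n_perm), function(i) sample(d), numeric(length(d)))
      A <- B %*% Dmat
      chi2_from_counts(m, A, D, N, mode)$stat
    })
  } else {
    al <- align_burden_phenotype(burden, phenotypes, trait, predictor, include_wt)
    n <- length(al$y)
    Xc <- al$X - rowMeans(al$X)
    sx <- sqrt(rowSums(Xc^2))
    ok <- sx > 0
    stats_mat <- with_seed(seed, {
      Ymat <- vapply(seq_len(n_perm), function(i) sample(al$y), numeric(n))
      Yc <- sweep(Ymat, 2, colMeans(Ymat))
      sy <- sqrt(colSums(Yc^2))
      r <- (Xc[ok, , drop = FALSE] %*% Yc) / outer(sx[ok], sy)
      r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
      abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
    })
  }
  maxima <- apply(stats_mat, 2, max, na.rm = TRUE)
  threshold <- if (statistic == "max") {
    sort(maxima, decreasing = TRUE)[k]
  } else {
    thr <- apply(stats_mat, 1, function(s) {
      s <- s[!is.na(s)]
      if (!length(s)) return(NA_real_)
      sort(s, decreasing = TRUE)[min(k, length(s))]
    })
    if (pathway == "regression") {
      full <- rep(NA_real_, length(burden$genes))
      full[ok] <- thr
      names(full) <- burden$genes
      full
    } else { names(thr) <- burden$genes; thr }
  }
  structure(list(threshold = threshold, maxima = maxima, pathway = pathway,
                 statistic = statistic, alpha = alpha, n_perm = n_perm,
                 seed = seed),
            class = "perm_threshold")
}

#' Run the full dual-pathway gene-level association
#'
#' Computes both pathways, their permutation thresholds, per-pathway ranks,
#' top-K membership and the candidate set (top-K intersection filtered by
#' both thresholds).
#'
#' @inheritParams permutation_threshold
#' @param K Top-K size per pathway.
#' @return Object of class `assoc_result`: per-gene `data.frame` `table`
#'   plus `split`, `thresholds`, `pool` (top-K intersection, the candidate
#'   gene pool) and `candidates` (pool members beyond both thresholds).
#' @export
run_gla <- function(burden, phenotypes, trait, K = 300, n_perm = 1000,
                    alpha = 0.05, z_threshold = 1.5,
                    center_mode = "population", predictor = "weighted",
                    mode = "contingency", statistic = "max",
                    include_wt = TRUE, seed = 1L) {
  split <- deviant_lines(phenotypes, trait, center_mode, z_threshold)
  chi <- enrichment_chi2(burden, split, mode)
  reg <- burden_regression(burden, phenotypes, trait, predictor, include_wt)
  thr_chi <- permutation_threshold(burden, phenotypes, trait, "chi2",
                                   n_perm = n_perm, alpha = alpha,
                                   seed = seed, statistic = statistic,
                                   mode = mode, z_threshold = z_threshold,
                                   center_mode = center_mode)
  thr_reg <- permutation_threshold(burden, phenotypes, trait, "regression",
                                   n_perm = n_perm, alpha = alpha,
                                   seed = seed + 1L, statistic = statistic,
                                   predictor = predictor,
                                   include_wt = include_wt)
  tab <- data.frame(gene_id = chi$gene_id, trait = trait,
                    n_carriers = chi$n_carriers,
                    chi2 = chi$chi2, p_chi2 = chi$p,
                    slope = reg$slope, se = reg$se, t = reg$t, p_reg = reg$p,
                    stringsAsFactors = FALSE)
  tab$rank_chi2 <- rank_by_p(tab$p_chi2, tab$gene_id)
  tab$rank_reg <- rank_by_p(tab$p_reg, tab$gene_id)
  res <- structure(list(table = tab, split = split,
                        thresholds = list(chi2 = thr_chi, regression = thr_reg),
                        K = K),
                   class = "assoc_result")
  cand <- intersect_candidates(res, K)
  res$pool <- cand$pool
  res$candidates <- cand$candidates
  res$table$in_top_chi2 <- res$table$rank_chi2 <= min(K, sum(!is.na(tab$p_chi2)))
  res$table$in_top_reg <- res$table$rank_reg <= min(K, sum(!is.na(tab$p_reg)))
  res$table$candidate <- res$table$gene_id %in% cand$candidates
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("Gene-level association (", x$table$trait[1], "): ",
      nrow(x$table), " genes\n", "  candidate pool (top-", x$K,
      " intersection): ", length(x$pool), "\n",
      "  candidates beyond both permutation thresholds: ",
      length(x$candidates), "\n", sep = "")
  invisible(x)
}

# p ascending, ties broken lexicographically by gene id; NAs rank last.
rank_by_p <- function(p, gene_id) {
  ord <- order(p, gene_id, na.last = TRUE)
  r <- integer(length(p))
  r[ord] <- seq_along(p)
  r
}

#' Intersect the top-K gene lists of the two pathways
#'
#' Genes are ranked per pathway by p-value (ties broken lexicographically by
#' gene id). The candidate pool is the intersection of the two top-K sets;
#' the candidate list keeps pool members whose statistics exceed both
#' permutation thresholds.
#'
#' @param results An `assoc_result` (or a list with `table` and
#'   `thresholds` in the same shape).
#' @param K Top-K size; clipped with a warning if it exceeds the number of
#'   tested genes.
#' @return List with `pool` and `candidates` (character vectors sorted by
#'   combined rank).
#' @export
intersect_candidates <- function(results, K = 300) {
  tab <- results$table
  n_chi <- sum(!is.na(tab$p_chi2))
  n_reg <- sum(!is.na(tab$p_reg))
  if (K > min(n_chi, n_reg)) {
    warning("K exceeds the number of tested genes; clipped")
  }
  top_chi <- tab$gene_id[tab$rank_chi2 <= min(K, n_chi) & !is.na(tab$p_chi2)]
  top_reg <- tab$gene_id[tab$rank_reg <= min(K, n_reg) & !is.na(tab$p_reg)]
  pool <- intersect(top_chi, top_reg)
  sel <- tab$gene_id %in% pool
  pool <- tab$gene_id[sel][order(tab$rank_chi2[sel] + tab$rank_reg[sel],
                                 tab$gene_id[sel])]
  thr_c <- results$thresholds$chi2$threshold
  thr_r <- results$thresholds$regression$threshold
  if (!is.null(names(thr_c))) thr_c <- thr_c[pool]
  if (!is.null(names(thr_r))) thr_r <- thr_r[pool]
  i <- match(pool, tab$gene_id)
  beyond <- !is.na(tab$chi2[i]) & tab$chi2[i] > thr_c &
    !is.na(tab$t[i]) & abs(tab$t[i]) > thr_r
  list(pool = pool, candidates = pool[beyond])
}

#' Prioritise candidate genes by tissue expression
#'
#' Keeps candidates whose maximum FPKM over the tissues of interest reaches
#' `min_fpkm`, ranked by that maximum descending. Candidates absent from the
#' expression matrix are retained at the bottom and flagged.
#'
#' @param candidates Character vector of gene ids.
#' @param expression Matrix or `data.frame` of FPKM, genes in rows (rownames
#'   or a `gene_id` column), tissues in columns.
#' @param tissues Tissue column names of interest.
#' @param min_fpkm Minimum max-FPKM to keep a candidate.
#' @return `data.frame`: `gene_id`, `max_fpkm`, `missing`, ranked.
#' @export
prioritize_by_expression <- function(candidates, expression, tissues,
                                     min_fpkm = 1) {
  if (!length(candidates)) {
    return(data.frame(gene_id = character(), max_fpkm = numeric(),
                      missing = logical()))
  }
  if (is.data.frame(expression) && "gene_id" %in% names(expression)) {
    rownames(expression) <- expression$gene_id
    expression$gene_id <- NULL
  }
  unknown <- setdiff(tissues, colnames(expression))
  if (length(unknown)) {
    stop("unknown tissue(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ex <- as.matrix(expression[, tissues, drop = FALSE])
  hit <- match(candidates, rownames(ex))
  max_fpkm <- rep(NA_real_, length(candidates))
  max_fpkm[!is.na(hit)] <- apply(ex[hit[!is.na(hit)], , drop = FALSE], 1, max)
  out <- data.frame(gene_id = candidates, max_fpkm = max_fpkm,
                    missing = is.na(hit), stringsAsFactors = FALSE)
  out <- out[out$missing | out$max_fpkm >= min_fpkm, , drop = FALSE]
  out <- out[order(out$missing, -ifelse(is.na(out$max_fpkm), -Inf, out$max_fpkm),
                   out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
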