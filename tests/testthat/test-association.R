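test_that("deviant split follows the z-threshold rule", {
  ph <- pheno_frame(sprintf("L%d", 1:4), c(0, 0, 0, 10))
  sp <- deviant_lines(ph, "trait", z_threshold = 1)
  expect_identical(sp$deviant, "L4")
  expect_setequal(sp$non_deviant, c("L1", "L2", "L3"))
  expect_setequal(c(sp$deviant, sp$non_deviant), sp$lines)

  # z = 0 marks everyone deviant; constant trait marks no one
  expect_setequal(deviant_lines(ph, "trait", z_threshold = 0)$deviant,
                  sprintf("L%d", 1:4))
  flat <- pheno_frame(sprintf("L%d", 1:4), rep(2, 4))
  expect_warning(sp0 <- deviant_lines(flat, "trait"), "constant")
  expect_length(sp0$deviant, 0)
})

test_that("wild-type rows set the centre but never enter the split", {
  ph <- rbind(pheno_frame(sprintf("L%d", 1:4), c(5, 6, 7, 20)),
              pheno_frame("WT1", 6, is_wt = TRUE))
  sp <- deviant_lines(ph, "trait", center_mode = "wild_type", z_threshold = 1)
  expect_equal(sp$center, 6)
  expect_false("WT1" %in% sp$lines)
})

test_that("literal chi-square evaluates (Obs-Exp)^2/Exp as printed", {
  # 20 lines, 10 deviant; gene carried by 10 lines, all deviant:
  # Obs = 10, Exp = 10 * 10/20 = 5 -> (10-5)^2/5 = 5
  lines <- sprintf("L%02d", 1:20)
  tab <- make_table(lines[1:10], pos = 1:10)
  gb <- aggregate_by_gene(tab, "G001", line_ids = lines)
  sp <- manual_split(lines, lines[1:10])
  res <- enrichment_chi2(gb, sp, mode = "literal")
  expect_equal(res$obs, 10)
  expect_equal(res$exp, 5)
  expect_equal(res$chi2, 5.0)

  # Obs = Exp gives statistic 0
  tab2 <- make_table(lines[c(1:5, 11:15)], pos = 1:10)
  gb2 <- aggregate_by_gene(tab2, "G001", line_ids = lines)
  expect_equal(enrichment_chi2(gb2, sp, mode = "literal")$chi2, 0)
})

test_that("contingency chi-square matches the textbook 2x2 oracle", {
  set.seed(401)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    lines <- sprintf("L%03d", seq_len(n))
    carrier <- runif(n) < runif(1, 0.2, 0.8)
    deviant <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(carrier) || all(carrier) || !any(deviant) || all(deviant)) next
    tab <- make_table(lines[carrier], pos = seq_len(sum(carrier)))
    gb <- aggregate_by_gene(tab, "G001", line_ids = lines)
    sp <- manual_split(lines, lines[deviant])
    res <- enrichment_chi2(gb, sp, mode = "contingency")
    a <- sum(carrier & deviant); b <- sum(carrier & !deviant)
    cc <- sum(!carrier & deviant); d <- sum(!carrier & !deviant)
    expect_equal(res$chi2, oracle_chi2_2x2(a, b, cc, d), tolerance = 1e-10)
    expect_equal(res$p, pchisq(oracle_chi2_2x2(a, b, cc, d), 1,
                               lower.tail = FALSE), tolerance = 1e-10)
  }
})

test_that("burden regression reproduces perfect fits and skips constants", {
  lines <- sprintf("L%02d", 1:10)
  tab <- make_table(rep(lines, times = 1:10 %% 3 + 1),
                    pos = seq_len(sum(1:10 %% 3 + 1)))
  gb <- aggregate_by_gene(tab, c("G001", "G002"), line_ids = lines)
  x <- gb$count["G001", ]
  ph <- pheno_frame(lines, as.numeric(2 * x))
  res <- burden_regression(gb, ph, "trait", predictor = "count",
                           include_wt = FALSE)
  expect_equal(res$slope[res$gene_id == "G001"], 2)
  expect_equal(res$p[res$gene_id == "G001"], 0)
  # G002 has no mutations anywhere: zero-variance predictor is skipped
  expect_true(res$skipped[res$gene_id == "G002"])
})

test_that("burden regression matches the closed-form OLS oracle", {
  set.seed(402)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    lines <- sprintf("L%03d", seq_len(n))
    counts <- rpois(n, 1.2)
    if (var(counts) == 0) next
    tab <- make_table(rep(lines, counts), pos = seq_len(sum(counts)))
    gb <- aggregate_by_gene(tab, "G001", line_ids = lines)
    y <- rnorm(n)
    res <- burden_regression(gb, pheno_frame(lines, y), "trait",
                             predictor = "count", include_wt = FALSE)
    o <- oracle_ols(counts, y)
    expect_equal(res$slope, unname(o$slope), tolerance = 1e-10)
    expect_equal(res$se, unname(o$se), tolerance = 1e-10)
    expect_equal(res$t, unname(o$t), tolerance = 1e-10)
    expect_equal(res$p, unname(o$p), tolerance = 1e-10)
  }
})

test_that("both pathways are invariant to line order and trait affine rescale", {
  cfg <- sim_config(n_lines = 60, genes = tiny_catalogue(12, 10),
                    mean_mutations_per_line = 15,
                    causal_effects = c(G002 = 1.5), seed = 23)
  mt <- simulate_genotypes(cfg)
  gb <- aggregate_by_gene(mt, tiny_catalogue(12, 10))
  ph <- simulate_phenotypes(mt, cfg, n_wt = 0)
  sp <- deviant_lines(ph, "trait")
  base_chi <- enrichment_chi2(gb, sp)
  base_reg <- burden_regression(gb, ph, "trait")

  perm <- ph[sample(nrow(ph)), ]
  expect_equal(enrichment_chi2(gb, deviant_lines(perm, "trait"))$chi2,
               base_chi$chi2)
  expect_equal(burden_regression(gb, perm, "trait")$t, base_reg$t)

  scaled <- ph; scaled$trait <- -3 * scaled$trait + 7
  expect_equal(enrichment_chi2(gb, deviant_lines(scaled, "trait"))$chi2,
               base_chi$chi2, tolerance = 1e-12)
  sreg <- burden_regression(gb, scaled, "trait")
  expect_equal(abs(sreg$t), abs(base_reg$t), tolerance = 1e-9)
  expect_equal(sreg$p, base_reg$p, tolerance = 1e-9)
})

test_that("permutation thresholds are deterministic and never exceeded by a constant trait", {
  cfg <- sim_config(n_lines = 50, genes = tiny_catalogue(10, 10),
                    mean_mutations_per_line = 12, seed = 33)
  mt <- simulate_genotypes(cfg)
  gb <- aggregate_by_gene(mt, tiny_catalogue(10, 10))
  ph <- simulate_phenotypes(mt, cfg, n_wt = 0)
  t1 <- permutation_threshold(gb, ph, "trait", "regression", n_perm = 50,
                              seed = 5)
  t2 <- permutation_threshold(gb, ph, "trait", "regression", n_perm = 50,
                              seed = 5)
  expect_identical(t1, t2)
  expect_warning(permutation_threshold(gb, ph, "trait", "regression",
                                       n_perm = 10, alpha = 0.05, seed = 1),
                 "poorly resolved")

  flat <- ph; flat$trait <- 1
  suppressWarnings({
    sp <- deviant_lines(flat, "trait")
    res <- enrichment_chi2(gb, sp)
  })
  expect_true(all(is.na(res$chi2) | res$chi2 == 0))
})

test_that("candidate intersection equals a brute-force set oracle", {
  set.seed(403)
  genes <- sprintf("G%03d", 1:40)
  tab <- data.frame(gene_id = genes, trait = "t",
                    n_carriers = 5, chi2 = rchisq(40, 1),
                    p_chi2 = runif(40), slope = 1, se = 1,
                    t = rnorm(40), p_reg = runif(40),
                    stringsAsFactors = FALSE)
  tab$rank_chi2 <- emsburden:::rank_by_p(tab$p_chi2, tab$gene_id)
  tab$rank_reg <- emsburden:::rank_by_p(tab$p_reg, tab$gene_id)
  fake <- list(table = tab,
               thresholds = list(chi2 = list(threshold = 0.5),
                                 regression = list(threshold = 0.5)))
  got <- intersect_candidates(fake, K = 10)
  top_chi <- tab$gene_id[order(tab$p_chi2, tab$gene_id)][1:10]
  top_reg <- tab$gene_id[order(tab$p_reg, tab$gene_id)][1:10]
  expect_setequal(got$pool, intersect(top_chi, top_reg))
  manual <- intersect(top_chi, top_reg)
  manual <- manual[tab$chi2[match(manual, tab$gene_id)] > 0.5 &
                     abs(tab$t[match(manual, tab$gene_id)]) > 0.5]
  expect_setequal(got$candidates, manual)
  # disjoint top lists give an empty pool
  tab2 <- tab
  tab2$p_chi2 <- seq(0.01, 0.4, length.out = 40)
  tab2$p_reg <- rev(tab2$p_chi2)
  tab2$rank_chi2 <- emsburden:::rank_by_p(tab2$p_chi2, tab2$gene_id)
  tab2$rank_reg <- emsburden:::rank_by_p(tab2$p_reg, tab2$gene_id)
  fake2 <- list(table = tab2, thresholds = fake$thresholds)
  expect_length(intersect_candidates(fake2, K = 10)$pool, 0)
  # identical rankings, everything past thresholds: min(K, n) candidates
  tab3 <- tab; tab3$p_reg <- tab3$p_chi2
  tab3$chi2 <- 10; tab3$t <- 10
  tab3$rank_chi2 <- emsburden:::rank_by_p(tab3$p_chi2, tab3$gene_id)
  tab3$rank_reg <- emsburden:::rank_by_p(tab3$p_reg, tab3$gene_id)
  fake3 <- list(table = tab3, thresholds = fake$thresholds)
  expect_warning(got3 <- intersect_candidates(fake3, K = 100), "clipped")
  expect_length(got3$candidates, 40)
})

test_that("expression prioritisation filters and ranks like a brute-force oracle", {
  set.seed(404)
  ex <- matrix(rexp(60, 0.2), nrow = 12,
               dimnames = list(sprintf("G%03d", 1:12), paste0("tis", 1:5)))
  cand <- c("G002", "G005", "G009", "G999")
  got <- prioritize_by_expression(cand, ex, tissues = c("tis1", "tis3"),
                                  min_fpkm = 1)
  known <- setdiff(cand, "G999")
  mx <- apply(ex[known, c("tis1", "tis3")], 1, max)
  keep <- names(sort(mx[mx >= 1], decreasing = TRUE))
  expect_equal(got$gene_id[!got$missing], keep)
  expect_true("G999" %in% got$gene_id[got$missing])
  # zero-expression candidate dropped; empty list stays empty
  ex["G002", ] <- 0
  got2 <- prioritize_by_expression("G002", ex, "tis1", min_fpkm = 1)
  expect_equal(nrow(got2), 0)
  expect_equal(nrow(prioritize_by_expression(character(), ex, "tis1")), 0)
  expect_error(prioritize_by_expression("G002", ex, "nope"), "unknown tissue")
})

test_that("run_gla flags planted causal genes as candidates", {
  genes <- tiny_catalogue(60, 10)
  cfg <- sim_config(n_lines = 300, genes = genes,
                    mean_mutations_per_line = 12,
                    causal_effects = c(G007 = 3), noise_sd = 1, seed = 77)
  mt <- simulate_genotypes(cfg)
  gb <- aggregate_by_gene(mt, genes)
  ph <- simulate_phenotypes(mt, cfg)
  res <- run_gla(gb, ph, "trait", K = 10, n_perm = 300, seed = 2)
  expect_true("G007" %in% res$pool)
  expect_true("G007" %in% res$candidates)
  expect_equal(res$table$candidate,
               res$table$gene_id %in% res$candidates)
  # candidate implies both top-K membership and both thresholds exceeded
  ct <- res$table[res$table$candidate, ]
  expect_true(all(ct$in_top_chi2 & ct$in_top_reg))
  expect_true(all(ct$chi2 > res$thresholds$chi2$threshold))
  expect_true(all(abs(ct$t) > res$thresholds$regression$threshold))
})
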