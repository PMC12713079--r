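test_that("a planted pure-interaction pair has the smallest p-value", {
  genes <- tiny_catalogue(12, 10)
  pairs <- data.frame(gene_i = "G003", gene_j = "G008", effect = 4)
  cfg <- sim_config(n_lines = 200, genes = genes,
                    mean_mutations_per_line = 8, epistatic_pairs = pairs,
                    noise_sd = 0, seed = 51)
  mt <- simulate_genotypes(cfg)
  gb <- aggregate_by_gene(mt, genes)
  ph <- simulate_phenotypes(mt, cfg, n_wt = 0)
  ed <- pairwise_epistasis(gb, ph, "trait", min_carriers = 5)
  best <- ed[which.min(ed$p), ]
  expect_equal(best$gene_i, "G003")
  expect_equal(best$gene_j, "G008")
  expect_lt(best$p, min(ed$p[-which.min(ed$p)]))
})

test_that("interaction statistics match the full-design OLS oracle", {
  set.seed(601)
  for (i in 1:100) {
    n <- sample(30:80, 1)
    gi <- rbinom(n, 1, 0.3)
    gj <- rbinom(n, 1, 0.3)
    y <- rnorm(n) + 0.5 * gi * gj
    o <- oracle_interaction_t(gi, gj, y)
    if (is.null(o)) next
    lines <- sprintf("L%03d", seq_len(n))
    tab <- rbind(make_table(lines[gi == 1], pos = seq_len(sum(gi)),
                            gene_id = "GAAA"),
                 make_table(lines[gj == 1], pos = 1000 + seq_len(sum(gj)),
                            gene_id = "GBBB"))
    gb <- aggregate_by_gene(tab, c("GAAA", "GBBB"), line_ids = lines)
    ed <- pairwise_epistasis(gb, pheno_frame(lines, y), "trait",
                             min_carriers = 1)
    expect_equal(ed$t, unname(o$t), tolerance = 1e-8)
    expect_equal(ed$p, unname(o$p), tolerance = 1e-8)
  }
})

test_that("the scan is symmetric in gene labels and respects eligibility", {
  set.seed(602)
  n <- 60
  lines <- sprintf("L%03d", seq_len(n))
  gi <- rbinom(n, 1, 0.4); gj <- rbinom(n, 1, 0.4)
  y <- rnorm(n)
  tab <- rbind(make_table(lines[gi == 1], pos = seq_len(sum(gi)),
                          gene_id = "GAAA"),
               make_table(lines[gj == 1], pos = 1000 + seq_len(sum(gj)),
                          gene_id = "GBBB"))
  gb <- aggregate_by_gene(tab, c("GAAA", "GBBB"), line_ids = lines)
  ed <- pairwise_epistasis(gb, pheno_frame(lines, y), "trait", min_carriers = 1)
  # swap the labels: statistic and p must be unchanged, pair stays i < j
  tab2 <- tab
  tab2$gene_id <- ifelse(tab$gene_id == "GAAA", "GBBB", "GAAA")
  gb2 <- aggregate_by_gene(tab2, c("GAAA", "GBBB"), line_ids = lines)
  ed2 <- pairwise_epistasis(gb2, pheno_frame(lines, y), "trait",
                            min_carriers = 1)
  expect_equal(abs(ed$t), abs(ed2$t), tolerance = 1e-10)
  expect_equal(ed$p, ed2$p, tolerance = 1e-10)
  expect_true(all(ed$gene_i < ed$gene_j))
  # a gene below the carrier floor removes its pairs
  expect_error(pairwise_epistasis(gb, pheno_frame(lines, y), "trait",
                                  min_carriers = n + 1), "at least 2 genes")
})

test_that("top_edges sorts by p with deterministic lexicographic ties", {
  ed <- data.frame(gene_i = c("GA", "GA", "GB", "GA"),
                   gene_j = c("GB", "GC", "GC", "GD"),
                   trait = "t", n_double_carriers = 5,
                   t = 1, p = c(0.5, 0.1, 0.1, 0.9),
                   stringsAsFactors = FALSE)
  got <- top_edges(ed, N = 2)
  expect_equal(got$gene_i, c("GA", "GB"))
  expect_equal(got$gene_j, c("GC", "GC"))
  expect_warning(all10 <- top_edges(ed, N = 1000), "fewer than N")
  expect_equal(nrow(all10), 4)
  # equal p everywhere: lexicographically first pairs win
  ed$p <- 0.5
  expect_equal(top_edges(ed, N = 2)$gene_j, c("GB", "GC"))
  # brute-force sort-and-take oracle on random p
  set.seed(603)
  ed$p <- runif(4)
  expect_equal(top_edges(ed, N = 3)$p, sort(ed$p)[1:3])
})

test_that("network metrics match hand counts on a star and BFS betweenness", {
  star <- data.frame(gene_i = "HUB", gene_j = paste0("LEAF", 1:6),
                     trait = "t", stringsAsFactors = FALSE)
  net <- build_epistasis_network(star)
  m <- network_metrics(net)
  expect_equal(m$nodes$degree[m$nodes$gene_id == "HUB"], 6)
  expect_true(all(m$nodes$degree[m$nodes$gene_id != "HUB"] == 1))
  expect_equal(m$average_degree, 2 * 6 / 7)
  expect_equal(sum(m$nodes$degree), 2 * net$summary$n_edges)
  expect_equal(network_metrics(igraph::make_empty_graph(0))$average_degree, 0)

  set.seed(604)
  for (i in 1:30) {
    n <- sample(8:30, 1)
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.2)
    adj <- adj + t(adj)
    if (sum(adj) == 0) next
    idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
    ed <- data.frame(gene_i = sprintf("N%02d", idx[, 1]),
                     gene_j = sprintf("N%02d", idx[, 2]), trait = "t",
                     stringsAsFactors = FALSE)
    net <- build_epistasis_network(ed)
    got <- network_metrics(net)$nodes
    present <- sort(unique(c(ed$gene_i, ed$gene_j)))
    sub <- adj[match(present, sprintf("N%02d", 1:n)),
               match(present, sprintf("N%02d", 1:n))]
    o <- oracle_betweenness(sub)
    expect_equal(got$betweenness[match(present, got$gene_id)], o,
                 tolerance = 1e-9)
  }
})

test_that("node removal: hub strategy kills a star in one step, trajectories conserve", {
  star <- data.frame(gene_i = "HUB", gene_j = paste0("LEAF", 1:5),
                     trait = "t", stringsAsFactors = FALSE)
  net <- build_epistasis_network(star, candidates = "LEAF1")
  hub <- node_removal_simulation(net, "hub", steps = 2, seed = 1)
  expect_equal(hub, c(2 * 5 / 6, 0, 0))
  cand <- node_removal_simulation(net, "candidate", steps = 1, seed = 1)
  expect_gt(cand[2], 0)  # removing a leaf is strictly slower than the hub
  full <- node_removal_simulation(net, "random", steps = 6, seed = 3)
  expect_equal(full[7], 0)  # all nodes removed
  expect_length(full, 7)
  expect_error(node_removal_simulation(net, "hub", steps = 10), "exceeds")
  net2 <- build_epistasis_network(star)
  expect_error(node_removal_simulation(net2, "candidate", steps = 1),
               "candidate")

  # oracle: replay hub removals manually with igraph deletions
  set.seed(605)
  g <- igraph::sample_gnp(15, 0.3)
  igraph::V(g)$name <- sprintf("N%02d", 1:15)
  ed <- igraph::as_data_frame(g)
  names(ed) <- c("gene_i", "gene_j")
  ed$trait <- "t"
  net3 <- build_epistasis_network(ed)
  traj <- node_removal_simulation(net3, "hub", steps = 5, seed = 1)
  gg <- net3$graph
  manual <- 2 * igraph::ecount(gg) / igraph::vcount(gg)
  for (s in 1:5) {
    nm <- igraph::V(gg)$name
    deg <- igraph::degree(gg)
    gg <- igraph::delete_vertices(gg, nm[order(-deg, nm)[1]])
    manual <- c(manual, 2 * igraph::ecount(gg) / igraph::vcount(gg))
  }
  expect_equal(traj, manual)
})

test_that("planted interacting genes out-rank random genes in degree", {
  genes <- tiny_catalogue(20, 10)
  pairs <- expand.grid(gene_i = c("G001", "G002"),
                       gene_j = c("G010", "G011", "G012"),
                       stringsAsFactors = FALSE)
  pairs$effect <- 3
  cfg <- sim_config(n_lines = 300, genes = genes,
                    mean_mutations_per_line = 10, epistatic_pairs = pairs,
                    noise_sd = 1, seed = 61)
  mt <- simulate_genotypes(cfg)
  gb <- aggregate_by_gene(mt, genes)
  ph <- simulate_phenotypes(mt, cfg, n_wt = 0)
  ed <- pairwise_epistasis(gb, ph, "trait")
  planted <- unique(c(pairs$gene_i, pairs$gene_j))
  net <- build_epistasis_network(top_edges(ed, N = 20), candidates = planted)
  m <- network_metrics(net)$nodes
  cand_deg <- mean(m$degree[m$gene_id %in% planted])
  other_deg <- mean(m$degree[!m$gene_id %in% planted])
  expect_gt(cand_deg, other_deg)
})
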