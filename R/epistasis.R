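# Gene-level pairwise epistasis: for each eligible gene pair, the trait is
# regressed on both 0/1 presence indicators and their product; the
# interaction t-test is the edge statistic. Top edges per trait form the
# network; igraph supplies centralities, and a node-removal simulation
# probes robustness.

# OLS with full inference via QR; returns NULL when the design is singular.
ols_fit <- function(X, y) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) return(NULL)
  coef <- qr.coef(qrx, y)
  res <- y - X %*% coef
  df <- length(y) - ncol(X)
  if (df <= 0) return(NULL)
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(xtx_inv))
  list(coef = as.numeric(coef), se = se, df = df)
}

#' Pairwise gene-level epistasis scan for one trait
#'
#' For each pair of eligible genes (each with at least `min_carriers`
#' carrier lines), fits `y = b0 + b1*g_i + b2*g_j + b3*g_i*g_j` on the 0/1
#' presence indicators and reports the two-sided t statistic and p-value of
#' the interaction coefficient `b3`. Pairs with a constant or collinear
#' interaction column are skipped.
#'
#' @param burden A `gene_burden` object (the binary matrix is used).
#' @param phenotypes,trait Phenotype table and trait column.
#' @param min_carriers Eligibility floor per gene.
#' @param include_wt Include wild-type reference rows at zero presence.
#' @return `data.frame` of edges: `gene_i`, `gene_j` (i < j
#'   lexicographically), `trait`, `n_double_carriers`, `t`, `p`.
#' @export
pairwise_epistasis <- function(burden, phenotypes, trait, min_carriers = 5,
                               include_wt = TRUE) {
  stopifnot(inherits(burden, "gene_burden"))
  al <- align_burden_phenotype(burden, phenotypes, trait, "binary", include_wt)
  B <- al$X
  y <- al$y
  eligible <- rowSums(B) >= min_carriers
  genes <- rownames(B)[eligible]
  if (length(genes) < 2) {
    stop("need at least 2 genes with >= min_carriers carriers", call. = FALSE)
  }
  genes <- sort(genes)
  B <- B[genes, , drop = FALSE]
  pairs <- utils::combn(genes, 2)
  one <- rep(1, length(y))
  fit_pair <- function(i) {
    gi <- B[pairs[1, i], ]
    gj <- B[pairs[2, i], ]
    X <- cbind(one, gi, gj, gi * gj)
    f <- ols_fit(X, y)
    if (is.null(f)) return(c(NA_real_, NA_real_, sum(gi * gj)))
    t <- f$coef[4] / f$se[4]
    c(t, 2 * stats::pt(abs(t), df = f$df, lower.tail = FALSE), sum(gi * gj))
  }
  res <- vapply(seq_len(ncol(pairs)), fit_pair, numeric(3))
  out <- data.frame(gene_i = pairs[1, ], gene_j = pairs[2, ], trait = trait,
                    n_double_carriers = as.integer(res[3, ]),
                    t = res[1, ], p = res[2, ], stringsAsFactors = FALSE)
  skipped <- is.na(out$t)
  if (all(skipped)) warning("all gene pairs skipped (degenerate designs)")
  out <- out[!skipped, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the most significant epistatic edges per trait
#'
#' The `N` smallest-p edges within each trait; ties broken by lexicographic
#' (gene_i, gene_j) pair id for determinism.
#'
#' @param edges Edge table from [pairwise_epistasis()] (possibly several
#'   traits bound together).
#' @param N Edges to keep per trait.
#' @return Filtered edge table.
#' @export
top_edges <- function(edges, N = 1000) {
  pick <- function(e) {
    if (N > nrow(e)) {
      warning("fewer than N edges available; returning all")
      n <- nrow(e)
    } else n <- N
    e[order(e$p, e$gene_i, e$gene_j), , drop = FALSE][seq_len(n), , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(edges, edges$trait), pick))
  rownames(out) <- NULL
  out
}

#' Assemble the epistatic interaction network
#'
#' Builds a simple undirected graph from the edge table: parallel edges from
#' different traits are merged for topology, but the trait-labelled edge
#' table is retained. Node centralities are computed on assembly.
#'
#' @param edges Edge table ([pairwise_epistasis()] / [top_edges()]).
#' @param candidates Optional character vector of candidate gene ids to flag
#'   on the nodes.
#' @return Object of class `epistasis_network`: `graph` (igraph), `edges`,
#'   `nodes` (`gene_id`, `candidate`, `degree`, `betweenness`), `summary`
#'   (node/edge counts, average degree).
#' @export
build_epistasis_network <- function(edges, candidates = character()) {
  stopifnot(all(c("gene_i", "gene_j") %in% names(edges)))
  if (any(edges$gene_i == edges$gene_j)) stop("self-edges are not allowed",
                                              call. = FALSE)
  simple <- unique(edges[, c("gene_i", "gene_j")])
  g <- igraph::graph_from_data_frame(simple, directed = FALSE)
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  nodes <- data.frame(gene_id = igraph::V(g)$name,
                      candidate = igraph::V(g)$name %in% candidates,
                      degree = as.numeric(deg),
                      betweenness = as.numeric(btw),
                      stringsAsFactors = FALSE)
  structure(list(graph = g, edges = edges, nodes = nodes,
                 summary = list(n_nodes = igraph::vcount(g),
                                n_edges = igraph::ecount(g),
                                average_degree = mean(deg))),
            class = "epistasis_network")
}

#' @export
print.epistasis_network <- function(x, ...) {
  cat("Epistatic interaction network: ", x$summary$n_nodes, " genes, ",
      x$summary$n_edges, " edges (average degree ",
      signif(x$summary$average_degree, 3), ")\n", sep = "")
  invisible(x)
}

#' Node centralities and global metrics
#'
#' Degree (incident edges on the simple merged graph) and shortest-path
#' betweenness per node, plus the global average degree.
#'
#' @param network An `epistasis_network` (or bare igraph graph).
#' @return List with `nodes` (`gene_id`, `degree`, `betweenness`) and
#'   `average_degree`.
#' @export
network_metrics <- function(network) {
  g <- if (inherits(network, "epistasis_network")) network$graph else network
  if (igraph::vcount(g) == 0) {
    return(list(nodes = data.frame(gene_id = character(), degree = numeric(),
                                   betweenness = numeric()),
                average_degree = 0))
  }
  deg <- igraph::degree(g)
  list(nodes = data.frame(gene_id = igraph::V(g)$name,
                          degree = as.numeric(deg),
                          betweenness = as.numeric(
                            igraph::betweenness(g, directed = FALSE)),
                          stringsAsFactors = FALSE),
       average_degree = mean(deg))
}

#' Node-removal robustness simulation
#'
#' Removes one node per step — the current highest-degree node (`"hub"`,
#' ties broken lexicographically), a random candidate-flagged node
#' (`"candidate"`), or a uniformly random node (`"random"`) — and records
#' the network average degree after each removal. The returned trajectory
#' has length `steps + 1`, the first entry being the intact graph.
#'
#' @param network An `epistasis_network`.
#' @param strategy `"hub"`, `"candidate"` or `"random"`.
#' @param steps Number of removals (at most the node count).
#' @param seed Integer seed (used by the random strategies).
#' @return Numeric average-degree trajectory of length `steps + 1`.
#' @export
node_removal_simulation <- function(network,
                                    strategy = c("hub", "candidate", "random"),
                                    steps, seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(network, "epistasis_network"))
  g <- network$graph
  if (steps > igraph::vcount(g)) stop("steps exceeds node count", call. = FALSE)
  cand <- network$nodes$gene_id[network$nodes$candidate]
  if (strategy == "candidate" && !length(cand)) {
    stop("strategy 'candidate' requires candidate-flagged nodes", call. = FALSE)
  }
  avg_deg <- function(g) {
    n <- igraph::vcount(g)
    if (n == 0) 0 else 2 * igraph::ecount(g) / n
  }
  with_seed(seed, {
    traj <- numeric(steps + 1)
    traj[1] <- avg_deg(g)
    for (s in seq_len(steps)) {
      nm <- igraph::V(g)$name
      victim <- switch(strategy,
        hub = {
          deg <- igraph::degree(g)
          nm[order(-deg, nm)[1]]
        },
        candidate = {
          present <- intersect(cand, nm)
          if (!length(present)) sample(nm, 1) else
            present[sample.int(length(present), 1)]
        },
        random = nm[sample.int(length(nm), 1)]
      )
      g <- igraph::delete_vertices(g, victim)
      traj[s + 1] <- avg_deg(g)
    }
    traj
  })
}

#' Export the network as GraphML
#'
#' Node attributes: degree, betweenness, candidate flag.
#'
#' @param network An `epistasis_network`.
#' @param path Output `.graphml` file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- network$graph
  igraph::V(g)$degree <- network$nodes$degree
  igraph::V(g)$betweenness <- network$nodes$betweenness
  igraph::V(g)$candidate <- network$nodes$candidate
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
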