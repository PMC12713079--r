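# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the package's code paths.

# Pearson 2x2 chi-square (no continuity correction) from the four cells.
oracle_chi2_2x2 <- function(a, b, cc, d) {
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}

# Simple-regression inference via explicit normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 2
  sigma2 <- sum(res^2) / df
  cov <- sigma2 * solve(t(X) %*% X)
  se <- sqrt(cov[2, 2])
  t <- beta[2] / se
  list(slope = beta[2], se = se, t = t,
       p = 2 * pt(abs(t), df = df, lower.tail = FALSE))
}

# Full-design interaction t-test via explicit normal equations.
oracle_interaction_t <- function(gi, gj, y) {
  X <- cbind(1, gi, gj, gi * gj)
  XtX <- t(X) %*% X
  if (abs(det(XtX)) < 1e-10) return(NULL)
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 4
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * solve(XtX)[4, 4])
  t <- beta[4] / se
  list(t = t, p = 2 * pt(abs(t), df = df, lower.tail = FALSE))
}

# Degree-4 least squares via the normal equations of the Vandermonde design.
oracle_quartic <- function(positions, values) {
  V <- outer(positions, 0:4, `^`)
  as.numeric(solve(t(V) %*% V, t(V) %*% values))
}

# Shortest-path betweenness by all-pairs BFS path counting (undirected,
# unweighted, unordered pairs).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs <- function(s) {
    dist <- rep(Inf, n); sigma <- rep(0, n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
          if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  info <- lapply(seq_len(n), bfs)
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (is.infinite(info[[s]]$dist[t])) next
    total <- info[[s]]$sigma[t]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (info[[s]]$dist[v] + info[[v]]$dist[t] == info[[s]]$dist[t]) {
        btw[v] <- btw[v] + info[[s]]$sigma[v] * info[[v]]$sigma[t] / total
      }
    }
  }
  btw
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Small gene catalogue: n genes of s sites each on one chromosome.
tiny_catalogue <- function(n_genes = 20, n_sites = 10) {
  start <- seq(1, by = 1000, length.out = n_genes)
  data.frame(gene_id = sprintf("G%03d", seq_len(n_genes)), n_sites = n_sites,
             chrom = "chr1A", start = start, end = start + 999,
             stringsAsFactors = FALSE)
}

# Hand-built mutation table.
make_table <- function(line_id, chrom = "chr1A", pos, ref = "G", alt = "A",
                       gene_id = "G001", impact = "MODERATE", qual = 100,
                       depth = 10) {
  n <- max(length(line_id), length(pos))
  data.frame(line_id = rep(line_id, length.out = n),
             chrom = rep(chrom, length.out = n),
             pos = rep(pos, length.out = n),
             ref = rep(ref, length.out = n), alt = rep(alt, length.out = n),
             gene_id = rep(gene_id, length.out = n),
             impact = rep(impact, length.out = n),
             qual = rep(qual, length.out = n),
             depth = rep(depth, length.out = n), stringsAsFactors = FALSE)
}

# Random small binary burden object (carriers guaranteed non-degenerate).
random_burden <- function(n_genes, n_lines, p = 0.3) {
  tabs <- list()
  genes <- sprintf("G%03d", seq_len(n_genes))
  lines <- sprintf("L%03d", seq_len(n_lines))
  count <- matrix(rbinom(n_genes * n_lines, 2, p), n_genes,
                  dimnames = list(genes, lines))
  imp <- lapply(c(HIGH = 1, MODERATE = 2, LOW = 3, MODIFIER = 4), function(i) {
    m <- count * 0
    m
  })
  imp$MODERATE <- count
  structure(list(genes = genes, lines = lines, count = count,
                 weighted = count * 0.66, binary = (count > 0) * 1L,
                 impact_counts = imp,
                 weights = emsburden::default_impact_weights()),
            class = "gene_burden")
}

# Deviant split with membership fixed by hand (bypasses the z rule).
manual_split <- function(lines, deviant) {
  structure(list(trait = "trait", center = 0, sd = 1, z_threshold = 1,
                 center_mode = "population", deviant = deviant,
                 non_deviant = setdiff(lines, deviant), lines = lines),
            class = "deviant_split")
}

pheno_frame <- function(line_ids, y, is_wt = FALSE, trait = "trait") {
  d <- data.frame(line_id = line_ids,
                  is_wt = rep(is_wt, length.out = length(line_ids)),
                  stringsAsFactors = FALSE)
  d[[trait]] <- y
  d
}
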