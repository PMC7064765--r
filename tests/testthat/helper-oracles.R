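# Brute-force oracles, independent of the implementation paths they check.

# closed-form logistic growth
oracle_logistic <- function(t, B0, r, k) {
  k * B0 * exp(r * t) / (k + B0 * (exp(r * t) - 1))
}

# rank correlation from first principles (average ranks, Pearson on ranks)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# power iteration on an adjacency matrix, max-normalized.  The spectral
# shift A + nI keeps the iteration from oscillating on bipartite graphs
# (eigenvalues +/- lambda) without changing the eigenvectors.  Well-posed
# only when the non-isolated subgraph is connected (unique Perron vector).
oracle_eigen <- function(adj, iter = 5000) {
  shifted <- adj + diag(nrow(adj)) * nrow(adj)
  v <- rep(1, nrow(adj))
  for (i in seq_len(iter)) {
    v2 <- shifted %*% v
    v <- v2 / sqrt(sum(v2^2))
  }
  v <- abs(as.numeric(v))
  v[v < 1e-8] <- 0
  v / max(v)
}

# TRUE when the subgraph over non-isolated nodes is a single component
nonisolated_connected <- function(adj) {
  keep <- which(rowSums(adj) > 0)
  length(keep) >= 2 &&
    oracle_components(adj[keep, keep, drop = FALSE]) == 1
}

# all-pairs BFS distances on an unweighted graph (0/1 adjacency)
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s; depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) nxt <- union(nxt, which(adj[v, ] > 0))
      nxt <- nxt[d[s, nxt] == Inf]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# betweenness by enumerating all shortest paths (DFS over the BFS DAG)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  score <- rep(0, n)
  all_paths <- function(s, t) {
    # enumerate node sequences of shortest s->t paths
    if (d[s, t] == Inf) return(list())
    if (s == t) return(list(s))
    out <- list()
    for (v in which(adj[s, ] > 0)) {
      if (d[v, t] == d[s, t] - 1) {
        for (p in all_paths(v, t)) out[[length(out) + 1L]] <- c(s, p)
      }
    }
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      score[inner] <- score[inner] + 1 / length(paths)
    }
  }
  score
}

# connected components by union-find
oracle_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (adj[i, j] > 0) parent[find(i)] <- find(j)
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

oracle_bray <- function(a, b) sum(abs(a - b)) / sum(a + b)

# random symmetric 0/1 adjacency, no self loops
random_adjacency <- function(n, p = 0.5) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# random connected adjacency (rejection sampling)
random_connected_adjacency <- function(n, p = 0.3) {
  repeat {
    a <- random_adjacency(n, p)
    if (all(rowSums(a) > 0) && oracle_components(a) == 1) return(a)
  }
}

# wrap a plain 0/1 (or weighted) adjacency as an interaction matrix
as_eta <- function(adj) {
  dimnames(adj) <- list(paste0("t", seq_len(nrow(adj))),
                        paste0("t", seq_len(nrow(adj))))
  threshold_network(adj, rho_min = 1e-9, p_max = 1)
}

# small synthetic zone tables for scenario tests
make_zone_tables <- function(seed = 101, n_taxa = 12, n_samples = 6) {
  blocks <- list(list(members = 1:3, rho = 0.9))
  ti <- gen_abundance_table(synth_spec(n_samples, n_taxa, blocks = blocks,
                                       seed = seed))
  to <- gen_abundance_table(synth_spec(n_samples, n_taxa, blocks = blocks,
                                       seed = seed + 1))
  list(inner = ti, outer = to)
}
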