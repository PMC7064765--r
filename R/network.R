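# Co-occurrence network inference: pairwise Spearman correlation across
# samples, significance + strength thresholding, and the centrality/diameter
# summaries used to characterize each reef zone's network.

#' Pairwise Spearman correlation matrix
#'
#' Rank correlation (average ranks for ties) between every pair of taxa
#' across samples.  P-values use the t-approximation on `n - 2` degrees of
#' freedom by default; `p_method = "exact"` enumerates all rank permutations
#' (feasible up to ~8 samples) for an exact two-sided permutation p-value.
#'
#' A taxon that is constant across samples has undefined correlations; its
#' rows/columns are reported as `NA` and later excluded from edges.
#'
#' @param table an [abundance_table()] (or sample x taxon matrix); >= 3
#'   samples and >= 2 taxa.
#' @param p_method `"t"` (default) or `"exact"`.
#' @return object of class `sml_corr`: list with symmetric matrices `rho`
#'   and `p` (diagonal 1 and 0), `n_samples`, and `constant_taxa`.
#' @export
spearman_matrix <- function(table, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  m <- as.matrix(table)
  n <- nrow(m); p <- ncol(m)
  if (n < 3L) stop_("need >= 3 samples for correlation (got %d)", n)
  if (p < 2L) stop_("need >= 2 taxa (got %d)", p)
  if (is.null(colnames(m))) colnames(m) <- paste0("taxon", seq_len(p))
  const <- apply(m, 2L, function(x) length(unique(x)) == 1L)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  rho[const, ] <- NA_real_; rho[, const] <- NA_real_
  diag(rho) <- ifelse(const, NA_real_, 1)
  if (p_method == "t") {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
    pmat <- 2 * stats::pt(-abs(tstat), df = n - 2)
    pmat[abs(rho) >= 1 - 1e-12] <- 0       # |rho| = 1: t diverges
  } else {
    if (n > 8L)
      stop_("exact permutation p-values are only supported for <= 8 samples")
    ranks <- apply(m, 2L, rank)
    perms <- .permutations(n)
    pmat <- matrix(NA_real_, p, p)
    for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
      if (const[i] || const[j]) next
      obs <- rho[i, j]
      null <- apply(perms, 1L, function(ix)
        stats::cor(ranks[, i], ranks[ix, j], method = "spearman"))
      pmat[i, j] <- pmat[j, i] <- mean(abs(null) >= abs(obs) - 1e-12)
    }
    diag(pmat) <- 0
  }
  diag(pmat)[!const] <- 0
  pmat[const, ] <- NA_real_; pmat[, const] <- NA_real_
  dimnames(rho) <- dimnames(pmat) <- list(colnames(m), colnames(m))
  structure(list(rho = rho, p = pmat, n_samples = n,
                 constant_taxa = colnames(m)[const]),
            class = "sml_corr")
}

# all permutations of 1..n (n <= 8)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    out[r + seq_len(rows), ] <- cbind(rep(k, rows),
                                      matrix(setdiff(seq_len(n), k)[sub],
                                             rows, n - 1L))
    r <- r + rows
  }
  out
}

#' @export
print.sml_corr <- function(x, ...) {
  cat(sprintf("<sml_corr> %d taxa over %d samples", ncol(x$rho), x$n_samples))
  if (length(x$constant_taxa))
    cat(sprintf("; %d constant taxa excluded", length(x$constant_taxa)))
  cat("\n")
  invisible(x)
}

#' Threshold a correlation matrix into an interaction network
#'
#' Retains coefficient `rho_ij` (with its sign) as interaction weight
#' `eta_ij` when `|rho_ij| >= rho_min` and `p_ij <= p_max`; every other
#' entry, undefined pairs, and the diagonal become 0.  Defaults follow the
#' network construction used for reef-zone co-occurrence graphs:
#' `rho_min = 0.7`, `p_max = 0.001`.
#'
#' @param corr an [spearman_matrix()] result (or a plain correlation matrix,
#'   in which case `p` defaults to all-zero and only the rho filter acts).
#' @param rho_min minimum |rho| retained.
#' @param p_max maximum p-value retained.
#' @return a symmetric matrix of class `interaction_matrix` with zero
#'   diagonal; retained p-values are kept in `attr(, "p")` for export.
#' @export
threshold_network <- function(corr, rho_min = 0.7, p_max = 0.001) {
  if (inherits(corr, "interaction_matrix")) {
    rho <- unclass(corr)
    pmat <- attr(corr, "p")
    if (is.null(pmat)) pmat <- matrix(0, nrow(rho), ncol(rho))
  } else if (inherits(corr, "sml_corr")) {
    rho <- corr$rho; pmat <- corr$p
  } else if (is.matrix(corr)) {
    rho <- corr; pmat <- matrix(0, nrow(rho), ncol(rho))
  } else stop_("`corr` must be an sml_corr or a matrix")
  check_number(rho_min, "rho_min", nonneg = TRUE)
  check_number(p_max, "p_max", nonneg = TRUE)
  keep <- !is.na(rho) & !is.na(pmat) & abs(rho) >= rho_min & pmat <= p_max
  eta <- ifelse(keep, rho, 0)
  diag(eta) <- 0
  pkeep <- ifelse(keep, pmat, NA_real_)
  diag(pkeep) <- NA_real_
  structure(eta, p = pkeep, rho_min = rho_min, p_max = p_max,
            class = c("interaction_matrix", "matrix", "array"))
}

#' @export
print.interaction_matrix <- function(x, ...) {
  e <- sum(unclass(x)[upper.tri(x)] != 0)
  cat(sprintf("<interaction_matrix> %d taxa, %d edges (|rho| >= %s, p <= %s)\n",
              nrow(x), e, format(attr(x, "rho_min")), format(attr(x, "p_max"))))
  invisible(x)
}

as_interaction_graph <- function(eta) {
  m <- abs(unclass(as.matrix(eta)))
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$sign <- sign(unclass(as.matrix(eta))[igraph::as_edgelist(g, names = FALSE)])
  g
}

#' Eigenvector centrality of an interaction network
#'
#' Principal-eigenvector scores on the absolute-weight adjacency matrix
#' (negative edge weights would break the Perron-Frobenius guarantee),
#' normalized so the maximum score is 1.  Nodes without retained edges score
#' 0 but are kept.
#'
#' @param eta an [threshold_network()] interaction matrix.
#' @return named numeric vector in `[0, 1]`.
#' @export
eigen_centrality_scores <- function(eta) {
  g <- as_interaction_graph(eta)
  if (igraph::ecount(g) == 0L)
    stop_("network has no edges; eigenvector centrality undefined")
  sc <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  # numerical zeros from ARPACK on isolated nodes
  sc[sc < 1e-10] <- 0
  sc
}

#' Betweenness centrality of an interaction network
#'
#' Unweighted shortest-path betweenness (undirected).  Unnormalized counts
#' by default, matching the scale on which reef-network brokers were ranked;
#' set `normalized = TRUE` for the `2/((n-1)(n-2))` scaling.
#'
#' @param eta an interaction matrix.
#' @param normalized logical.
#' @return named numeric vector, >= 0.
#' @export
betweenness_scores <- function(eta, normalized = FALSE) {
  g <- as_interaction_graph(eta)
  igraph::betweenness(g, directed = FALSE, weights = NA,
                      normalized = normalized)
}

#' Unweighted network diameter
#'
#' Longest shortest path in hops over the whole network; requires a
#' connected graph (isolated, edge-less taxa are ignored).
#'
#' @param eta an interaction matrix.
#' @return integer number of hops.
#' @export
network_diameter <- function(eta) {
  g <- as_interaction_graph(eta)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  if (igraph::vcount(g) < 2L)
    stop_("network has fewer than 2 connected nodes; diameter undefined")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    sizes <- paste(comp$csize, collapse = ", ")
    stop_("network is disconnected (%d components of sizes %s); diameter undefined",
          comp$no, sizes)
  }
  as.integer(igraph::diameter(g, weights = NA))
}

#' Connected components of an interaction network
#'
#' Counts connected components among nodes that have at least one retained
#' edge; taxa with no edges are reported separately via the `"isolated"`
#' attribute rather than inflating the count.
#'
#' @param eta an interaction matrix.
#' @return integer component count with attribute `isolated` (number of
#'   edge-less taxa).
#' @export
component_count <- function(eta) {
  g <- as_interaction_graph(eta)
  iso <- sum(igraph::degree(g) == 0L)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0L))
  n <- if (igraph::vcount(g) == 0L) 0L else igraph::components(g)$no
  structure(as.integer(n), isolated = as.integer(iso))
}

#' Summarize an interaction network
#'
#' Per-node eigenvector and betweenness centrality plus whole-network
#' counts: connected nodes, edges, unweighted diameter (NA when
#' disconnected) and component count.
#'
#' @param eta an interaction matrix.
#' @return list with `nodes` (data.frame `taxon,eigen_centrality,betweenness`),
#'   `n_nodes`, `n_edges`, `diameter`, `n_components`, `n_isolated`.
#' @export
network_summary <- function(eta) {
  g <- as_interaction_graph(eta)
  deg <- igraph::degree(g)
  eig <- if (igraph::ecount(g) > 0L) eigen_centrality_scores(eta)
         else stats::setNames(rep(0, nrow(eta)), rownames(eta))
  btw <- betweenness_scores(eta)
  diam <- tryCatch(network_diameter(eta), error = function(e) NA_integer_)
  cc <- component_count(eta)
  list(nodes = data.frame(taxon = names(deg),
                          eigen_centrality = unname(eig),
                          betweenness = unname(btw),
                          stringsAsFactors = FALSE),
       n_nodes = sum(deg > 0L),
       n_edges = igraph::ecount(g),
       diameter = diam,
       n_components = as.integer(cc),
       n_isolated = attr(cc, "isolated"))
}

#' Export an interaction network
#'
#' `write_edge_list()` writes a weighted edge list CSV
#' (`taxon_a,taxon_b,rho,p`); `write_graphml()` writes GraphML with signed
#' `rho` edge weights.
#'
#' @param eta an interaction matrix (from [threshold_network()], so that
#'   retained p-values are available; otherwise p is NA).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(eta, path) {
  m <- unclass(as.matrix(eta))
  pmat <- attr(eta, "p")
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  df <- data.frame(
    taxon_a = rownames(m)[idx[, 1L]],
    taxon_b = colnames(m)[idx[, 2L]],
    rho = m[idx],
    p = if (is.null(pmat)) NA_real_ else pmat[idx])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(eta, path) {
  m <- unclass(as.matrix(eta))
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname network_summary
#' @param summary a [network_summary()] result.
#' @param path output file path.
#' @export
write_network_summary <- function(summary, path) {
  utils::write.csv(summary$nodes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
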