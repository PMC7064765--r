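test_that("spearman_matrix recovers rank correlation", {
  m <- cbind(a = 1:6, b = c(2, 4, 6, 8, 10, 12), c = 6:1)
  sm <- spearman_matrix(m)
  expect_equal(sm$rho["a", "b"], 1)    # identical rank order
  expect_equal(sm$rho["a", "c"], -1)   # reversed ranks
  # 5-sample toy, frozen from the brute-force rank-correlation oracle
  toy <- cbind(x = 1:5, y = c(2, 1, 4, 3, 5), z = c(3, 3, 1, 5, 2))
  expect_equal(oracle_spearman(toy[, "x"], toy[, "y"]), 0.8)
  sm2 <- spearman_matrix(toy)
  expect_equal(sm2$rho["x", "y"], 0.8)
  expect_equal(sm2$rho["x", "z"], oracle_spearman(toy[, "x"], toy[, "z"]))
  # symmetry and diagonal
  expect_equal(sm2$rho, t(sm2$rho))
  expect_equal(unname(diag(sm2$rho)), rep(1, 3))
  expect_equal(unname(diag(sm2$p)), rep(0, 3))
})

test_that("spearman p-values match the t-approximation", {
  set.seed(42)
  m <- matrix(rlnorm(8 * 5), 8, 5, dimnames = list(NULL, paste0("t", 1:5)))
  sm <- spearman_matrix(m)
  for (i in 1:4) for (j in (i + 1):5) {
    ct <- suppressWarnings(cor.test(m[, i], m[, j], method = "spearman",
                                    exact = FALSE))
    expect_equal(sm$rho[i, j], unname(ct$estimate))
    expect_equal(sm$p[i, j], ct$p.value, tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  m <- matrix(rlnorm(7 * 4), 7, 4)
  sm <- spearman_matrix(m)
  m2 <- m
  m2[, 1] <- exp(m2[, 1]); m2[, 2] <- m2[, 2]^3; m2[, 3] <- log1p(m2[, 3])
  expect_equal(spearman_matrix(m2)$rho, sm$rho)
})

test_that("constant taxa are reported missing, not correlated", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  sm <- spearman_matrix(m)
  expect_equal(sm$constant_taxa, "b")
  expect_true(all(is.na(sm$rho[, "b"])))
  expect_false(anyNA(sm$rho[c("a", "c"), c("a", "c")]))
  # constant taxa never produce edges
  eta <- threshold_network(sm, rho_min = 0, p_max = 1)
  expect_true(all(unclass(eta)[, "b"] == 0))
})

test_that("exact permutation p-values enumerate the null", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1.5, 2.5, 3.5, 10))
  sm <- spearman_matrix(m, p_method = "exact")
  # perfectly concordant ranks: 2 of 4! = 24 permutations reach |rho| = 1
  expect_equal(sm$p["a", "b"], 2 / 24)
  expect_error(spearman_matrix(matrix(rnorm(9 * 2), 9, 2),
                               p_method = "exact"), "8 samples")
})

test_that("threshold_network applies both filters and is idempotent", {
  rho <- matrix(c(1, 0.65, 0.9, -0.8,
                  0.65, 1, 0.2, 0.75,
                  0.9, 0.2, 1, 0.1,
                  -0.8, 0.75, 0.1, 1), 4, 4,
                dimnames = list(letters[1:4], letters[1:4]))
  p <- matrix(1e-6, 4, 4, dimnames = dimnames(rho))
  p["b", "d"] <- p["d", "b"] <- 0.05   # strong rho but not significant
  corr <- structure(list(rho = rho, p = p, n_samples = 6,
                         constant_taxa = character()), class = "sml_corr")
  eta <- threshold_network(corr)
  expect_equal(eta["a", "b"], 0)       # |rho| below 0.7
  expect_equal(eta["a", "c"], 0.9)     # retained
  expect_equal(eta["a", "d"], -0.8)    # negative edge retained with sign
  expect_equal(eta["b", "d"], 0)       # p above 0.001
  expect_equal(unname(diag(unclass(eta))), rep(0, 4))
  expect_equal(unclass(threshold_network(eta)), unclass(eta))  # idempotent
})

test_that("eigenvector centrality matches closed forms and the oracle", {
  # complete graph: all scores 1
  cg <- as_eta(random_adjacency(4, p = 1.1))
  expect_equal(unname(eigen_centrality_scores(cg)), rep(1, 4))
  # 5-node star: hub 1, leaves 1/2
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star[2:5, 1] <- 1
  expect_equal(unname(eigen_centrality_scores(as_eta(star))),
               c(1, rep(0.5, 4)))
  # isolated node scores 0
  star6 <- rbind(cbind(star, 0), 0)
  expect_equal(unname(eigen_centrality_scores(as_eta(star6)))[6], 0)
  # empty graph errors
  expect_error(eigen_centrality_scores(as_eta(matrix(0, 3, 3))), "no edges")
  # random graphs vs power iteration
  set.seed(31)
  for (i in 1:15) {
    adj <- random_connected_adjacency(sample(3:6, 1), p = 0.5)
    expect_equal(unname(eigen_centrality_scores(as_eta(adj))),
                 oracle_eigen(adj), tolerance = 1e-6)
  }
})

test_that("betweenness matches path enumeration", {
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  expect_equal(unname(betweenness_scores(as_eta(path3))), c(0, 1, 0))
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star[2:5, 1] <- 1
  expect_equal(unname(betweenness_scores(as_eta(star))), c(6, 0, 0, 0, 0))
  cg <- random_adjacency(5, p = 1.1)
  expect_equal(unname(betweenness_scores(as_eta(cg))), rep(0, 5))
  set.seed(13)
  for (i in 1:15) {
    adj <- random_connected_adjacency(sample(3:6, 1), p = 0.4)
    expect_equal(unname(betweenness_scores(as_eta(adj))),
                 oracle_betweenness(adj), tolerance = 1e-10)
  }
  # normalized flag rescales by 2 / ((n-1)(n-2))
  expect_equal(unname(betweenness_scores(as_eta(star), normalized = TRUE)),
               c(6 / 6, 0, 0, 0, 0))
})

test_that("diameter and components match BFS / union-find oracles", {
  path4 <- matrix(0, 4, 4)
  path4[cbind(1:3, 2:4)] <- 1; path4 <- path4 + t(path4)
  expect_equal(network_diameter(as_eta(path4)), 3L)
  expect_equal(network_diameter(as_eta(random_adjacency(5, p = 1.1))), 1L)
  set.seed(99)
  adj <- random_connected_adjacency(15, p = 0.2)
  d <- oracle_distances(adj)
  expect_equal(network_diameter(as_eta(adj)), as.integer(max(d)))
  # disconnected graph errors with component sizes
  two <- matrix(0, 4, 4); two[1, 2] <- two[2, 1] <- 1
  two[3, 4] <- two[4, 3] <- 1
  expect_error(network_diameter(as_eta(two)), "disconnected")
  expect_equal(as.integer(component_count(as_eta(two))), 2L)
  one <- matrix(0, 3, 3); one[1, 2] <- one[2, 1] <- 1
  cc <- component_count(as_eta(one))
  expect_equal(as.integer(cc), 1L)
  expect_equal(attr(cc, "isolated"), 1L)   # node 3 reported separately
  set.seed(17)
  for (i in 1:10) {
    adj <- random_adjacency(6, p = 0.3)
    connected <- which(rowSums(adj) > 0)
    if (!length(connected)) next
    expect_equal(as.integer(component_count(as_eta(adj))),
                 oracle_components(adj[connected, connected, drop = FALSE]))
  }
})

test_that("network summary and exports are consistent", {
  set.seed(8)
  tab <- gen_abundance_table(synth_spec(
    12, 8, blocks = list(list(members = 1:4, rho = 0.97)), seed = 8))
  eta <- threshold_network(spearman_matrix(tab))
  ns <- network_summary(eta)
  expect_equal(nrow(ns$nodes), 8)
  expect_equal(ns$n_edges, sum(unclass(eta)[upper.tri(eta)] != 0))
  expect_true(all(ns$nodes$eigen_centrality >= 0 &
                    ns$nodes$eigen_centrality <= 1))
  # edge list round-trips the retained pairs
  f <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(eta, f)
  el <- read.csv(f)
  expect_named(el, c("taxon_a", "taxon_b", "rho", "p"))
  expect_equal(nrow(el), ns$n_edges)
  expect_true(all(abs(el$rho) >= 0.7 & el$p <= 0.001))
  # graphml round-trips through igraph
  gfile <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(eta, gfile)
  g <- igraph::read_graph(gfile, format = "graphml")
  expect_equal(igraph::ecount(g), ns$n_edges)
  sfile <- withr::local_tempfile(fileext = ".csv")
  write_network_summary(ns, sfile)
  expect_named(read.csv(sfile), c("taxon", "eigen_centrality", "betweenness"))
})
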