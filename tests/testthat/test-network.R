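perfect_corr <- function(nt = 3, ns = 6, r = 0.9) {
  # construct a cooccur_cor by hand with uniform off-diagonal structure
  ids <- sprintf("t%d", seq_len(nt))
  rmat <- matrix(r, nt, nt, dimnames = list(ids, ids))
  diag(rmat) <- 1
  p <- matrix(0.0001, nt, nt, dimnames = list(ids, ids))
  diag(p) <- 1
  q <- matrix(0.001, nt, nt, dimnames = list(ids, ids))
  diag(q) <- 1
  structure(list(r = rmat, p = p, q = q, method = "spearman",
                 n_samples = ns, zero_variance = character()),
            class = "cooccur_cor")
}

test_that("edge thresholds behave as a strict filter", {
  cc <- perfect_corr()
  net <- build_network(cc, r_min = 0.6, alpha = 0.05)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$sign == "+"))
  empty <- build_network(cc, r_min = 1.01, alpha = 0.05)
  expect_true(empty$empty)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("the edge set equals a brute-force filter over all pairs", {
  withr::with_seed(31, m <- matrix(rexp(120), 12, 10))
  dimnames(m) <- list(sprintf("t%02d", 1:12), sprintf("s%02d", 1:10))
  ab <- dplyr::bind_cols(tibble::tibble(taxon_id = rownames(m)),
                         tibble::as_tibble(m))
  cc <- pairwise_correlation(ab)
  for (r_min in c(0.3, 0.6)) {
    net <- build_network(cc, r_min = r_min, alpha = 0.4)
    want <- 0
    for (i in 1:11) for (j in (i + 1):12) {
      if (abs(cc$r[i, j]) >= r_min && cc$q[i, j] < 0.4) want <- want + 1
    }
    expect_equal(nrow(net$edges), want)
  }
  # monotonicity: tightening either threshold never adds edges
  e1 <- nrow(build_network(cc, 0.3, 0.4)$edges)
  e2 <- nrow(build_network(cc, 0.5, 0.4)$edges)
  e3 <- nrow(build_network(cc, 0.3, 0.2)$edges)
  expect_lte(e2, e1)
  expect_lte(e3, e1)
})

test_that("topology matches hand-computed values on named fixtures", {
  triangle <- make_network(tibble::tibble(
    taxon_a = c("a", "b", "c"), taxon_b = c("b", "c", "a"), r = 0.9))
  tp <- topology(triangle)
  expect_equal(tp$graph_density, 1)
  expect_equal(tp$clustering_coefficient, 1)
  expect_equal(tp$average_path_length, 1)
  expect_equal(tp$average_degree, 2)

  path3 <- make_network(tibble::tibble(
    taxon_a = c("a", "b"), taxon_b = c("b", "c"), r = 0.9))
  tp <- topology(path3)
  expect_equal(tp$clustering_coefficient, 0)
  expect_equal(tp$average_path_length, 4 / 3)

  two_tri <- make_network(tibble::tibble(
    taxon_a = c("a", "b", "c", "x", "y", "z"),
    taxon_b = c("b", "c", "a", "y", "z", "x"), r = 0.9))
  tp <- topology(two_tri)
  # two modules of three: Q = 2 * (3/6 - (6/12)^2)
  expect_equal(tp$modularity, 0.5)
  expect_equal(tp$average_path_length, 1)
})

test_that("topology agrees with brute-force loops on random graphs", {
  for (seed in c(5, 17)) {
    withr::with_seed(seed, {
      ids <- sprintf("v%02d", 1:9)
      pairs <- t(combn(ids, 2))
      take <- sample(nrow(pairs), 14)
    })
    edges <- tibble::tibble(taxon_a = pairs[take, 1],
                            taxon_b = pairs[take, 2], r = 0.8)
    net <- make_network(edges)
    tp <- topology(net)
    adj <- edges_to_adj(edges)
    expect_equal(tp$clustering_coefficient,
                 mean(brute_local_clustering(adj)), tolerance = 1e-12)
    expect_equal(tp$average_path_length,
                 brute_avg_path_length(adj), tolerance = 1e-12)
    expect_equal(tp$n_edges, nrow(edges))
    expect_equal(tp$average_degree, 2 * nrow(edges) / nrow(adj))
  }
})

test_that("an empty network reports zero metrics with a flag", {
  empty <- build_network(perfect_corr(r = 0.1), r_min = 0.6, alpha = 0.05)
  tp <- topology(empty)
  expect_true(tp$empty)
  expect_equal(tp$n_nodes, 0L)
  expect_equal(tp$average_path_length, 0)
})

test_that("complexity PC1 matches an eigen oracle and is oriented", {
  withr::with_seed(9, {
    base <- data.frame(
      n_nodes = sample(20:60, 6), n_edges = sample(30:200, 6),
      average_degree = runif(6, 2, 8), graph_density = runif(6, 0.05, 0.4),
      clustering_coefficient = runif(6), modularity = runif(6, 0.2, 0.8),
      average_path_length = runif(6, 1.2, 3))
  })
  base$average_degree <- base$n_edges / 10  # couple degree to edges
  pc <- complexity_pc1(base)
  oracle <- eigen_pc1(as.matrix(base))
  r <- cor(tidy(pc)$pc1, oracle)
  expect_gt(abs(r), 1 - 1e-9)
  expect_gte(pc$loadings["average_degree", 1], 0)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
})

test_that("degenerate PCA inputs behave as documented", {
  tp <- tibble::tibble(
    n_nodes = c(10, 10, 20), n_edges = c(30, 30, 80),
    average_degree = c(6, 6, 8), graph_density = c(0.2, 0.2, 0.3),
    clustering_coefficient = c(0.5, 0.5, 0.7),
    modularity = c(0.4, 0.4, 0.4),  # constant -> dropped
    average_path_length = c(2, 2, 1.5))
  pc <- complexity_pc1(tp)
  expect_equal(pc$dropped, "modularity")
  # the two identical networks get identical scores
  expect_equal(tidy(pc)$pc1[1], tidy(pc)$pc1[2])
  # perfectly collinear metrics -> PC1 explains everything
  lin <- tp
  for (nm in names(lin)) lin[[nm]] <- c(1, 2, 3) * mean(tp[[nm]])
  pc2 <- complexity_pc1(lin)
  expect_equal(pc2$var_explained[1], 1, tolerance = 1e-9)
  expect_error(complexity_pc1(tp[1:2, ]), "at least 3 networks")
})
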