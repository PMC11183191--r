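abund_tbl <- function(m) {
  dplyr::bind_cols(tibble::tibble(taxon_id = rownames(m)),
                   tibble::as_tibble(m))
}

test_that("Monte-Carlo null correction approaches the exhaustive null", {
  # small instance: every permutation of one taxon's vector enumerated
  withr::with_seed(14, m <- matrix(rexp(20), 4, 5))
  m <- sweep(m, 2, colSums(m), "/")
  dimnames(m) <- list(paste0("t", 1:4), paste0("s", 1:5))
  perms <- all_perms(5)
  exhaustive <- matrix(0, 4, 4)
  for (j in 1:3) for (k in (j + 1):4) {
    acc <- 0
    for (p in seq_len(nrow(perms))) {
      acc <- acc + cor(m[j, perms[p, ]], m[k, ]) +
        cor(m[j, ], m[k, perms[p, ]])
    }
    null_mean <- acc / (2 * nrow(perms))
    exhaustive[j, k] <- exhaustive[k, j] <- cor(m[j, ], m[k, ]) - null_mean
  }
  got <- null_corrected_correlations(abund_tbl(m), n_iter = 20000, seed = 4)
  expect_lt(max(abs(got[upper.tri(got)] - exhaustive[upper.tri(got)])),
            0.015)
})

test_that("a constant taxon gets corrected r of zero everywhere", {
  m <- rbind(t1 = c(1, 2, 3, 4, 5), t2 = rep(0.2, 5),
             t3 = c(5, 1, 4, 2, 3))
  colnames(m) <- paste0("s", 1:5)
  cc <- null_corrected_correlations(abund_tbl(m), n_iter = 50, seed = 1)
  expect_true(all(cc["t2", ] == 0))
  expect_equal(attr(cc, "zero_variance"), "t2")
})

test_that("the null mean vanishes for exchangeable data", {
  withr::with_seed(8, m <- matrix(rnorm(160, 10), 8, 20))
  dimnames(m) <- list(paste0("t", 1:8), paste0("s", 1:20))
  cc <- null_corrected_correlations(abund_tbl(m), n_iter = 500, seed = 2)
  obs <- suppressWarnings(cor(t(m)))
  diag(obs) <- 0
  # corrected should sit close to the raw correlation: null mean ~ 0
  expect_lt(max(abs(cc - obs)), 0.06)
})

test_that("connectedness partitions partners by sign", {
  cmat <- matrix(0, 4, 4, dimnames = list(paste0("t", 1:4),
                                          paste0("t", 1:4)))
  cmat["t1", 2:4] <- cmat[2:4, "t1"] <- c(0.2, 0.4, -0.3)
  cmat["t2", "t3"] <- cmat["t3", "t2"] <- -0.1
  cn <- connectedness(cmat)
  expect_equal(cn$pos[cn$taxon_id == "t1"], 0.3)
  expect_equal(cn$neg[cn$taxon_id == "t1"], -0.3)
  all_neg <- -abs(cmat)
  diag(all_neg) <- 0
  cn2 <- connectedness(all_neg)
  expect_true(all(cn2$pos == 0))
})

test_that("connectedness and cohesion agree with loop oracles", {
  withr::with_seed(21, cm <- matrix(runif(900, -1, 1), 30, 30))
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 0
  dimnames(cm) <- list(sprintf("t%02d", 1:30), sprintf("t%02d", 1:30))
  cn <- connectedness(cm)
  oracle <- loop_connectedness(cm)
  expect_equal(cn$pos, oracle$pos, tolerance = 1e-12)
  expect_equal(cn$neg, oracle$neg, tolerance = 1e-12)

  ab <- random_relabund(30, 12, seed = 22)
  m <- as.matrix(ab[-1])
  rownames(m) <- ab$taxon_id
  ch <- cohesion(ab, cn)
  oc <- loop_cohesion(m, oracle$pos, oracle$neg)
  expect_equal(ch$pos, oc$pos, tolerance = 1e-12)
  expect_equal(ch$neg, oc$neg, tolerance = 1e-12)
  expect_equal(ch$total, oc$pos + abs(oc$neg), tolerance = 1e-12)
})

test_that("worked cohesion example: abundance-weighted connectedness", {
  ab <- tibble::tibble(taxon_id = c("a", "b"), s1 = c(0.5, 0.5))
  conn <- tibble::tibble(taxon_id = c("a", "b"), pos = c(0.2, 0.4),
                         neg = c(0, 0))
  ch <- cohesion(ab, conn)
  expect_equal(ch$pos, 0.3)
  expect_equal(ch$neg, 0)
  expect_equal(ch$neg_pos_ratio, 0)
  expect_true(ch$ratio_defined)

  # all-zero connectedness: everything 0 and the ratio is undefined
  conn0 <- dplyr::mutate(conn, pos = 0, neg = 0)
  ch0 <- cohesion(ab, conn0)
  expect_equal(ch0$total, 0)
  expect_true(is.na(ch0$neg_pos_ratio))
  expect_false(ch0$ratio_defined)
})

test_that("sign and scale contracts hold on random instances", {
  for (seed in 1:4) {
    ab <- random_relabund(15, 10, seed = seed)
    cc <- null_corrected_correlations(ab, n_iter = 60, seed = seed)
    cn <- connectedness(cc)
    expect_true(all(cn$pos >= 0))
    expect_true(all(cn$neg <= 0))
    ch <- cohesion(ab, cn)
    expect_true(all(ch$pos >= 0))
    expect_true(all(ch$neg <= 0))
    expect_true(all(ch$pos <= max(cn$pos) + 1e-12))
    expect_true(all(abs(ch$neg) <= max(abs(cn$neg)) + 1e-12))
  }
})

test_that("null-corrected correlations are deterministic under a seed", {
  ab <- random_relabund(8, 8, seed = 5)
  a <- null_corrected_correlations(ab, n_iter = 40, seed = 9)
  b <- null_corrected_correlations(ab, n_iter = 40, seed = 9)
  expect_identical(a, b)
  c2 <- null_corrected_correlations(ab, n_iter = 40, seed = 10)
  expect_false(identical(a, c2))
})

test_that("grouped cohesion estimates connectedness within groups", {
  b <- simulate_dataset(sim_config(n_taxa = 16, reps_per_level = 4,
                                   seq_depth = 800, module_size = 6,
                                   rng_seed = 6))
  rel <- to_relative_abundance(b$counts)
  res <- compute_cohesion(rel, b$metadata, group = "n_rate",
                          n_iter = 30, seed = 1)
  expect_equal(sort(unique(res$cohesion$n_rate)), sort(b$config$n_levels))
  expect_equal(nrow(res$cohesion), nrow(b$metadata))
  joint <- compute_cohesion(rel, n_iter = 30, seed = 1)
  expect_equal(nrow(joint$cohesion), nrow(b$metadata))
  expect_false("n_rate" %in% names(joint$cohesion))
})
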