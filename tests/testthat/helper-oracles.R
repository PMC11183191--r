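# Independent oracle implementations used to cross-check the package.
# Deliberately naive (loops, enumeration) and kept free of package code
# paths beyond trivial constructors.

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

brute_cor_matrix <- function(m, method = "spearman") {
  nt <- nrow(m)
  r <- diag(1, nt)
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      r[i, j] <- suppressWarnings(cor(m[i, ], m[j, ], method = method))
    }
  }
  r
}

bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o[m]] <- p[o[m]]
  for (i in (m - 1):1) {
    q[o[i]] <- min(q[o[i + 1]], p[o[i]] * m / i)
  }
  pmin(q, 1)
}

# adjacency-matrix graph helpers for topology oracles
brute_local_clustering <- function(adj) {
  n <- nrow(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    k <- length(nb)
    if (k < 2) { out[v] <- 0; next }
    links <- 0
    for (a in nb) for (b in nb) if (a < b && adj[a, b] > 0) links <- links + 1
    out[v] <- 2 * links / (k * (k - 1))
  }
  out
}

brute_avg_path_length <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  # largest connected component
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1
    comp[is.finite(d[v, ])] <- cid
  }
  big <- as.integer(names(which.max(table(comp))))
  idx <- which(comp == big)
  if (length(idx) < 2) return(0)
  vals <- d[idx, idx][upper.tri(d[idx, idx])]
  mean(vals)
}

# build a signed_network object directly from an edge data frame
make_network <- function(edges) {
  corr_like <- structure(list(), class = "cooccur_cor")
  edges$r <- if ("r" %in% names(edges)) edges$r else 0.9
  edges$q <- if ("q" %in% names(edges)) edges$q else 0.001
  edges$sign <- ifelse(edges$r > 0, "+", "-")
  edges$weight <- abs(edges$r)
  g <- igraph::graph_from_data_frame(
    edges[c("taxon_a", "taxon_b", "weight")], directed = FALSE)
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  nodes <- tibble::tibble(
    taxon_id = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    module = as.integer(igraph::membership(comm))
  )
  structure(list(edges = tibble::as_tibble(edges), nodes = nodes,
                 r_min = 0.6, alpha = 0.05, empty = FALSE),
            class = "signed_network")
}

edges_to_adj <- function(edges) {
  ids <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    adj[edges$taxon_a[i], edges$taxon_b[i]] <- 1
    adj[edges$taxon_b[i], edges$taxon_a[i]] <- 1
  }
  adj
}

loop_connectedness <- function(cmat) {
  nt <- nrow(cmat)
  pos <- neg <- numeric(nt)
  for (j in seq_len(nt)) {
    v <- cmat[j, -j]
    pos[j] <- if (any(v > 0)) mean(v[v > 0]) else 0
    neg[j] <- if (any(v < 0)) mean(v[v < 0]) else 0
  }
  list(pos = pos, neg = neg)
}

loop_cohesion <- function(ab, pos, neg) {
  ns <- ncol(ab)
  out_pos <- out_neg <- numeric(ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(nrow(ab))) {
      out_pos[i] <- out_pos[i] + ab[j, i] * pos[j]
      out_neg[i] <- out_neg[i] + ab[j, i] * neg[j]
    }
  }
  list(pos = out_pos, neg = out_neg)
}

# first principal component scores of z-scored columns via eigen()
eigen_pc1 <- function(x) {
  z <- scale(x)
  ev <- eigen(cov(z))
  as.numeric(z %*% ev$vectors[, 1])
}

# non-adjacent unordered pair count of a DAG given a parent->child edge list
count_nonadjacent <- function(vars, parent, child) {
  cnt <- 0
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (j <= i) next
    a <- vars[i]; b <- vars[j]
    adj <- any(parent == a & child == b) || any(parent == b & child == a)
    if (!adj) cnt <- cnt + 1
  }
  cnt
}
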