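#' Build a signed co-occurrence network from thresholded correlations
#'
#' An edge joins taxa j and k when `|r| >= r_min` and the BH q-value is
#' below `alpha`; its sign is the sign of r and its weight `|r|`. A node
#' is a taxon with at least one edge (isolated taxa are dropped). Module
#' membership comes from deterministic greedy modularity maximization on
#' the unsigned weighted graph.
#'
#' @param corr a [pairwise_correlation()] result.
#' @param r_min minimum absolute correlation for an edge, in (0, 1);
#'   default 0.6.
#' @param alpha FDR threshold on q-values; default 0.05.
#' @return an object of class `signed_network`: list with `edges`
#'   (tibble: taxon_a, taxon_b, r, q, sign, weight), `nodes` (tibble:
#'   taxon_id, degree, module), thresholds, and an `empty` flag. A
#'   zero-edge network is returned flagged, not as an error.
#' @export
build_network <- function(corr, r_min = 0.6, alpha = 0.05) {
  if (!inherits(corr, "cooccur_cor")) {
    ngn_abort("corr must come from pairwise_correlation()",
              "ngn_validate_error")
  }
  if (r_min <= 0 || alpha <= 0 || alpha >= 1) {
    ngn_abort("need r_min > 0 and alpha in (0, 1)", "ngn_config_error")
  }
  pairs <- tidy.cooccur_cor(corr)
  edges <- dplyr::filter(pairs, abs(.data$r) >= r_min, .data$q < alpha)
  edges <- dplyr::mutate(edges,
                         sign = ifelse(.data$r > 0, "+", "-"),
                         weight = abs(.data$r))
  edges <- dplyr::select(edges, "taxon_a", "taxon_b", "r", "q", "sign",
                         "weight")
  if (nrow(edges) == 0) {
    return(structure(list(
      edges = edges,
      nodes = tibble(taxon_id = character(), degree = integer(),
                     module = integer()),
      r_min = r_min, alpha = alpha, empty = TRUE
    ), class = "signed_network"))
  }
  g <- igraph::graph_from_data_frame(
    edges[c("taxon_a", "taxon_b", "weight")], directed = FALSE)
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  nodes <- tibble(
    taxon_id = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    module = as.integer(igraph::membership(comm))
  )
  nodes <- dplyr::arrange(nodes, .data$taxon_id)
  structure(list(edges = edges, nodes = nodes, r_min = r_min,
                 alpha = alpha, empty = FALSE),
            class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("<signed_network> %d nodes, %d edges (%d +, %d -)%s\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "+"),
              sum(x$edges$sign == "-"),
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[c("taxon_a", "taxon_b", "weight")], directed = FALSE,
    vertices = net$nodes$taxon_id)
}

#' The seven topology parameters of a signed network
#'
#' Computes node and edge counts, average degree (2E/N), graph density
#' (2E/(N(N-1))), mean local clustering (nodes of degree < 2 contribute
#' 0), modularity of the greedy partition on the unsigned weighted
#' graph, and mean shortest-path length (unweighted hops) over the
#' largest connected component. An empty network yields all zeros plus
#' an `empty` flag.
#'
#' @param net a [build_network()] result.
#' @return a one-row tibble with columns `n_nodes`, `n_edges`,
#'   `average_degree`, `graph_density`, `clustering_coefficient`,
#'   `modularity`, `average_path_length`, `empty`.
#' @export
topology <- function(net) {
  if (!inherits(net, "signed_network")) {
    ngn_abort("net must come from build_network()", "ngn_validate_error")
  }
  if (net$empty) {
    return(tibble(n_nodes = 0L, n_edges = 0L, average_degree = 0,
                  graph_density = 0, clustering_coefficient = 0,
                  modularity = 0, average_path_length = 0, empty = TRUE))
  }
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  local_cc <- igraph::transitivity(g, type = "localundirected",
                                   isolates = "zero")
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  q_mod <- igraph::modularity(g, igraph::membership(comm),
                              weights = igraph::E(g)$weight)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  apl <- if (igraph::vcount(sub) < 2) 0 else
    igraph::mean_distance(sub, weights = NA, directed = FALSE)
  tibble(
    n_nodes = as.integer(n), n_edges = as.integer(e),
    average_degree = 2 * e / n,
    graph_density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    clustering_coefficient = mean(local_cc),
    modularity = q_mod,
    average_path_length = apl,
    empty = FALSE
  )
}

topology_metrics <- c("n_nodes", "n_edges", "average_degree",
                      "graph_density", "clustering_coefficient",
                      "modularity", "average_path_length")

#' Network-complexity PC1 across a set of networks
#'
#' Z-standardizes the seven topology parameters across networks and
#' takes the first principal component as a single complexity score.
#' PC1 is oriented so that its loading on average degree is
#' non-negative (ties broken by the edge-count loading), making higher
#' scores mean more complex networks. Constant metric columns are
#' dropped with a note.
#'
#' @param summaries a data frame of [topology()] rows (>= 3 networks),
#'   optionally with a `network_id` column.
#' @return an object of class `complexity_pca`: list with `scores`
#'   (tibble: network_id, pc1), `loadings`, `var_explained`, and
#'   `dropped` metric names. [tidy()] returns the scores; [glance()]
#'   the variance explained.
#' @export
complexity_pc1 <- function(summaries) {
  if (nrow(summaries) < 3) {
    ngn_abort("need at least 3 networks for the complexity PCA",
              "ngn_validate_error")
  }
  ids <- if ("network_id" %in% names(summaries)) {
    as.character(summaries$network_id)
  } else {
    as.character(seq_len(nrow(summaries)))
  }
  m <- as.matrix(summaries[intersect(topology_metrics, names(summaries))])
  if (any(!is.finite(m))) {
    ngn_abort("topology metrics must be finite for PCA",
              "ngn_validate_error")
  }
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  keep <- sds > 0
  if (sum(keep) < 1) {
    ngn_abort("all topology metrics are constant across networks",
              "ngn_validate_error")
  }
  z <- scale(m[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  load1 <- pc$rotation[, 1L]
  orient <- orient_sign(load1, c("average_degree", "n_edges"))
  scores <- pc$x[, 1L] * orient
  loadings <- pc$rotation
  loadings[, 1L] <- loadings[, 1L] * orient
  structure(list(
    scores = tibble(network_id = ids, pc1 = as.numeric(scores)),
    loadings = loadings,
    var_explained = ve,
    dropped = dropped
  ), class = "complexity_pca")
}

# sign chosen so the loading on the first available anchor is >= 0
orient_sign <- function(loadings, anchors) {
  for (a in anchors) {
    if (a %in% names(loadings) && loadings[[a]] != 0) {
      return(if (loadings[[a]] < 0) -1 else 1)
    }
  }
  1
}

#' @export
print.complexity_pca <- function(x, ...) {
  cat(sprintf("<complexity_pca> %d networks, PC1 explains %.1f%%\n",
              nrow(x$scores), 100 * x$var_explained[1L]))
  if (length(x$dropped) > 0) {
    cat("  dropped constant metrics:", paste(x$dropped, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @rdname complexity_pc1
#' @param x a `complexity_pca` object.
#' @param ... unused.
#' @method tidy complexity_pca
#' @export
tidy.complexity_pca <- function(x, ...) x$scores

#' @rdname complexity_pc1
#' @method glance complexity_pca
#' @export
glance.complexity_pca <- function(x, ...) {
  tibble(n_networks = nrow(x$scores),
         pc1_var_explained = x$var_explained[1L],
         n_dropped_metrics = length(x$dropped))
}
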