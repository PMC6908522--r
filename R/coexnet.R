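## Coexpression networks: |Pearson| similarity, clustering-coefficient-
## guided threshold selection (compare the observed mean local clustering
## coefficient with the Erdos-Renyi expectation at the same density), and
## common connectivity patterns (CCPs) as edge-set intersections between
## two disease networks.

#' Construct a GeneNetwork
#'
#' @param nodes character node labels.
#' @param edges 2-column character matrix of endpoints (undirected).
#' @param weights numeric `|r|` per edge.
#' @param threshold the tau that produced the network (NA when not
#'   applicable).
#' @return an object of class `GeneNetwork` with canonical edges
#'   (lexicographic endpoint order, no self-loops, no duplicates).
#' @export
gene_network <- function(nodes, edges, weights = rep(NA_real_, nrow(edges)),
                         threshold = NA_real_) {
  edges <- matrix(as.character(edges), ncol = 2)
  if (nrow(edges)) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    self <- edges[, 1] == edges[, 2]
    edges <- edges[!self, , drop = FALSE]
    weights <- weights[!self]
    key <- paste(edges[, 1], edges[, 2], sep = "|")
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    weights <- weights[keep]
  }
  structure(list(nodes = sort(unique(as.character(nodes))), edges = edges,
                 weights = as.numeric(weights), threshold = threshold),
            class = "GeneNetwork")
}

#' @export
print.GeneNetwork <- function(x, ...) {
  cat(sprintf("GeneNetwork: %d nodes and %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (is.na(x$threshold)) "" else sprintf(" (tau = %.2f)", x$threshold)))
  invisible(x)
}

#' Convert a GeneNetwork to an igraph graph
#' @param network a `GeneNetwork`.
#' @return an undirected `igraph` graph with `weight` edge attributes.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$edges[, 1], to = network$edges[, 2],
               weight = network$weights, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
  g
}

#' Absolute-Pearson similarity matrix
#'
#' `|r_ij|` across all samples of the study, restricted to `gene_subset`
#' when given. Genes with zero variance are dropped with a warning;
#' requested genes absent from the study are reported in attribute
#' `missing_genes`.
#'
#' @param study an `ExpressionStudy` with at least 3 samples.
#' @param gene_subset optional character vector of genes to keep.
#' @return a symmetric numeric matrix of class `SimilarityMatrix` with
#'   unit diagonal.
#' @export
similarity_matrix <- function(study, gene_subset = NULL) {
  if (ncol(study$values) < 3)
    stop_network("similarity needs at least 3 samples (study '%s')", study$study_id)
  v <- study$values
  missing <- character(0)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(v))
    if (length(missing))
      warning(sprintf("%d requested genes absent from study '%s'",
                      length(missing), study$study_id))
    v <- v[intersect(gene_subset, rownames(v)), , drop = FALSE]
  }
  vars <- apply(v, 1, sd)
  if (any(vars == 0)) {
    warning(sprintf("dropping %d zero-variance genes", sum(vars == 0)))
    v <- v[vars > 0, , drop = FALSE]
  }
  r <- abs(cor(t(v)))
  diag(r) <- 1
  r <- (r + t(r)) / 2
  structure(r, class = c("SimilarityMatrix", "matrix", "array"),
            missing_genes = missing)
}

#' Mean local clustering coefficient
#'
#' Watts-Strogatz local coefficient
#' `2 * triangles(v) / (deg(v) * (deg(v) - 1))`, averaged over nodes of
#' degree at least 2; `0` when no such node exists.
#'
#' @param network a `GeneNetwork`.
#' @return scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(network) {
  if (!nrow(network$edges)) return(0)
  g <- as_igraph(network)
  local <- igraph::transitivity(g, type = "local", isolates = "NaN")
  local <- local[!is.nan(local)]   # NaN for degree < 2
  if (!length(local)) return(0)
  mean(local)
}

#' Expected clustering coefficient of a random graph
#'
#' For an Erdos-Renyi graph `G(N, p)` the expected local clustering
#' coefficient equals the edge density `p = 2E / (N (N - 1))`.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param n_edges number of edges.
#' @return scalar density in `[0, 1]`.
#' @export
expected_random_cc <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop_network("need at least 2 nodes")
  max_e <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_e)
    stop_network("%d edges exceed the %d possible on %d nodes",
                 n_edges, max_e, n_nodes)
  n_edges / max_e
}

#' Build a coexpression network at threshold tau
#'
#' Edges are gene pairs with `|r| >= tau` (closed rule, so `tau = 1`
#' keeps perfect correlations); nodes are edge endpoints — isolated
#' genes are excluded.
#'
#' @param sim a `SimilarityMatrix`.
#' @param tau threshold in `[0, 1]`.
#' @return a `GeneNetwork`.
#' @export
build_network <- function(sim, tau) {
  if (tau < 0 || tau > 1) stop_config("tau must lie in [0, 1]")
  lab <- rownames(sim)
  hit <- which(sim >= tau & upper.tri(sim), arr.ind = TRUE)
  edges <- cbind(lab[hit[, 1]], lab[hit[, 2]])
  gene_network(unique(c(edges)), edges, sim[hit], threshold = tau)
}

#' Scan thresholds and record clustering-coefficient excess
#'
#' For each tau on the grid, builds the network of pairs with
#' `|r| >= tau` and records active node and edge counts, the observed
#' clustering coefficient `C`, the random-graph expectation `C_o` at the
#' same size, and the excess `D = C - C_o`. Empty networks are recorded
#' with `C = C_o = 0`.
#'
#' @param sim a `SimilarityMatrix`.
#' @param grid numeric vector of thresholds (default 0.50 to 0.99 by
#'   0.01).
#' @return a data frame of class `ThresholdScan` with columns `tau`,
#'   `n_nodes`, `n_edges`, `C`, `C_o`, `D`.
#' @export
threshold_scan <- function(sim, grid = seq(0.50, 0.99, by = 0.01)) {
  rows <- lapply(grid, function(tau) {
    net <- build_network(sim, tau)
    n_nodes <- length(net$nodes); n_edges <- nrow(net$edges)
    C <- clustering_coefficient(net)
    C_o <- if (n_nodes >= 2) expected_random_cc(n_nodes, n_edges) else 0
    data.frame(tau = tau, n_nodes = n_nodes, n_edges = n_edges,
               C = C, C_o = C_o, D = C - C_o)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ThresholdScan", "data.frame")
  out
}

#' Select the network threshold from a scan
#'
#' The selected `tau*` is the smallest grid value that is a local
#' maximum of `D = C - C_o` within a window of `window` grid steps on
#' each side and whose network has at least `min_edges` edges. If no
#' local maximum qualifies, the global argmax of `D` subject to
#' `min_edges` is used; if no threshold reaches `min_edges`, an error
#' advises lowering it.
#'
#' @param scan a `ThresholdScan`.
#' @param window half-width in grid steps for the local-maximum test.
#' @param min_edges minimum edge count for an admissible network.
#' @return the selected threshold (scalar).
#' @export
select_threshold <- function(scan, window = 5, min_edges = 10) {
  if (!nrow(scan)) stop_network("empty threshold scan")
  D <- scan$D
  ok <- scan$n_edges >= min_edges
  if (!any(ok))
    stop_network("no threshold yields >= %d edges; lower min_edges", min_edges)
  for (i in seq_along(D)) {
    if (!ok[i]) next
    lo <- max(1, i - window); hi <- min(length(D), i + window)
    if (D[i] >= max(D[lo:hi])) return(scan$tau[i])
  }
  scan$tau[which(ok & D == max(D[ok]))[1]]
}

#' Common connectivity pattern (CCP) of two networks
#'
#' The CCP is the graph of edges present in both networks
#' (label-matched, undirected); its nodes are the endpoints of the
#' shared edges. Connected-component membership is attached as attribute
#' `components`.
#'
#' @param net_a,net_b `GeneNetwork` objects over comparable gene labels.
#' @return a `GeneNetwork` (possibly empty).
#' @export
ccp_intersection <- function(net_a, net_b) {
  ka <- edge_keys(net_a$edges[, 1], net_a$edges[, 2])
  kb <- edge_keys(net_b$edges[, 1], net_b$edges[, 2])
  shared <- intersect(ka, kb)
  if (!length(shared)) {
    out <- gene_network(character(0), matrix(character(0), 0, 2), numeric(0))
    attr(out, "components") <- integer(0)
    return(out)
  }
  idx <- match(shared, ka)
  edges <- net_a$edges[idx, , drop = FALSE]
  w <- pmin(net_a$weights[idx], net_b$weights[match(shared, kb)])
  out <- gene_network(unique(c(edges)), edges, w)
  comp <- igraph::components(as_igraph(out))
  attr(out, "components") <- comp$membership
  out
}

#' Rank network hubs by degree
#'
#' @param network a `GeneNetwork`.
#' @param top_k number of genes to return.
#' @return data frame (gene, degree), descending degree, ties broken
#'   lexicographically.
#' @export
hub_rank <- function(network, top_k = 10) {
  if (top_k <= 0) stop_config("top_k must be positive")
  deg <- table(factor(c(network$edges), levels = network$nodes))
  ord <- order(-as.integer(deg), names(deg))
  out <- data.frame(gene = names(deg)[ord], degree = as.integer(deg)[ord],
                    stringsAsFactors = FALSE)
  head(out, top_k)
}
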