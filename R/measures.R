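# Whole-network and per-node sociometric measures on confirmed binary
# networks: density, normalized degree/betweenness centrality, Freeman
# centralization, isolates.

check_binary_symmetric <- function(net, min_n = 2) {
  stopifnot(inherits(net, "ona_network"))
  m <- net$values
  if (anyNA(m)) stop("measures require a confirmed network without missing entries")
  if (!all(m %in% c(0, 1))) {
    stop("measures are defined on binary ties: binarize() the network first")
  }
  if (!isSymmetric(unname(m))) stop("measures require a symmetric network")
  if (nrow(m) < min_n) {
    stop(sprintf("measure undefined for n < %d (network has n = %d)",
                 min_n, nrow(m)))
  }
  m
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$values, mode = "undirected",
                                      diag = FALSE)
}

#' Network density
#'
#' The ratio of realized undirected ties to the number of possible ties
#' n(n-1)/2, as a percentage.
#'
#' @param net A confirmed binary `ona_network` with n >= 2.
#' @return Density in percent.
#' @export
density_pct <- function(net) {
  m <- check_binary_symmetric(net, min_n = 2)
  n <- nrow(m)
  100 * sum(m[upper.tri(m)]) / (n * (n - 1) / 2)
}

#' Normalized degree centrality
#'
#' A node's tie count divided by the n-1 possible alters, as a percentage.
#'
#' @param net A confirmed binary `ona_network` with n >= 2.
#' @return Named numeric vector (percent) over the nodes.
#' @export
degree_centrality <- function(net) {
  m <- check_binary_symmetric(net, min_n = 2)
  100 * rowSums(m) / (nrow(m) - 1)
}

#' Normalized betweenness centrality
#'
#' The share of geodesics (shortest paths) between other node pairs that
#' pass through a node, counting all geodesics per pair, normalized by the
#' (n-1)(n-2)/2 pairs and expressed as a percentage. Pairs in different
#' components contribute nothing.
#'
#' @param net A confirmed binary `ona_network` with n >= 3.
#' @return Named numeric vector (percent) over the nodes.
#' @export
betweenness_centrality <- function(net) {
  m <- check_binary_symmetric(net, min_n = 3)
  n <- nrow(m)
  g <- as_igraph(net)
  raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  stats::setNames(100 * raw / ((n - 1) * (n - 2) / 2), rownames(m))
}

# Freeman centralization: sum of (max - c_i) over nodes, for centrality
# fractions c_i in [0, 1], divided by the maximum the sum can attain (the
# star graph's value), as a percentage.
freeman_centralization <- function(fractions, max_sum) {
  100 * sum(max(fractions) - fractions) / max_sum
}

#' Freeman degree centralization
#'
#' How concentrated degree centrality is on the most central node: the sum
#' of differences from the maximum normalized degree, divided by its
#' largest possible value (n-2, attained by the star graph), in percent.
#'
#' @param net A confirmed binary `ona_network` with n >= 3.
#' @return Centralization in percent.
#' @export
degree_centralization <- function(net) {
  m <- check_binary_symmetric(net, min_n = 3)
  n <- nrow(m)
  freeman_centralization(rowSums(m) / (n - 1), n - 2)
}

#' Freeman betweenness centralization
#'
#' The centralization of normalized betweenness fractions; the star graph
#' attains 100% (maximum possible sum of differences n-1).
#'
#' @param net A confirmed binary `ona_network` with n >= 3.
#' @return Centralization in percent.
#' @export
betweenness_centralization <- function(net) {
  check_binary_symmetric(net, min_n = 3)
  n <- nrow(net$values)
  freeman_centralization(betweenness_centrality(net) / 100, n - 1)
}

#' Isolates of a network
#'
#' @param net A confirmed binary `ona_network`.
#' @return Character vector of org ids with degree 0, in node order.
#' @export
isolates <- function(net) {
  m <- check_binary_symmetric(net, min_n = 1)
  rownames(m)[rowSums(m) == 0]
}

#' Per-node measure table for one network
#'
#' @param net A confirmed binary `ona_network` with n >= 3.
#' @return Data.frame with `org_id`, `degree` and `betweenness` (percent,
#'   full precision).
#' @export
node_measures <- function(net) {
  data.frame(org_id = network_nodes(net),
             degree = unname(degree_centrality(net)),
             betweenness = unname(betweenness_centrality(net)),
             stringsAsFactors = FALSE)
}

#' Whole-network measure summary for one network
#'
#' @param net A confirmed binary `ona_network` with n >= 3.
#' @return List with `layer`, `n_nodes`, `density`,
#'   `degree_centralization`, `betweenness_centralization` (all percent)
#'   and `isolates` (character vector).
#' @export
network_measures <- function(net) {
  list(layer = net$layer,
       n_nodes = nrow(net$values),
       density = density_pct(net),
       degree_centralization = degree_centralization(net),
       betweenness_centralization = betweenness_centralization(net),
       isolates = isolates(net))
}
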