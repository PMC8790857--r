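# Multiplexity: the number of nutrition relation layers on which a dyad
# has a confirmed tie.

#' Stack confirmed binary layers into a multiplex network
#'
#' The multiplexity score of a dyad is the number of layers (at most 4:
#' policy, capacity, knowledge, implementation) with a confirmed tie — the
#' elementwise sum of the binary layer matrices.
#'
#' @param layers Named list of confirmed binary `ona_network`s on an
#'   identical node set, in canonical layer order (see
#'   [nutrition_layers()]). Names default to each network's layer.
#' @return An object of class `ona_multiplex`: list with `nodes`, `layers`
#'   (the input networks) and `scores` (symmetric integer matrix, values
#'   0..length(layers)).
#' @export
multiplexity_matrix <- function(layers) {
  stopifnot(length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    names(layers) <- vapply(layers, function(x) x$layer, character(1))
  }
  ref <- network_nodes(layers[[1]])
  for (k in seq_along(layers)) {
    net <- layers[[k]]
    stopifnot(inherits(net, "ona_network"))
    if (!all(net$values %in% c(0, 1))) {
      stop("layer '", names(layers)[k], "' is not binary: binarize() first")
    }
    nodes <- network_nodes(net)
    if (!identical(nodes, ref)) {
      extra <- setdiff(nodes, ref)
      miss <- setdiff(ref, nodes)
      stop("layer '", names(layers)[k], "' node set differs from '",
           names(layers)[1], "'",
           if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")),
           if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")))
    }
  }
  scores <- Reduce(`+`, lapply(layers, function(x) x$values))
  structure(list(nodes = ref, layers = layers, scores = scores),
            class = "ona_multiplex")
}

#' @export
print.ona_multiplex <- function(x, ...) {
  ut <- x$scores[upper.tri(x$scores)]
  cat(sprintf("ONA multiplex network: %d nodes, %d layers, %d tied dyads\n",
              length(x$nodes), length(x$layers), sum(ut > 0)))
  invisible(x)
}

#' Summarize a multiplex network
#'
#' @param mx An `ona_multiplex`.
#' @return List with `dyad_counts` (named integer vector: dyads at each
#'   score 1..K) and `node_summary` (data.frame: per-node number of
#'   multiplex ties, maximum and mean multiplexity over its ties; NA
#'   mean/max for nodes without ties).
#' @export
multiplex_summary <- function(mx) {
  stopifnot(inherits(mx, "ona_multiplex"))
  k <- length(mx$layers)
  ut <- mx$scores[upper.tri(mx$scores)]
  counts <- vapply(seq_len(k), function(s) sum(ut == s), integer(1))
  names(counts) <- as.character(seq_len(k))

  node_summary <- data.frame(
    org_id = mx$nodes,
    n_ties = apply(mx$scores, 1, function(r) sum(r > 0)),
    max_multiplexity = apply(mx$scores, 1, function(r) {
      if (any(r > 0)) max(r) else NA_integer_
    }),
    mean_multiplexity = apply(mx$scores, 1, function(r) {
      if (any(r > 0)) mean(r[r > 0]) else NA_real_
    }),
    stringsAsFactors = FALSE)
  rownames(node_summary) <- NULL
  list(dyad_counts = counts, node_summary = node_summary)
}

#' Write the multiplex edge list
#'
#' One row per dyad with score >= 1: `source`, `target`, `score`, plus one
#' 0/1 flag column per layer. Dyads with score 0 are absent.
#'
#' @param mx An `ona_multiplex`.
#' @param path Output path.
#' @param sep Field separator.
#' @return The edge-list data.frame, invisibly; written to `path` if given.
#' @export
multiplex_edgelist <- function(mx, path = NULL, sep = ",") {
  stopifnot(inherits(mx, "ona_multiplex"))
  idx <- which(mx$scores > 0 & upper.tri(mx$scores), arr.ind = TRUE)
  df <- data.frame(source = mx$nodes[idx[, 1]],
                   target = mx$nodes[idx[, 2]],
                   score = mx$scores[idx],
                   stringsAsFactors = FALSE)
  for (nm in names(mx$layers)) {
    df[[nm]] <- mx$layers[[nm]]$values[idx]
  }
  df <- df[order(df$source, df$target), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}
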