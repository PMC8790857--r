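# Measure reports shaped like the study's centrality table, and styled
# network plots.

#' Combined per-node measure report across networks
#'
#' One row per organization with normalized degree and betweenness columns
#' for each supplied network (conventionally the whole/overall network
#' followed by the four nutrition layers), percentages rounded to one
#' decimal. A summary block carries density and the two centralizations
#' per network at the same precision.
#'
#' @param nets Named list of confirmed binary `ona_network`s on the same
#'   node set. Networks named in `expected` but absent are filled with NA
#'   sentinel columns, with a warning.
#' @param expected Network names the report should cover (default: the
#'   names of `nets`).
#' @param path Optional output path; the node table and summary are
#'   written as delimited text separated by a blank line.
#' @param sep Field separator for `path`.
#' @return List with `nodes` (data.frame: org_id, then degree_<name> and
#'   betweenness_<name> columns) and `summary` (data.frame: network,
#'   n_nodes, density, degree_centralization, betweenness_centralization,
#'   n_isolates).
#' @export
measures_report <- function(nets, expected = names(nets), path = NULL,
                            sep = ",") {
  stopifnot(length(nets) >= 1, !is.null(names(nets)))
  missing_nets <- setdiff(expected, names(nets))
  if (length(missing_nets) > 0) {
    warning("no network supplied for: ", paste(missing_nets, collapse = ", "),
            "; filling with NA")
  }
  ids <- network_nodes(nets[[1]])
  for (nm in names(nets)) {
    if (!identical(network_nodes(nets[[nm]]), ids)) {
      stop("network '", nm, "' is not on the same node set as '",
           names(nets)[1], "'")
    }
  }

  nodes <- data.frame(org_id = ids, stringsAsFactors = FALSE)
  summary_rows <- list()
  for (nm in expected) {
    if (nm %in% names(nets)) {
      net <- nets[[nm]]
      nodes[[paste0("degree_", nm)]] <- round(unname(degree_centrality(net)), 1)
      nodes[[paste0("betweenness_", nm)]] <-
        round(unname(betweenness_centrality(net)), 1)
      nw <- network_measures(net)
      summary_rows[[nm]] <- data.frame(
        network = nm, n_nodes = nw$n_nodes,
        density = round(nw$density, 1),
        degree_centralization = round(nw$degree_centralization, 1),
        betweenness_centralization = round(nw$betweenness_centralization, 1),
        n_isolates = length(nw$isolates), stringsAsFactors = FALSE)
    } else {
      nodes[[paste0("degree_", nm)]] <- NA_real_
      nodes[[paste0("betweenness_", nm)]] <- NA_real_
      summary_rows[[nm]] <- data.frame(
        network = nm, n_nodes = NA_integer_, density = NA_real_,
        degree_centralization = NA_real_,
        betweenness_centralization = NA_real_, n_isolates = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.table(nodes, con, sep = sep, row.names = FALSE,
                       quote = FALSE)
    writeLines("", con)
    utils::write.table(summary, con, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  list(nodes = nodes, summary = summary)
}

#' Plot style for ONA networks
#'
#' Encodings follow the study's plotting conventions: node shape by the
#' number of countries of operation (bins 1-2, 3-5, 6-8), node colour by
#' organization type, node size by normalized betweenness centrality (with
#' a floor so isolates stay visible), edge colour by the edge value
#' (intensity level, frequency level, or multiplexity score).
#'
#' @param country_bins Upper bin edges for the country-count shape bins.
#' @param shapes igraph vertex shapes, one per bin.
#' @param type_palette Named colours per `org_type`.
#' @param edge_palette Colours indexed by edge value (1-based).
#' @param size_range Node size range (min = isolate floor, max).
#' @param seed Layout seed.
#' @return List of class `ona_plot_style`.
#' @export
plot_style <- function(country_bins = c(2, 5, 8),
                       shapes = c("circle", "square", "rectangle"),
                       type_palette = NULL,
                       edge_palette = NULL,
                       size_range = c(6, 20),
                       seed = 42L) {
  if (length(shapes) != length(country_bins)) {
    stop("need one shape per country bin")
  }
  if (is.null(type_palette)) {
    type_palette <- stats::setNames(
      grDevices::hcl.colors(length(org_types()), "Dark 3"), org_types())
  }
  if (is.null(edge_palette)) {
    edge_palette <- c("grey60", "#377EB8", "#4DAF4A", "#E41A1C")
  }
  structure(list(country_bins = country_bins, shapes = shapes,
                 type_palette = type_palette, edge_palette = edge_palette,
                 size_range = size_range, seed = as.integer(seed)),
            class = "ona_plot_style")
}

country_bin_labels <- function(bins) {
  lo <- c(1, utils::head(bins, -1) + 1)
  sprintf("%d-%d countries", lo, bins)
}

# Deterministic layout: Fruchterman-Reingold on the non-isolate subgraph,
# isolates lined up along the bottom margin.
ona_layout <- function(adj, seed) {
  n <- nrow(adj)
  deg <- rowSums(adj > 0)
  coords <- matrix(0, n, 2, dimnames = list(rownames(adj), c("x", "y")))
  core <- which(deg > 0)
  if (length(core) > 0) {
    g <- igraph::graph_from_adjacency_matrix(
      adj[core, core, drop = FALSE] > 0, mode = "undirected")
    xy <- with_seed(seed, function() igraph::layout_with_fr(g))
    xy <- igraph::norm_coords(xy, xmin = -1, xmax = 1, ymin = -0.8, ymax = 1)
    coords[core, ] <- xy
  }
  iso <- which(deg == 0)
  if (length(iso) > 0) {
    coords[iso, 1] <- seq(-1, 1, length.out = length(iso) + 2)[-c(1, length(iso) + 2)]
    coords[iso, 2] <- -1
  }
  coords
}

#' Plot a confirmed or multiplex network with the study's encodings
#'
#' @param x A confirmed `ona_network` (edge values colour-coded by level)
#'   or an `ona_multiplex` (edge values are multiplexity scores).
#' @param roster `ona_roster` supplying `org_type` and country counts for
#'   every plotted node.
#' @param style An `ona_plot_style`.
#' @param file Optional output path ending in `.png` or `.svg`; plots to
#'   the active device when NULL.
#' @param main Plot title.
#' @return Invisibly, a list with `layout` (coordinates), `edges` (edge
#'   data.frame with value classes), and `legend` (used shape, colour and
#'   edge categories). The input is never modified.
#' @export
plot_ona <- function(x, roster, style = plot_style(), file = NULL,
                     main = NULL) {
  stopifnot(inherits(roster, "ona_roster"), inherits(style, "ona_plot_style"))
  if (inherits(x, "ona_multiplex")) {
    adj <- x$scores
    value_labels <- paste(seq_along(x$layers), "layer(s)")
  } else if (inherits(x, "ona_network")) {
    if (x$directed) stop("plot a confirmed (symmetric) network")
    adj <- x$values
    lv <- scale_levels(layer_scale(x$layer))
    value_labels <- names(lv)[-1]
  } else {
    stop("x must be an ona_network or ona_multiplex")
  }
  ids <- rownames(adj)
  at <- match(ids, roster$org_id)
  if (anyNA(at)) {
    stop("nodes absent from roster: ", paste(ids[is.na(at)], collapse = ", "))
  }
  info <- roster[at, , drop = FALSE]

  bin <- findInterval(pmax(info$n_countries, 1), style$country_bins + 1) + 1
  bin <- pmin(bin, length(style$shapes))
  vshape <- style$shapes[bin]
  vcolor <- style$type_palette[info$org_type]

  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # node size by betweenness with an isolate-visible floor
  n <- nrow(adj)
  if (n >= 3) {
    bt <- igraph::betweenness(igraph::graph_from_adjacency_matrix(
      adj > 0, mode = "undirected"), directed = FALSE)
    bt <- 100 * bt / ((n - 1) * (n - 2) / 2)
  } else {
    bt <- rep(0, n)
  }
  smin <- style$size_range[1]; smax <- style$size_range[2]
  vsize <- if (max(bt) > 0) smin + (smax - smin) * bt / max(bt) else
    rep(smin, n)

  ev <- igraph::E(g)$weight
  ecol <- style$edge_palette[pmin(pmax(round(ev), 1),
                                  length(style$edge_palette))]
  coords <- ona_layout(adj, style$seed)

  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
      png = grDevices::png(file, width = 1600, height = 1200, res = 150),
      svg = grDevices::svg(file, width = 11, height = 8),
      stop("unsupported image format '", ext, "': use .png or .svg"))
    on.exit(grDevices::dev.off())
  }

  graphics::par(mar = c(1, 1, if (is.null(main)) 1 else 3, 1))
  igraph::plot.igraph(g, layout = coords, rescale = FALSE,
                      xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1),
                      vertex.shape = vshape, vertex.color = vcolor,
                      vertex.size = vsize, vertex.label = ids,
                      vertex.label.cex = 0.6,
                      vertex.label.color = "black",
                      edge.color = ecol, edge.width = 1.5, main = main)
  used_types <- sort(unique(info$org_type))
  used_values <- sort(unique(round(ev)))
  used_bins <- sort(unique(bin))
  graphics::legend("topleft", legend = used_types, bty = "n", cex = 0.7,
                   fill = style$type_palette[used_types],
                   title = "Organization type")
  if (length(used_values) > 0) {
    graphics::legend("bottomleft", bty = "n", cex = 0.7, lty = 1, lwd = 2,
                     col = style$edge_palette[used_values],
                     legend = value_labels[used_values],
                     title = "Tie level")
  }
  graphics::legend("topright",
                   legend = country_bin_labels(style$country_bins)[used_bins],
                   pch = c(21, 22, 22)[used_bins], bty = "n", cex = 0.7,
                   title = "Countries of operation")

  edge_df <- igraph::as_data_frame(g, what = "edges")
  invisible(list(layout = coords,
                 edges = edge_df,
                 legend = list(types = used_types,
                               edge_values = used_values,
                               edge_labels = value_labels[used_values],
                               country_bins = used_bins)))
}
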