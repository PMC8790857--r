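# End-to-end pipeline: read survey -> build -> confirm -> binarize ->
# measures -> multiplex -> reports and plots, with a run manifest.

#' Run the full ONA pipeline
#'
#' Reads a roster and long-format dyadic reports, builds a directed valued
#' network per layer, applies the confirmation rule (mutual
#' acknowledgement for the binary overall layer, minimum rule for ordinal
#' layers), binarizes at `threshold`, computes network and node measures,
#' stacks the nutrition layers into a multiplex network, and writes DL
#' matrices, measure tables, edge lists, plots and a JSON manifest into
#' `out_dir`.
#'
#' Every dropped report row, unconfirmable dyad and excluded
#' non-respondent is counted in the manifest: the confirmation step
#' discards data and the run record must say how much.
#'
#' @param roster_path Path to the roster file (see [read_roster()]).
#' @param reports_path Path to the reports file (see [read_reports()]).
#' @param out_dir Output directory, created if needed.
#' @param layers Layers to analyse (default: all present in the reports).
#' @param threshold Binarization threshold for ordinal layers.
#' @param node_policy `"respondents"` (default: non-respondents are
#'   excluded from confirmed networks) or `"all"` (kept as structural
#'   isolates).
#' @param plots Write network plots (PNG) for each analysed layer.
#' @param seed Seed for plot layouts.
#' @param sep Field separator of the input files.
#' @return Invisibly, a list with the confirmed networks, measure report,
#'   multiplex network, manifest and output paths.
#' @export
run_ona_pipeline <- function(roster_path, reports_path, out_dir,
                             layers = NULL, threshold = 1L,
                             node_policy = c("respondents", "all"),
                             plots = TRUE, seed = 42L, sep = ",") {
  node_policy <- match.arg(node_policy)
  roster <- read_roster(roster_path, sep = sep)
  reports <- read_reports(reports_path, roster, sep = sep)
  dropped <- attr(reports, "dropped")
  if (is.null(layers)) {
    layers <- intersect(relation_layers(), unique(reports$layer))
  }
  if (length(layers) == 0) stop("no recognizable layers in the reports")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  keep_nr <- node_policy == "all"
  confirmed <- list()
  binary <- list()
  unconfirmable <- integer(0)
  for (ly in layers) {
    directed <- build_directed(reports, ly, roster)
    conf <- confirm_network(directed, keep_nonrespondents = keep_nr)
    unconfirmable[ly] <- attr(conf, "unconfirmable_dyads")
    confirmed[[ly]] <- conf
    binary[[ly]] <- if (layer_scale(ly) == "binary") conf else
      binarize(conf, threshold)
    write_dl(directed, file.path(out_dir, sprintf("directed_%s.dl", ly)))
    write_dl(conf, file.path(out_dir, sprintf("confirmed_%s.dl", ly)))
    write_edgelist(conf, file.path(out_dir, sprintf("confirmed_%s.csv", ly)))
  }

  report <- measures_report(binary, path = file.path(out_dir, "measures.csv"))

  mx <- NULL
  mx_layers <- intersect(nutrition_layers(), names(binary))
  if (length(mx_layers) >= 2) {
    mx <- multiplexity_matrix(binary[mx_layers])
    multiplex_edgelist(mx, file.path(out_dir, "multiplex.csv"))
    msum <- multiplex_summary(mx)
    utils::write.table(
      data.frame(score = names(msum$dyad_counts),
                 n_dyads = as.integer(msum$dyad_counts)),
      file.path(out_dir, "multiplex_counts.csv"),
      sep = ",", row.names = FALSE, quote = FALSE)
  }

  plot_paths <- character(0)
  if (plots) {
    style <- plot_style(seed = seed)
    for (ly in layers) {
      p <- file.path(out_dir, sprintf("network_%s.png", ly))
      plot_ona(confirmed[[ly]], roster, style, file = p,
               main = sprintf("Confirmed %s network", ly))
      plot_paths[ly] <- p
    }
    if (!is.null(mx)) {
      p <- file.path(out_dir, "network_multiplex.png")
      plot_ona(mx, roster, style, file = p,
               main = "Multiplexity of nutrition working relationships")
      plot_paths["multiplex"] <- p
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("onasurvey")),
    inputs = list(roster = roster_path, reports = reports_path),
    config = list(layers = layers, threshold = threshold,
                  node_policy = node_policy, seed = seed),
    counts = list(
      organizations = nrow(roster),
      respondents = sum(roster$respondent),
      excluded_nonrespondents =
        if (keep_nr) 0L else sum(!roster$respondent),
      report_rows_accepted = nrow(reports),
      report_rows_dropped = nrow(dropped),
      unconfirmable_dyads = as.list(unconfirmable)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(roster = roster, confirmed = confirmed, binary = binary,
                 measures = report, multiplex = mx, manifest = manifest,
                 out_dir = out_dir, plots = plot_paths))
}
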