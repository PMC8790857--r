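# Synthetic survey generator: planted-structure sociometric data with
# ground truth, for validating the confirmation pipeline and its measures.

#' Specification for a synthetic dyadic survey
#'
#' Describes a multi-layer latent network and a reporting model from which
#' survey-shaped data are drawn. Defaults emulate the regional nutrition
#' study setting: 50 organizations across the field's type mix, a 14%
#' non-response rate (so ~43 respondents), an overall any-purpose layer
#' around 20% latent density, four sparse nutrition layers (latent
#' densities roughly 4-10%, knowledge densest), type homophily, two broker
#' organizations bridging types, and contact frequencies concentrated on
#' 'rarely'/'sometimes'.
#'
#' The discordance model captures why confirmation is needed: with
#' probability `discordance` a directed report deviates from the dyad's
#' latent value — half of that mass omits the report, half shifts it one
#' ordinal level down (never up).
#'
#' @param n_per_type Named integer vector: organizations per `org_type`.
#' @param layers Character vector of layers to generate.
#' @param p_in Named numeric: within-type tie probability per layer.
#' @param p_out Named numeric: between-type tie probability per layer.
#' @param brokers Character vector of org ids given cross-type tie
#'   probability `p_broker`; defaults to the first UN and first
#'   multilateral organization.
#' @param p_broker Tie probability for a cross-type pair touching a broker.
#' @param frequency_dist Probabilities over rarely..very_often given a tie.
#' @param intensity_dist Probabilities over communication..collaboration.
#' @param discordance Probability a directed report deviates from latent.
#' @param nonresponse Probability an organization returns no reports.
#' @param seed Master seed; all substreams derive from it.
#' @return A validated list of class `ona_synth_spec`.
#' @export
synthetic_spec <- function(
    n_per_type = c(UN = 9L, multilateral = 4L, bilateral = 5L, NGO = 10L,
                   "academic/research" = 5L, intergovernmental = 1L,
                   foundation = 5L, network = 11L),
    layers = relation_layers(),
    p_in = c(overall = 0.45, intensity = 0.45, policy = 0.22,
             capacity = 0.16, knowledge = 0.30, implementation = 0.18),
    p_out = c(overall = 0.16, intensity = 0.16, policy = 0.035,
              capacity = 0.025, knowledge = 0.06, implementation = 0.03),
    brokers = NULL,
    p_broker = 0.5,
    frequency_dist = c(rarely = 0.45, sometimes = 0.35, often = 0.15,
                       very_often = 0.05),
    intensity_dist = c(communication = 0.6, coordination = 0.3,
                       collaboration = 0.1),
    discordance = 0.15,
    nonresponse = 0.14,
    seed = 1L) {
  stopifnot(length(n_per_type) >= 1, all(n_per_type >= 0))
  bad_type <- setdiff(names(n_per_type), org_types())
  if (length(bad_type) > 0) {
    stop("unknown org_type in n_per_type: ", paste(bad_type, collapse = ", "))
  }
  layers <- match.arg(layers, relation_layers(), several.ok = TRUE)
  for (ly in layers) {
    if (is.na(p_in[ly]) || is.na(p_out[ly])) {
      stop("p_in and p_out must name every generated layer; missing: ", ly)
    }
  }
  probs <- c(p_in[layers], p_out[layers], p_broker, discordance, nonresponse)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  for (d in list(frequency_dist, intensity_dist)) {
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8) {
      stop("level distributions must be non-negative and sum to 1")
    }
  }
  if (!identical(names(frequency_dist),
                 names(scale_levels("frequency"))[-1])) {
    stop("frequency_dist must be named rarely, sometimes, often, very_often")
  }
  if (!identical(names(intensity_dist),
                 names(scale_levels("intensity"))[-1])) {
    stop("intensity_dist must be named communication, coordination, collaboration")
  }
  seed <- as.integer(seed)

  spec <- list(n_per_type = n_per_type, layers = layers, p_in = p_in,
               p_out = p_out, brokers = brokers, p_broker = p_broker,
               frequency_dist = frequency_dist,
               intensity_dist = intensity_dist, discordance = discordance,
               nonresponse = nonresponse, seed = seed)
  class(spec) <- "ona_synth_spec"
  spec
}

# Deterministic substream seeds from the master seed, kept within 32-bit
# integer range. Stage: 1 roster, 2 latent, 3 reports; layer indexed
# within stage.
substream_seed <- function(seed, stage, layer_index = 0L) {
  (as.integer(seed) + 97003L * as.integer(stage) +
     10007L * as.integer(layer_index)) %% 2147480009L
}

# Evaluate fn with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

type_prefixes <- c(UN = "UN", multilateral = "MUL", bilateral = "BIL",
                   NGO = "NGO", "academic/research" = "ACA",
                   intergovernmental = "IGO", foundation = "FDN",
                   network = "NET")

# Roster draw: ids per type, country coverage (2-8, most orgs in a handful
# of countries, a sizeable minority region-wide), respondent flags.
synth_roster <- function(spec) {
  types <- rep(names(spec$n_per_type), spec$n_per_type)
  ids <- unlist(lapply(names(spec$n_per_type), function(tp) {
    k <- spec$n_per_type[[tp]]
    if (k == 0) return(character(0))
    sprintf("%s%02d", type_prefixes[[tp]], seq_len(k))
  }), use.names = FALSE)
  with_seed(substream_seed(spec$seed, 1L), function() {
    n <- length(ids)
    n_countries <- sample(2:8, n, replace = TRUE,
                          prob = c(0.10, 0.15, 0.15, 0.15, 0.15, 0.10, 0.20))
    respondent <- stats::runif(n) >= spec$nonresponse
    df <- data.frame(org_id = ids, acronym = ids,
                     full_name = paste("Synthetic organization", ids),
                     org_type = types, countries = n_countries,
                     respondent = respondent, stringsAsFactors = FALSE)
    as_roster(df)
  })
}

#' Draw latent ground-truth networks
#'
#' Each layer is an independent undirected blockmodel draw over the
#' roster: a pair is tied with probability `p_in` (same type), `p_out`
#' (different types), or `p_broker` when the types differ and either
#' endpoint is a designated broker. Tied dyads receive an ordinal level
#' from the layer's conditional level distribution (binary layers get 1).
#' Deterministic given the spec's seed.
#'
#' @param spec An `ona_synth_spec`.
#' @return An object of class `ona_ground_truth`: list with `roster`,
#'   `latent` (named list of symmetric valued `ona_network`s), `brokers`
#'   and `spec`.
#' @export
generate_latent <- function(spec) {
  stopifnot(inherits(spec, "ona_synth_spec"))
  roster <- synth_roster(spec)
  ids <- roster$org_id
  n <- length(ids)
  types <- stats::setNames(roster$org_type, ids)
  brokers <- spec$brokers
  if (is.null(brokers)) {
    brokers <- c(ids[grepl("^UN", ids)][1], ids[grepl("^MUL", ids)][1])
    brokers <- brokers[!is.na(brokers)]
  }
  unknown <- setdiff(brokers, ids)
  if (length(unknown) > 0) {
    stop("broker id(s) not in the generated roster: ",
         paste(unknown, collapse = ", "))
  }

  same_type <- outer(types, types, `==`)
  is_broker <- ids %in% brokers
  broker_pair <- outer(is_broker, is_broker, `|`) & !same_type
  pair_prob <- function(ly) {
    p <- matrix(spec$p_out[[ly]], n, n)
    p[same_type] <- spec$p_in[[ly]]
    p[broker_pair] <- spec$p_broker
    p
  }

  latent <- list()
  for (k in seq_along(spec$layers)) {
    ly <- spec$layers[k]
    sc <- layer_scale(ly)
    latent[[ly]] <- with_seed(substream_seed(spec$seed, 2L, k), function() {
      p <- pair_prob(ly)
      m <- matrix(0, n, n, dimnames = list(ids, ids))
      ut <- which(upper.tri(m))
      tied <- ut[stats::runif(length(ut)) < p[ut]]
      if (length(tied) > 0) {
        if (sc == "binary") {
          m[tied] <- 1
        } else {
          dist <- if (sc == "frequency") spec$frequency_dist else
            spec$intensity_dist
          lv <- scale_levels(sc)[-1]
          m[tied] <- sample(unname(lv), length(tied), replace = TRUE,
                            prob = dist)
        }
        m[lower.tri(m)] <- t(m)[lower.tri(m)]
      }
      ona_network(m, layer = ly, directed = FALSE,
                  respondent = stats::setNames(roster$respondent, ids))
    })
  }
  structure(list(roster = roster, latent = latent, brokers = brokers,
                 spec = spec),
            class = "ona_ground_truth")
}

#' Emit directed survey reports from ground truth
#'
#' Every respondent reports each of its latent ties, independently per
#' direction and layer, perturbed by the discordance model: with
#' probability d/2 the report is omitted, with probability d/2 it is
#' shifted one ordinal level down (a level-1 tie shifted down vanishes).
#' Non-respondents emit nothing. Deterministic given the spec's seed; rows
#' are ordered by layer, source, target.
#'
#' @param gt An `ona_ground_truth` from [generate_latent()].
#' @return An `ona_reports` data.frame consumable by [build_directed()].
#' @export
emit_reports <- function(gt) {
  stopifnot(inherits(gt, "ona_ground_truth"))
  spec <- gt$spec
  roster <- gt$roster
  ids <- roster$org_id
  resp <- stats::setNames(roster$respondent, ids)

  pieces <- list()
  for (k in seq_along(spec$layers)) {
    ly <- spec$layers[k]
    m <- gt$latent[[ly]]$values
    pieces[[ly]] <- with_seed(substream_seed(spec$seed, 3L, k), function() {
      idx <- which(m > 0 & resp[row(m)], arr.ind = TRUE)
      if (nrow(idx) == 0) return(NULL)
      v <- m[idx]
      u <- stats::runif(nrow(idx))
      d <- spec$discordance
      v[u < d / 2] <- 0                       # omitted report
      shift <- u >= d / 2 & u < d             # one level under-report
      v[shift] <- v[shift] - 1
      keep <- v > 0
      if (!any(keep)) return(NULL)
      data.frame(source = ids[idx[keep, 1]], target = ids[idx[keep, 2]],
                 layer = ly, value = as.integer(v[keep]),
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(source = character(0), target = character(0),
                      layer = character(0), value = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(match(out$layer, relation_layers()), out$source,
                   out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(row = integer(0), reason = character(0),
                                     stringsAsFactors = FALSE)
  class(out) <- c("ona_reports", "data.frame")
  out
}

#' Generate a complete synthetic survey bundle on disk
#'
#' Writes `roster.csv`, `reports.csv` (textual Likert labels, as a real
#' survey export would carry) and one latent ground-truth DL matrix per
#' layer (`latent_<layer>.dl`) into `dir`.
#'
#' @param spec An `ona_synth_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the `ona_ground_truth`, the emitted
#'   reports and the written file paths.
#' @export
generate_survey <- function(spec, dir) {
  gt <- generate_latent(spec)
  reports <- emit_reports(gt)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  roster_path <- file.path(dir, "roster.csv")
  roster_out <- gt$roster
  names(roster_out)[names(roster_out) == "n_countries"] <- "countries"
  utils::write.table(roster_out, roster_path, sep = ",", row.names = FALSE,
                     quote = FALSE)

  reports_path <- file.path(dir, "reports.csv")
  reports_out <- as.data.frame(reports)
  reports_out$value <- mapply(function(v, ly) decode_value(v, ly),
                              reports_out$value, reports_out$layer)
  utils::write.table(reports_out, reports_path, sep = ",",
                     row.names = FALSE, quote = FALSE)

  latent_paths <- character(0)
  for (ly in names(gt$latent)) {
    p <- file.path(dir, sprintf("latent_%s.dl", ly))
    write_dl(gt$latent[[ly]], p)
    latent_paths[ly] <- p
  }
  invisible(list(ground_truth = gt, reports = reports,
                 paths = c(list(roster = roster_path, reports = reports_path),
                           as.list(latent_paths))))
}
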