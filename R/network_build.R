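# Building directed valued matrices from reports and applying the
# confirmation rule.

#' Build a directed valued network from dyadic reports
#'
#' Entry (i, j) holds i's reported value about j on the requested layer.
#' Dyads a respondent did not report are 0 (reported absence); rows of
#' non-respondents are `NA` (missing, not zero) — the survey distinguishes
#' non-response from a reported absence of a tie.
#'
#' @param reports An `ona_reports` data.frame (see [read_reports()]).
#' @param layer Layer name to extract.
#' @param roster The `ona_roster` defining the node set and order.
#' @return A directed `ona_network` with respondent flags attached.
#' @export
build_directed <- function(reports, layer, roster) {
  stopifnot(inherits(roster, "ona_roster"))
  layer <- match.arg(layer, relation_layers())
  ids <- roster$org_id
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  respondent <- stats::setNames(roster$respondent, ids)
  m[!respondent, ] <- NA
  diag(m) <- 0

  rows <- reports[reports$layer == layer, , drop = FALSE]
  if (nrow(rows) == 0 && nrow(reports) > 0) {
    warning("no reports for layer '", layer, "': returning an empty matrix")
  }
  if (nrow(rows) > 0) {
    from_nonresp <- !respondent[rows$source]
    if (any(from_nonresp)) {
      warning(sprintf(
        "dropped %d report(s) from organizations flagged as non-respondents",
        sum(from_nonresp)))
      rows <- rows[!from_nonresp, , drop = FALSE]
    }
    key <- paste(rows$source, rows$target)
    if (anyDuplicated(key)) {
      warning("duplicate directed reports for the same dyad/layer; keeping the maximum")
      # max is order-independent, and the later minimum rule is conservative
      agg <- tapply(rows$value, key, max)
      rows <- rows[!duplicated(key), , drop = FALSE]
      rows$value <- unname(agg[paste(rows$source, rows$target)])
    }
    m[cbind(rows$source, rows$target)] <- rows$value
  }
  ona_network(m, layer = layer, directed = TRUE, respondent = respondent)
}

# Shared core of the two confirmation rules. Dyads with a missing
# (non-respondent) side are unconfirmable: set to 0 and counted.
confirm_core <- function(net, combine, keep_nonrespondents) {
  stopifnot(inherits(net, "ona_network"))
  m <- net$values
  resp <- net$respondent
  conf <- combine(m, t(m))
  unconfirmable <- is.na(conf)
  diag(unconfirmable) <- FALSE
  n_unconf <- sum(unconfirmable[upper.tri(unconfirmable)])
  conf[unconfirmable] <- 0

  if (!keep_nonrespondents) {
    keep <- which(resp)
    conf <- conf[keep, keep, drop = FALSE]
    resp <- resp[keep]
  }
  out <- ona_network(conf, layer = net$layer, directed = FALSE,
                     respondent = resp, confirmed = TRUE)
  attr(out, "unconfirmable_dyads") <- n_unconf
  out
}

#' Confirm a binary layer by mutual acknowledgement
#'
#' A confirmed tie exists between i and j only when i reports a tie with j
#' AND j reports a tie with i. Dyads with a non-respondent on either side
#' are unconfirmable and recorded as 0; their count is attached as the
#' `unconfirmable_dyads` attribute.
#'
#' @param net A directed `ona_network`.
#' @param keep_nonrespondents Retain non-respondents as structural isolates
#'   (useful for plotting); by default they are excluded from the confirmed
#'   network.
#' @return A symmetric binary confirmed `ona_network`.
#' @export
confirm_binary <- function(net, keep_nonrespondents = FALSE) {
  confirm_core(net, function(a, b) (a > 0) * (b > 0), keep_nonrespondents)
}

#' Confirm an ordinal layer by the minimum rule
#'
#' For scales with multiple levels (frequency of contact, intensity) the
#' confirmed value of a dyad is the minimum of the two directed reports:
#' if A reports 'often' about B but B reports 'sometimes' about A, the
#' confirmed frequency is 'sometimes'. A zero on either side leaves the
#' dyad unconfirmed.
#'
#' @inheritParams confirm_binary
#' @return A symmetric ordinal confirmed `ona_network`.
#' @export
confirm_ordinal <- function(net, keep_nonrespondents = FALSE) {
  confirm_core(net, pmin, keep_nonrespondents)
}

#' Apply the confirmation rule appropriate to a layer
#'
#' Binary layers use mutual acknowledgement ([confirm_binary()]); ordinal
#' layers use the minimum rule ([confirm_ordinal()]).
#'
#' @inheritParams confirm_binary
#' @return A confirmed `ona_network`.
#' @export
confirm_network <- function(net, keep_nonrespondents = FALSE) {
  if (layer_scale(net$layer) == "binary") {
    confirm_binary(net, keep_nonrespondents)
  } else {
    confirm_ordinal(net, keep_nonrespondents)
  }
}

#' Binarize a confirmed ordinal network
#'
#' A tie exists where the confirmed value is at least `threshold`. The
#' default threshold of 1 keeps every confirmed tie (>= 'rarely' on the
#' frequency scale, >= 'communication' on the intensity scale).
#'
#' @param net A confirmed `ona_network`.
#' @param threshold Positive ordinal level within the layer's scale.
#' @return A binary confirmed `ona_network`.
#' @export
binarize <- function(net, threshold = 1L) {
  stopifnot(inherits(net, "ona_network"))
  if (threshold <= 0) {
    stop("threshold must be positive: 0 would declare every dyad tied")
  }
  if (threshold > layer_max(net$layer)) {
    stop(sprintf("threshold %s exceeds the maximum level (%d) of the '%s' scale",
                 threshold, layer_max(net$layer), net$layer))
  }
  m <- (net$values >= threshold) * 1
  ona_network(m, layer = net$layer, directed = net$directed,
              respondent = net$respondent, confirmed = net$confirmed)
}
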