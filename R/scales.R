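# Relation layers and ordinal response scales used by the dyadic survey.

#' Relation layers recognized by the pipeline
#'
#' The survey asks about an overall relationship (any purpose, binary), its
#' intensity (communication < coordination < collaboration), and four
#' nutrition working relationships rated on a five-point frequency scale.
#'
#' @return Character vector of layer names in canonical order.
#' @export
relation_layers <- function() {
  c("overall", "intensity", "policy", "capacity", "knowledge",
    "implementation")
}

#' The four nutrition working-relationship layers, in canonical order
#' @return Character vector of the four layer names.
#' @export
nutrition_layers <- function() {
  c("policy", "capacity", "knowledge", "implementation")
}

#' Organization type categories
#' @return Character vector of the closed category set for `org_type`.
#' @export
org_types <- function() {
  c("UN", "multilateral", "bilateral", "NGO", "academic/research",
    "intergovernmental", "foundation", "network")
}

#' The eight South Asian countries of operation
#' @return Character vector of country names.
#' @export
south_asia_countries <- function() {
  c("Afghanistan", "Bangladesh", "Bhutan", "India", "Maldives", "Nepal",
    "Pakistan", "Sri Lanka")
}

#' Response scale of a relation layer
#'
#' @param layer A layer name from [relation_layers()].
#' @return One of `"binary"`, `"intensity"`, `"frequency"`.
#' @export
layer_scale <- function(layer) {
  layer <- match.arg(layer, relation_layers())
  switch(layer,
    overall = "binary",
    intensity = "intensity",
    "frequency"
  )
}

#' Ordered levels of a response scale
#'
#' Integer codes are fixed: frequency runs not_at_all = 0 < rarely = 1 <
#' sometimes = 2 < often = 3 < very_often = 4; intensity runs none = 0 <
#' communication = 1 < coordination = 2 < collaboration = 3; binary is 0/1.
#'
#' @param scale One of `"binary"`, `"intensity"`, `"frequency"`.
#' @return Named integer vector mapping level labels to codes.
#' @export
scale_levels <- function(scale) {
  scale <- match.arg(scale, c("binary", "intensity", "frequency"))
  switch(scale,
    binary = c(no = 0L, yes = 1L),
    intensity = c(none = 0L, communication = 1L, coordination = 2L,
                  collaboration = 3L),
    frequency = c(not_at_all = 0L, rarely = 1L, sometimes = 2L, often = 3L,
                  very_often = 4L)
  )
}

#' Maximum code on a layer's scale
#' @param layer A layer name.
#' @return Integer.
#' @export
layer_max <- function(layer) {
  max(scale_levels(layer_scale(layer)))
}

# Normalize a level label: lowercase, spaces/hyphens to underscores.
normalize_label <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(x)))
}

#' Map survey responses to integer codes
#'
#' Textual labels are matched case-insensitively against the exact level
#' names of the layer's scale (spaces and hyphens are treated as
#' underscores); no fuzzy matching is attempted. Numeric strings are
#' accepted when they fall within the scale's range. Unmappable values
#' return `NA`.
#'
#' @param values Character or numeric vector of responses.
#' @param layer Layer name determining the scale.
#' @return Integer vector of codes, `NA` where the value is invalid.
#' @export
code_value <- function(values, layer) {
  lv <- scale_levels(layer_scale(layer))
  out <- rep(NA_integer_, length(values))
  chr <- normalize_label(as.character(values))
  hit <- match(chr, names(lv))
  out[!is.na(hit)] <- lv[hit[!is.na(hit)]]
  numlike <- is.na(hit) & grepl("^[0-9]+$", chr)
  nv <- suppressWarnings(as.integer(chr[numlike]))
  nv[!(nv %in% lv)] <- NA_integer_
  out[numlike] <- nv
  out
}

#' Label for an integer code on a layer's scale
#' @param codes Integer vector of codes.
#' @param layer Layer name.
#' @return Character vector of level labels.
#' @export
decode_value <- function(codes, layer) {
  lv <- scale_levels(layer_scale(layer))
  names(lv)[match(codes, lv)]
}
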