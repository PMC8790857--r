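# Input/output: roster and dyadic-report tables, UCINET DL full-matrix
# files, edge lists.

#' Read an organization roster
#'
#' The roster is a delimited text file with columns `org_id`, `acronym`,
#' `full_name`, `org_type`, `countries`, `respondent`. `countries` may be an
#' integer count 0-8 or a semicolon-separated list of South Asian country
#' names; `respondent` is logical (TRUE/FALSE, yes/no, 1/0). Organizations
#' are ordered by `org_id` unless `keep_order = TRUE`, so the node indexing
#' downstream is deterministic.
#'
#' @param path Path to the roster file.
#' @param sep Field separator (default `,`).
#' @param keep_order Keep the file's row order instead of sorting by
#'   `org_id`.
#' @return A data.frame of class `ona_roster` with columns `org_id`,
#'   `acronym`, `full_name`, `org_type`, `n_countries`, `respondent`.
#' @export
read_roster <- function(path, sep = ",", keep_order = FALSE) {
  if (!file.exists(path)) stop("roster file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  as_roster(df, keep_order = keep_order)
}

#' Build a roster from a data.frame
#'
#' @param df Data.frame with the roster columns (see [read_roster()]).
#' @param keep_order Keep row order instead of sorting by `org_id`.
#' @return An `ona_roster` data.frame.
#' @export
as_roster <- function(df, keep_order = FALSE) {
  required <- c("org_id", "acronym", "org_type", "respondent")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("roster is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"full_name" %in% names(df)) df$full_name <- df$acronym
  if (!"countries" %in% names(df)) df$countries <- NA

  df$org_id <- as.character(df$org_id)
  dup <- unique(df$org_id[duplicated(df$org_id)])
  if (length(dup) > 0) {
    stop("duplicate org_id in roster: ", paste(dup, collapse = ", "))
  }

  bad_type <- setdiff(unique(df$org_type), org_types())
  if (length(bad_type) > 0) {
    stop("unknown org_type in roster: ", paste(bad_type, collapse = ", "),
         " (valid: ", paste(org_types(), collapse = ", "), ")")
  }

  df$n_countries <- parse_countries(df$countries)
  df$respondent <- parse_logical(df$respondent)
  if (anyNA(df$respondent)) {
    stop("respondent column must be logical (TRUE/FALSE, yes/no, 1/0)")
  }

  keep <- c("org_id", "acronym", "full_name", "org_type", "n_countries",
            "respondent")
  out <- df[, keep, drop = FALSE]
  if (!keep_order && nrow(out) > 0) out <- out[order(out$org_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ona_roster", "data.frame")
  out
}

# countries: integer count, or semicolon-separated list of country names.
parse_countries <- function(x) {
  if (is.numeric(x)) {
    n <- as.integer(x)
  } else {
    x <- as.character(x)
    n <- rep(NA_integer_, length(x))
    numlike <- grepl("^\\s*[0-9]+\\s*$", x)
    n[numlike] <- as.integer(x[numlike])
    listlike <- !numlike & !is.na(x) & nzchar(trimws(x))
    for (i in which(listlike)) {
      parts <- trimws(strsplit(x[i], ";", fixed = TRUE)[[1]])
      parts <- parts[nzchar(parts)]
      bad <- setdiff(parts, south_asia_countries())
      if (length(bad) > 0) {
        stop("unknown country label(s): ", paste(bad, collapse = ", "))
      }
      n[i] <- length(unique(parts))
    }
    n[!numlike & !listlike] <- 0L
  }
  n[is.na(n)] <- 0L
  if (any(n < 0 | n > 8)) stop("countries count must be within 0..8")
  n
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[v %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' @export
print.ona_roster <- function(x, ...) {
  cat(sprintf("ONA roster: %d organizations (%d respondents)\n",
              nrow(x), sum(x$respondent)))
  NextMethod()
}

#' Read long-format dyadic survey reports
#'
#' The reports file has columns `source`, `target`, `layer`, `value`: one
#' row per directed survey answer. Likert labels are mapped to integer
#' codes via [code_value()]. Invalid rows (self-reports, org ids absent
#' from the roster, unknown layers, values outside the layer's scale) are
#' dropped with a warning and counted, or raise an error when
#' `strict = TRUE`; accepted plus dropped always equals the row total.
#'
#' @param path Path to the reports file.
#' @param roster An `ona_roster` the org ids must resolve in.
#' @param sep Field separator (default `,`).
#' @param strict Error on the first invalid row instead of dropping.
#' @return Data.frame of class `ona_reports` with columns `source`,
#'   `target`, `layer`, `value` (integer codes); attribute `dropped` is a
#'   data.frame (row, reason) of rejected input rows.
#' @export
read_reports <- function(path, roster, sep = ",", strict = FALSE) {
  if (!file.exists(path)) stop("reports file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  as_reports(df, roster, strict = strict)
}

#' Validate a data.frame of dyadic reports
#'
#' @inheritParams read_reports
#' @param df Data.frame with columns `source`, `target`, `layer`, `value`.
#' @return An `ona_reports` data.frame (see [read_reports()]).
#' @export
as_reports <- function(df, roster, strict = FALSE) {
  stopifnot(inherits(roster, "ona_roster"))
  required <- c("source", "target", "layer", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("reports table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(df)
  src <- as.character(df$source)
  tgt <- as.character(df$target)
  layer <- as.character(df$layer)
  reason <- rep(NA_character_, n)

  known <- roster$org_id
  reason[is.na(reason) & !(src %in% known)] <- "unknown source org_id"
  reason[is.na(reason) & !(tgt %in% known)] <- "unknown target org_id"
  reason[is.na(reason) & src == tgt] <- "self-report"
  reason[is.na(reason) & !(layer %in% relation_layers())] <- "unknown layer"

  value <- rep(NA_integer_, n)
  ok <- is.na(reason)
  for (ly in unique(layer[ok])) {
    sel <- ok & layer == ly
    value[sel] <- code_value(df$value[sel], ly)
  }
  reason[ok & is.na(value)] <- "value outside scale"

  bad <- which(!is.na(reason))
  if (strict && length(bad) > 0) {
    stop(sprintf("invalid report at row %d: %s", bad[1], reason[bad[1]]))
  }
  if (length(bad) > 0) {
    warning(sprintf("dropped %d invalid report row(s): %s", length(bad),
                    paste(sprintf("row %d (%s)", bad, reason[bad]),
                          collapse = "; ")))
  }

  keepers <- setdiff(seq_len(n), bad)
  out <- data.frame(source = src[keepers], target = tgt[keepers],
                    layer = layer[keepers], value = value[keepers],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(row = bad,
                                     reason = reason[bad],
                                     stringsAsFactors = FALSE)
  class(out) <- c("ona_reports", "data.frame")
  out
}

#' Construct a network object
#'
#' A thin container for a square valued matrix over an ordered node set.
#' Rows/columns are labelled by `org_id`; the diagonal must be zero.
#' Missing rows (non-respondents in a directed network) are `NA`.
#'
#' @param values Square numeric matrix with identical row/column names.
#' @param layer Layer name (see [relation_layers()]).
#' @param directed Is the matrix directed (pre-confirmation)?
#' @param respondent Named logical vector over the nodes.
#' @param confirmed Has the confirmation rule been applied?
#' @return An object of class `ona_network`.
#' @export
ona_network <- function(values, layer, directed = TRUE,
                        respondent = NULL, confirmed = FALSE) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("network matrix must carry node labels as dimnames")
  }
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column labels must agree")
  }
  if (any(diag(values) != 0, na.rm = TRUE)) stop("diagonal must be zero")
  layer <- match.arg(layer, relation_layers())
  if (is.null(respondent)) {
    respondent <- stats::setNames(rep(TRUE, nrow(values)), rownames(values))
  }
  stopifnot(identical(names(respondent), rownames(values)))
  structure(list(values = values, layer = layer, directed = directed,
                 respondent = respondent, confirmed = confirmed),
            class = "ona_network")
}

#' @export
print.ona_network <- function(x, ...) {
  kind <- if (x$confirmed) "confirmed" else if (x$directed) "directed" else
    "undirected"
  cat(sprintf("ONA network [%s, %s]: %d nodes, %d positive entries\n",
              x$layer, kind, nrow(x$values),
              sum(x$values > 0, na.rm = TRUE)))
  invisible(x)
}

#' Node labels of a network
#' @param net An `ona_network`.
#' @return Character vector of org ids in node order.
#' @export
network_nodes <- function(net) rownames(net$values)

#' Write a network as a UCINET DL full-matrix file
#'
#' Writes the `dl n=<n>` / `format = fullmatrix` / `labels embedded`
#' dialect: node labels appear as the first data row and lead each matrix
#' row. `NA` entries (non-respondent rows) are written as 0; use the
#' respondent flags to recover them.
#'
#' @param net An `ona_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dl <- function(net, path) {
  m <- net$values
  m[is.na(m)] <- 0
  labels <- rownames(m)
  if (any(grepl("[[:space:]]", labels))) {
    stop("DL labels may not contain whitespace: ",
         paste(labels[grepl("[[:space:]]", labels)], collapse = ", "))
  }
  lines <- c(sprintf("dl n=%d", nrow(m)),
             "format = fullmatrix",
             "labels embedded",
             "data:",
             paste(labels, collapse = " "),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(labels[i], format(m[i, ], trim = TRUE,
                                         scientific = FALSE)),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a UCINET DL full-matrix file
#'
#' Accepts the dialect written by [write_dl()]. `read_dl(write_dl(x))`
#' reproduces `x`'s values and labels exactly.
#'
#' @param path Path to the DL file.
#' @param layer Layer name to attach (default `"overall"`).
#' @param roster Optional `ona_roster`; when given, node labels must
#'   resolve in it and respondent flags are attached.
#' @return An `ona_network`.
#' @export
read_dl <- function(path, layer = "overall", roster = NULL) {
  if (!file.exists(path)) stop("DL file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- regmatches(lines[1], regexec("^\\s*dl\\s+n\\s*=\\s*([0-9]+)\\s*$",
                                      lines[1], ignore.case = TRUE))[[1]]
  if (length(hdr) != 2) {
    stop("malformed DL header at line 1: expected 'dl n=<n>', got '",
         lines[1], "'")
  }
  n <- as.integer(hdr[2])
  data_at <- which(grepl("^\\s*data\\s*:\\s*$", lines, ignore.case = TRUE))
  if (length(data_at) != 1) stop("malformed DL file: missing 'data:' line")
  pre <- tolower(gsub("\\s", "", lines[2:(data_at - 1)]))
  if (!any(grepl("format=fullmatrix", pre))) {
    stop("unsupported DL format: only 'format = fullmatrix' is read")
  }
  embedded <- any(grepl("labels(embedded|:embedded)", pre)) ||
    any(grepl("labelsembedded", pre))
  body <- lines[(data_at + 1):length(lines)]
  if (!embedded) {
    stop("unsupported DL dialect: only embedded labels are read")
  }
  if (length(body) != n + 1) {
    stop(sprintf("malformed DL body at line %d: expected %d rows after the label row, found %d",
                 data_at + 1, n, length(body) - 1))
  }
  labels <- strsplit(trimws(body[1]), "\\s+")[[1]]
  if (length(labels) != n) {
    stop(sprintf("malformed DL label row at line %d: %d labels for n=%d",
                 data_at + 1, length(labels), n))
  }
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(body[i + 1]), "\\s+")[[1]]
    if (length(parts) != n + 1 || parts[1] != labels[i]) {
      stop(sprintf("malformed DL matrix row at line %d", data_at + 1 + i))
    }
    m[i, ] <- as.numeric(parts[-1])
  }
  respondent <- NULL
  if (!is.null(roster)) {
    unknown <- setdiff(labels, roster$org_id)
    if (length(unknown) > 0) {
      stop("DL labels absent from roster: ", paste(unknown, collapse = ", "))
    }
    respondent <- stats::setNames(
      roster$respondent[match(labels, roster$org_id)], labels)
  }
  ona_network(m, layer = layer, directed = !isSymmetric(unname(m)),
              respondent = respondent)
}

#' Write a network as a plain edge list
#'
#' One row per positive entry: `source`, `target`, `layer`, `value`. For
#' symmetric (confirmed) networks only the upper triangle is written.
#'
#' @param net An `ona_network`.
#' @param path Output path.
#' @param sep Field separator.
#' @return The path, invisibly.
#' @export
write_edgelist <- function(net, path, sep = ",") {
  m <- net$values
  m[is.na(m)] <- 0
  idx <- which(m > 0, arr.ind = TRUE)
  if (!net$directed) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  df <- data.frame(source = rownames(m)[idx[, 1]],
                   target = colnames(m)[idx[, 2]],
                   layer = net$layer,
                   value = m[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
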