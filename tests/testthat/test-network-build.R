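test_that("directed matrices place each report at (source, target)", {
  roster <- toy_roster(3)
  rep1 <- as_reports(data.frame(source = "ORG01", target = "ORG02",
                                layer = "policy", value = "often"), roster)
  net <- build_directed(rep1, "policy", roster)
  expect_equal(sum(net$values != 0), 1)
  expect_equal(net$values["ORG01", "ORG02"], 3)

  # empty layer: zero matrix with a warning, all-respondent rows present
  expect_warning(z <- build_directed(rep1, "capacity", roster), "empty")
  expect_true(all(z$values == 0))
  expect_false(anyNA(z$values))
})

test_that("directed construction equals a naive per-row insertion oracle", {
  roster <- toy_roster(8)
  set.seed(23)
  src <- sample(roster$org_id, 20, replace = TRUE)
  tgt <- sample(roster$org_id, 20, replace = TRUE)
  keep <- src != tgt
  df <- data.frame(source = src[keep], target = tgt[keep],
                   layer = "knowledge",
                   value = sample(1:4, sum(keep), replace = TRUE),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$source, df$target)), ]
  net <- build_directed(as_reports(df, roster), "knowledge", roster)

  oracle <- matrix(0, 8, 8, dimnames = list(roster$org_id, roster$org_id))
  for (r in seq_len(nrow(df))) {
    oracle[df$source[r], df$target[r]] <- df$value[r]
  }
  expect_identical(net$values, oracle)
})

test_that("non-respondent rows are missing, not zero", {
  roster <- toy_roster(4, respondent = c(TRUE, TRUE, FALSE, TRUE))
  rep1 <- as_reports(data.frame(source = "ORG01", target = "ORG03",
                                layer = "policy", value = "often"), roster)
  net <- build_directed(rep1, "policy", roster)
  expect_true(all(is.na(net$values["ORG03", c(1, 2, 4)])))
  expect_equal(net$values["ORG03", "ORG03"], 0)
  expect_equal(net$values["ORG01", "ORG03"], 3)
})

test_that("binary confirmation requires mutual acknowledgement", {
  roster <- toy_roster(3)
  one_way <- as_reports(data.frame(source = "ORG01", target = "ORG02",
                                   layer = "overall", value = "yes"), roster)
  net <- confirm_binary(build_directed(one_way, "overall", roster))
  expect_true(all(net$values == 0))

  both <- as_reports(data.frame(source = c("ORG01", "ORG02"),
                                target = c("ORG02", "ORG01"),
                                layer = "overall", value = "yes"), roster)
  net <- confirm_binary(build_directed(both, "overall", roster))
  expect_equal(net$values["ORG01", "ORG02"], 1)
  expect_equal(net$values["ORG02", "ORG01"], 1)
})

test_that("binary confirmation equals the transpose-AND oracle", {
  set.seed(31)
  for (rep_i in 1:20) {
    m <- (rand_directed_matrix(9, max_level = 1, p = 0.5) > 0) * 1
    ids <- sprintf("N%d", 1:9)
    dimnames(m) <- list(ids, ids)
    net <- ona_network(m, layer = "overall")
    conf <- confirm_binary(net)
    expect_identical(unname(conf$values), unname((m > 0 & t(m) > 0) * 1))
  }
})

test_that("ordinal confirmation takes the dyad minimum", {
  roster <- toy_roster(3)
  # A reports 'often' about B; B reports 'sometimes' about A ->
  # confirmed frequency is 'sometimes'
  df <- data.frame(source = c("ORG01", "ORG02"),
                   target = c("ORG02", "ORG01"),
                   layer = "knowledge", value = c("often", "sometimes"),
                   stringsAsFactors = FALSE)
  conf <- confirm_ordinal(build_directed(as_reports(df, roster),
                                         "knowledge", roster))
  expect_equal(conf$values["ORG01", "ORG02"],
               scale_levels("frequency")[["sometimes"]])

  # a zero on either side leaves the dyad unconfirmed
  df$value <- c("very often", "not at all")
  conf <- confirm_ordinal(build_directed(as_reports(df, roster),
                                         "knowledge", roster))
  expect_equal(conf$values["ORG01", "ORG02"], 0)
})

test_that("ordinal confirmation equals the transpose-min oracle", {
  set.seed(37)
  for (rep_i in 1:20) {
    m <- rand_directed_matrix(10)
    ids <- sprintf("N%02d", 1:10)
    dimnames(m) <- list(ids, ids)
    conf <- confirm_ordinal(ona_network(m, layer = "capacity"))
    expect_identical(unname(conf$values), unname(pmin(m, t(m))))
  }
})

test_that("confirmation is idempotent, dominated, monotone and permutation-equivariant", {
  set.seed(41)
  ids <- sprintf("N%02d", 1:10)
  for (rep_i in 1:10) {
    m <- rand_directed_matrix(10)
    dimnames(m) <- list(ids, ids)
    net <- ona_network(m, layer = "policy")
    conf <- confirm_ordinal(net)

    # idempotence
    again <- confirm_ordinal(ona_network(conf$values, layer = "policy",
                                         directed = FALSE, confirmed = TRUE))
    expect_identical(again$values, conf$values)

    # dominance: confirmed value never exceeds either directed report
    pos <- which(conf$values > 0, arr.ind = TRUE)
    expect_true(all(conf$values[pos] <= m[pos]))
    expect_true(all(conf$values[pos] <= t(m)[pos]))

    # binary rule is the ordinal rule binarized at the existence threshold
    cb <- confirm_binary(net)
    expect_identical(cb$values, binarize(conf, 1L)$values)

    # raising one directed report never lowers any confirmed value
    m2 <- m
    off <- which(row(m2) != col(m2))
    bump <- sample(off, 1)
    m2[bump] <- min(m2[bump] + 1, 4)
    conf2 <- confirm_ordinal(ona_network(m2, layer = "policy"))
    expect_true(all(conf2$values >= conf$values))

    # permuting node labels commutes with confirmation
    perm <- sample(10)
    mp <- m[perm, perm]
    confp <- confirm_ordinal(ona_network(mp, layer = "policy"))
    expect_identical(confp$values, conf$values[perm, perm])
  }
})

test_that("dyads touching a non-respondent are unconfirmable and counted", {
  roster <- toy_roster(4, respondent = c(TRUE, TRUE, FALSE, TRUE))
  df <- data.frame(source = c("ORG01", "ORG02", "ORG01"),
                   target = c("ORG02", "ORG01", "ORG03"),
                   layer = "knowledge",
                   value = c("often", "often", "very often"),
                   stringsAsFactors = FALSE)
  net <- build_directed(as_reports(df, roster), "knowledge", roster)

  conf <- confirm_ordinal(net)
  # default: non-respondent dropped from the confirmed node set
  expect_identical(network_nodes(conf), c("ORG01", "ORG02", "ORG04"))
  expect_equal(conf$values["ORG01", "ORG02"], 3)
  # ORG03's three dyads could not be confirmed
  expect_equal(attr(conf, "unconfirmable_dyads"), 3)

  kept <- confirm_ordinal(net, keep_nonrespondents = TRUE)
  expect_identical(network_nodes(kept), roster$org_id)
  expect_true(all(kept$values["ORG03", ] == 0))
})

test_that("binarize thresholds correctly and rejects degenerate thresholds", {
  vals <- matrix(c(0, 0, 1, 2, 0, 0, 3, 4,
                   1, 3, 0, 0, 2, 4, 0, 0), 4, 4)
  vals <- pmin(vals, t(vals))
  ids <- c("A", "B", "C", "D")
  dimnames(vals) <- list(ids, ids)
  net <- ona_network(vals, layer = "knowledge", directed = FALSE,
                     confirmed = TRUE)
  expect_identical(unname(binarize(net, 1)$values), unname((vals >= 1) * 1))
  b4 <- binarize(net, 4)
  expect_equal(sum(b4$values), sum(vals == 4))
  expect_error(binarize(net, 0), "threshold")
  expect_error(binarize(net, 5), "exceeds")

  set.seed(43)
  m <- rand_ordinal_matrix(8)
  dimnames(m) <- rep(list(sprintf("N%d", 1:8)), 2)
  net <- ona_network(m, layer = "policy", directed = FALSE, confirmed = TRUE)
  expect_identical(unname(binarize(net, 2)$values), unname((m >= 2) * 1))
})
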