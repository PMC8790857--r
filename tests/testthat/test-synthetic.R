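test_that("spec validation rejects impossible parameters", {
  expect_error(synthetic_spec(discordance = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_spec(p_in = c(overall = 2), layers = "overall"),
               "\\[0, 1\\]")
  expect_error(synthetic_spec(frequency_dist = c(rarely = 0.5,
                                                 sometimes = 0.2,
                                                 often = 0.2,
                                                 very_often = 0.2)),
               "sum to 1")
  expect_error(synthetic_spec(layers = "policy",
                              p_in = c(overall = 0.5)), "missing")
  expect_error(synthetic_spec(n_per_type = c(guild = 5)), "unknown org_type")
})

test_that("degenerate probability corners behave as stated", {
  base <- list(n_per_type = c(UN = 4, NGO = 4), layers = "knowledge",
               nonresponse = 0, discordance = 0, seed = 5)
  # p = 0 everywhere: empty latent layer
  spec0 <- do.call(synthetic_spec, c(base, list(p_in = c(knowledge = 0),
                                                p_out = c(knowledge = 0),
                                                p_broker = 0)))
  gt0 <- generate_latent(spec0)
  expect_true(all(gt0$latent$knowledge$values == 0))
  expect_equal(nrow(emit_reports(gt0)), 0)

  # p = 1 with all frequency mass on 'sometimes': complete graph at level 2
  spec1 <- do.call(synthetic_spec, c(base, list(
    p_in = c(knowledge = 1), p_out = c(knowledge = 1), p_broker = 1,
    frequency_dist = c(rarely = 0, sometimes = 1, often = 0,
                       very_often = 0))))
  m <- generate_latent(spec1)$latent$knowledge$values
  expect_true(all(m[upper.tri(m)] == 2))

  # full nonresponse: nobody reports anything
  specnr <- synthetic_spec(n_per_type = c(UN = 4, NGO = 4),
                           layers = "knowledge",
                           p_in = c(knowledge = 0.5),
                           p_out = c(knowledge = 0.5),
                           nonresponse = 1, seed = 5)
  expect_equal(nrow(emit_reports(generate_latent(specnr))), 0)
})

test_that("identical spec and seed give byte-identical survey files", {
  spec <- synthetic_spec(seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_survey(spec, d1)
  generate_survey(spec, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  # and a different seed actually changes the draw
  d3 <- withr::local_tempdir()
  generate_survey(synthetic_spec(seed = 100), d3)
  expect_false(identical(readLines(file.path(d1, "reports.csv")),
                         readLines(file.path(d3, "reports.csv"))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_latent(synthetic_spec(seed = 7,
                                           n_per_type = c(UN = 3, NGO = 3),
                                           layers = "policy")))
  expect_identical(.Random.seed, before)
})

test_that("noise-free reports reproduce the latent truth through the pipeline", {
  spec <- synthetic_spec(discordance = 0, nonresponse = 0, seed = 17)
  gt <- generate_latent(spec)
  reports <- emit_reports(gt)
  for (ly in spec$layers) {
    conf <- confirm_network(build_directed(reports, ly, gt$roster))
    expect_identical(conf$values, gt$latent[[ly]]$values * 1.0)
  }
})

test_that("blockmodel tie rates hit their targets within Monte-Carlo error", {
  n_seeds <- 120
  p_in <- 0.3
  p_out <- 0.05
  types <- c(UN = 10, NGO = 10, network = 10, foundation = 10)
  win <- bet <- 0
  n_win_pairs <- n_bet_pairs <- 0
  for (s in seq_len(n_seeds)) {
    spec <- synthetic_spec(n_per_type = types, layers = "policy",
                           p_in = c(policy = p_in), p_out = c(policy = p_out),
                           p_broker = p_out, nonresponse = 0, seed = 1000 + s)
    gt <- generate_latent(spec)
    m <- gt$latent$policy$values > 0
    same <- outer(gt$roster$org_type, gt$roster$org_type, `==`)
    ut <- upper.tri(m)
    win <- win + sum(m[ut & same])
    n_win_pairs <- n_win_pairs + sum(ut & same)
    bet <- bet + sum(m[ut & !same])
    n_bet_pairs <- n_bet_pairs + sum(ut & !same)
  }
  se_in <- sqrt(p_in * (1 - p_in) / n_win_pairs)
  se_out <- sqrt(p_out * (1 - p_out) / n_bet_pairs)
  expect_lt(abs(win / n_win_pairs - p_in), 3 * se_in)
  expect_lt(abs(bet / n_bet_pairs - p_out), 3 * se_out)
})

test_that("discordance produces the expected rate of asymmetric dyads", {
  # all latent ties at 'sometimes' (level 2): each direction independently
  # stays (1-d), drops (d/2) or shifts down one (d/2), so a dyad's two
  # reports disagree with probability 2d - 3d^2/2
  d <- 0.2
  expected <- 1 - ((1 - d)^2 + 2 * (d / 2)^2)
  n_seeds <- 100
  asym <- total <- 0
  for (s in seq_len(n_seeds)) {
    spec <- synthetic_spec(
      n_per_type = c(UN = 12, NGO = 12), layers = "knowledge",
      p_in = c(knowledge = 0.4), p_out = c(knowledge = 0.4), p_broker = 0.4,
      frequency_dist = c(rarely = 0, sometimes = 1, often = 0,
                         very_often = 0),
      discordance = d, nonresponse = 0, seed = 2000 + s)
    gt <- generate_latent(spec)
    net <- build_directed(emit_reports(gt), "knowledge", gt$roster)
    m <- net$values
    latent <- gt$latent$knowledge$values
    ut <- upper.tri(latent) & latent > 0
    asym <- asym + sum((m != t(m))[ut])
    total <- total + sum(ut)
  }
  se <- sqrt(expected * (1 - expected) / total)
  expect_lt(abs(asym / total - expected), 3 * se)
})

test_that("confirmed density falls below directed-report density, more so with noise", {
  gaps <- vapply(c(0, 0.2, 0.4), function(d) {
    gap <- 0
    for (s in 1:30) {
      spec <- synthetic_spec(n_per_type = c(UN = 10, NGO = 10),
                             layers = "knowledge",
                             p_in = c(knowledge = 0.35),
                             p_out = c(knowledge = 0.1), p_broker = 0.1,
                             discordance = d, nonresponse = 0,
                             seed = 3000 + s)
      gt <- generate_latent(spec)
      net <- build_directed(emit_reports(gt), "knowledge", gt$roster)
      n <- nrow(net$values)
      directed_density <- sum(net$values > 0) / (n * (n - 1))
      conf <- binarize(confirm_ordinal(net), 1)
      gap <- gap + (directed_density - density_pct(conf) / 100)
    }
    gap / 30
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
  expect_equal(gaps[1], 0, tolerance = 1e-12)
})
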