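# Test fixtures and independent oracles. The betweenness oracle counts all
# geodesics by level-synchronous BFS from every source, independently of
# the package's implementation path.

net_from_matrix <- function(m, layer = "overall", ids = NULL) {
  n <- nrow(m)
  if (is.null(ids)) ids <- sprintf("ORG%02d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  ona_network(m, layer = layer, directed = FALSE, confirmed = TRUE)
}

star_net <- function(n) {
  m <- matrix(0, n, n)
  m[1, 2:n] <- 1
  m[2:n, 1] <- 1
  net_from_matrix(m)
}

complete_net <- function(n) {
  m <- matrix(1, n, n) - diag(n)
  net_from_matrix(m)
}

empty_net <- function(n) net_from_matrix(matrix(0, n, n))

cycle_net <- function(n) {
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    m[i, j] <- 1
    m[j, i] <- 1
  }
  net_from_matrix(m)
}

path_net <- function(n) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    m[i, i + 1] <- 1
    m[i + 1, i] <- 1
  }
  net_from_matrix(m)
}

# Erdos-Renyi draw as a symmetric binary matrix; caller controls the RNG.
rand_binary_matrix <- function(n, p = 0.3) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Random symmetric ordinal matrix (levels 0..max_level).
rand_ordinal_matrix <- function(n, max_level = 4, p = 0.4) {
  m <- matrix(0, n, n)
  ut <- which(upper.tri(m))
  tied <- ut[stats::runif(length(ut)) < p]
  m[tied] <- sample(seq_len(max_level), length(tied), replace = TRUE)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Random directed ordinal matrix with zero diagonal.
rand_directed_matrix <- function(n, max_level = 4, p = 0.4) {
  m <- matrix(sample(0:max_level, n * n, replace = TRUE,
                     prob = c(1 - p, rep(p / max_level, max_level))), n, n)
  diag(m) <- 0
  m
}

# Brute-force normalized betweenness (percent): for every pair (s, t) and
# intermediate i, geodesic counts sigma from BFS give the pair's share
# sigma_si * sigma_it / sigma_st when i lies on a shortest s-t path.
bf_betweenness <- function(m) {
  n <- nrow(m)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n)
    sg <- rep(0, n)
    d[s] <- 0
    sg[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(m[v, ] > 0)) {
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
          if (d[w] == d[v] + 1) sg[w] <- sg[w] + sg[v]
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
  }
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == i || t == i || is.infinite(dist[s, t])) next
        if (dist[s, i] + dist[i, t] == dist[s, t]) {
          b[i] <- b[i] + sigma[s, i] * sigma[i, t] / sigma[s, t]
        }
      }
    }
  }
  100 * b / ((n - 1) * (n - 2) / 2)
}

# Direct Freeman centralization from centrality fractions.
freeman_oracle <- function(fractions, max_sum) {
  100 * sum(max(fractions) - fractions) / max_sum
}

# Small deterministic roster for io tests.
toy_roster <- function(n = 5, respondent = rep(TRUE, n)) {
  ids <- sprintf("ORG%02d", seq_len(n))
  as_roster(data.frame(
    org_id = ids, acronym = ids, full_name = paste("Org", ids),
    org_type = rep(org_types(), length.out = n),
    countries = rep(2:8, length.out = n),
    respondent = respondent, stringsAsFactors = FALSE))
}
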