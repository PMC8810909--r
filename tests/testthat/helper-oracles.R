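# Independent brute-force oracles used across tests. These are
# deliberately naive O(n^2) / exhaustive implementations kept separate
# from the package's algorithms.

# exhaustive maximum independent set size of the conflict graph
# (pairs closer than min_dist conflict); n <= 15
oracle_mis_size <- function(x, y, min_dist) {
  n <- length(x)
  stopifnot(n <= 15L)
  conflict <- as.matrix(stats::dist(cbind(x, y))) < min_dist
  diag(conflict) <- FALSE
  adj_mask <- vapply(seq_len(n),
                     function(i) sum(2^(which(conflict[i, ]) - 1L)), 0)
  # subset DP over all 2^n vertex subsets: a set is independent iff
  # the set without its lowest vertex is independent and that vertex
  # has no conflict inside the remainder
  nmask <- 2^n
  ok <- logical(nmask); ok[1L] <- TRUE
  size <- integer(nmask)
  for (m in seq_len(nmask - 1L)) {
    low <- bitwAnd(m, -m)
    i <- as.integer(round(log2(low))) + 1L
    rest <- m - low
    ok[m + 1L] <- ok[rest + 1L] && bitwAnd(adj_mask[i], rest) == 0
    size[m + 1L] <- size[rest + 1L] + 1L
  }
  max(size[ok])
}

# dense inverse-distance weight matrix within a radius
oracle_weight_matrix <- function(x, y, radius) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  w <- ifelse(d > 0 & d <= radius, 1 / d, 0)
  diag(w) <- 0
  w
}

# double-loop autocovariate from a dense weight matrix
oracle_autocov <- function(values, W) {
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- sum(W[i, ])
    out[i] <- if (s > 0) sum(W[i, ] * values) / s else 0
  }
  out
}

# O(n^2) nearest-neighbor scan
oracle_max_nn <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  max(apply(d, 1L, min))
}

# Moran's I for one distance bin, direct formula over all ordered pairs
oracle_moran_bin <- function(values, x, y, lo, hi) {
  n <- length(values)
  z <- values - mean(values)
  d <- as.matrix(stats::dist(cbind(x, y)))
  w <- (d > lo & d <= hi) * 1
  diag(w) <- 0
  s0 <- sum(w)
  if (s0 == 0) return(NA_real_)
  (n / s0) * sum(w * outer(z, z)) / sum(z^2)
}

# tiny deterministic vote fixture with known truth
make_vote_fixture <- function(n_images, error_rate, seed,
                              n_voters = 10L) {
  cfg <- sim_config(n_voters = n_voters, vote_error_rate = error_rate,
                    seed = seed)
  set.seed(seed)
  obs <- data.frame(
    obs_id = sprintf("img%05d", seq_len(n_images)),
    x = runif(n_images, 0, 1000), y = runif(n_images, 0, 1000),
    color = sample(c("gray", "melanic", "other"), n_images, TRUE,
                   prob = c(0.8, 0.15, 0.05)),
    stringsAsFactors = FALSE)
  list(obs = obs, votes = simulate_votes(obs, cfg), config = cfg)
}

# small model frame with hand-set covariates for GLMM unit tests
make_toy_frame <- function(n_per_city = 200L, n_cities = 6L, seed = 1L,
                           beta = c(-1, 0.8), sigma = 0.5) {
  set.seed(seed)
  city <- rep(sprintf("c%02d", seq_len(n_cities)), each = n_per_city)
  x1 <- rnorm(n_per_city * n_cities)
  u <- rnorm(n_cities, 0, sigma)
  eta <- beta[1L] + beta[2L] * x1 + u[as.integer(factor(city))]
  data.frame(y = rbinom(length(eta), 1L, plogis(eta)),
             x1 = x1, city_id = city, stringsAsFactors = FALSE)
}
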