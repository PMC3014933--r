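mk_matrix <- function(counts, n, types = NULL, include_self = FALSE) {
  K <- nrow(counts)
  if (is.null(types)) types <- LETTERS[seq_len(K)]
  dimnames(counts) <- list(inserted = types, host = types)
  tintr:::new_tint_matrix(types, matrix(as.integer(counts), K, K,
                                        dimnames = dimnames(counts)),
                          stats::setNames(as.integer(n), types), include_self)
}

test_that("the accumulation curve has Gaussian-CDF shape and limits", {
  expect_equal(tint_eta(3.2, peak = 3.2, sigma = 1.5, n = 1000), 500)
  expect_equal(tint_eta(1e9, peak = 0, sigma = 2, n = 750), 750)
  expect_equal(tint_eta(4.7, peak = 3.2, sigma = 1.5, n = 1000),
               1000 * pnorm(1))
  tt <- seq(-5, 5, length.out = 101)
  expect_true(all(diff(tint_eta(tt, 0, 1, 100)) >= 0))
})

test_that("target probabilities are normalized and symmetric", {
  set.seed(41)
  for (rep in 1:20) {
    K <- sample(2:6, 1)
    peak <- rnorm(K, 0, 3); sigma <- runif(K, 0.3, 3); n <- runif(K, 50, 5000)
    q <- insertion_probability(peak, sigma, n)
    expect_lt(max(abs(rowSums(q) - 1)), 1e-12)
    q2 <- insertion_probability(peak, sigma, n, exclude_self_target = TRUE)
    expect_lt(max(abs(rowSums(q2) - 1)), 1e-12)
    expect_true(all(diag(q2) == 0))
  }
  # permutation equivariance: relabeling types permutes q accordingly
  peak <- c(-1, 0.2, 1.4); sigma <- c(0.7, 1.1, 0.5); n <- c(300, 120, 900)
  q <- insertion_probability(peak, sigma, n)
  perm <- c(3, 1, 2)
  expect_equal(insertion_probability(peak[perm], sigma[perm], n[perm]),
               q[perm, perm])
  # two identical types split targets evenly including self
  qq <- insertion_probability(c(0, 0), c(1, 1), c(100, 100))
  expect_equal(unname(qq), matrix(0.5, 2, 2), tolerance = 1e-12)
})

test_that("closed-form target probabilities match numerical quadrature", {
  set.seed(97)
  for (rep in 1:8) {
    K <- sample(2:5, 1)
    peak <- rnorm(K, 0, 2); sigma <- runif(K, 0.4, 2); n <- runif(K, 100, 2000)
    expect_equal(insertion_probability(peak, sigma, n),
                 oracle_q(peak, sigma, n), tolerance = 1e-7)
    expect_equal(insertion_probability(peak, sigma, n, exclude_self_target = TRUE),
                 oracle_q(peak, sigma, n, exclude_self = TRUE), tolerance = 1e-7)
  }
})

test_that("extreme separations stay normalized; degenerate input raises the guard", {
  # log-space evaluation keeps even astronomically separated types normalized
  q <- insertion_probability(c(0, 1e6), c(1e-3, 1e-3), c(10, 10),
                             exclude_self_target = TRUE)
  expect_lt(max(abs(rowSums(q) - 1)), 1e-12)
  # a truly degenerate row (all target weights identically zero) is an error
  expect_error(insertion_probability(c(0, Inf), c(1, 1), c(10, 10),
                                     exclude_self_target = TRUE),
               "rescale", class = "tint_numeric_error")
})

test_that("log-likelihood matches a naive per-event product", {
  counts <- matrix(c(0, 5, 2,
                     1, 0, 7,
                     3, 4, 0), 3, 3, byrow = TRUE)
  m <- mk_matrix(counts, n = c(400, 900, 250))
  peak <- c(-1, 0.5, 2); sigma <- c(0.4, 0.9, 0.25)
  naive <- 0
  q <- oracle_q(peak, sigma, c(400, 900, 250))
  for (i in 1:3) for (j in 1:3) if (i != j)
    for (e in seq_len(counts[i, j])) naive <- naive + log(q[i, j])
  expect_equal(tint_loglik(m, peak, sigma), naive, tolerance = 1e-6)
  # all-zero matrix has zero log-likelihood
  z <- mk_matrix(matrix(0, 2, 2), n = c(10, 10))
  expect_identical(tint_loglik(z, c(0, 1), c(1, 1)), 0)
})

test_that("the likelihood is invariant under a common shift of all peaks", {
  counts <- matrix(rpois(16, 4), 4, 4); diag(counts) <- 0
  m <- mk_matrix(counts, n = c(100, 200, 300, 400))
  peak <- c(-2, -0.5, 1, 2.2); sigma <- rep(1, 4)
  l0 <- tint_loglik(m, peak, sigma)
  for (shift in c(-7, 0.3, 12))
    expect_equal(tint_loglik(m, peak + shift, sigma), l0, tolerance = 1e-9)
})

test_that("an asymmetric two-type matrix forces the insertion direction", {
  m <- mk_matrix(matrix(c(0, 10, 0, 0), 2, 2, byrow = TRUE), n = c(500, 500))
  est <- fit_activity(m, seed = 2)
  tA <- est$peak[est$type == "A"]; tB <- est$peak[est$type == "B"]
  expect_gt(tA, tB)  # A inserted into B, so B must predate A
  expect_identical(est$type[1], "B")  # sorted oldest first
})

test_that("a symmetric two-type matrix gives coincident peaks", {
  m <- mk_matrix(matrix(c(0, 6, 6, 0), 2, 2), n = c(400, 400))
  est <- fit_activity(m, seed = 3)
  expect_lt(abs(diff(est$peak)), 1e-4)
})

test_that("intervals are centered, nested, and use the normal quantiles", {
  sim <- simulate_tints(small_sim_config(seed = 13))
  m <- filter_types(build_tint_matrix(detect_tints(sim$hits),
                                      group_elements(sim$hits)))
  est <- fit_activity(m, seed = 1)
  expect_equal(est$hi75 - est$lo75, 2 * 1.150349 * est$sigma, tolerance = 1e-6)
  expect_equal(est$hi95 - est$lo95, 2 * 1.959964 * est$sigma, tolerance = 1e-6)
  expect_equal(est$hi99 - est$lo99, 2 * 2.575829 * est$sigma, tolerance = 1e-6)
  expect_true(all(est$lo99 < est$lo95 & est$lo95 < est$lo75 &
                    est$hi75 < est$hi95 & est$hi95 < est$hi99))
  expect_equal((est$lo75 + est$hi75) / 2, est$peak)
  # gauge: copy-number-weighted center at the origin
  expect_lt(abs(sum(est$peak * est$copy_number)), 1e-6 * sum(est$copy_number))
  expect_true(all(est$normalized_peak >= 0 & est$normalized_peak <= 1))
  expect_false(is.unsorted(est$peak))
})

test_that("the optimizer reaches the dense grid-search optimum on 3-type problems", {
  set.seed(55)
  for (rep in 1:2) {
    n <- c(300, 500, 400)
    true_peak <- sort(rnorm(3, 0, 1.5))
    q <- insertion_probability(true_peak, n / max(n), n)
    counts <- round(q * 150); diag(counts) <- 0
    m <- mk_matrix(counts, n)
    est <- fit_activity(m, seed = rep, restarts = 6)
    ll_fit <- attr(est, "log_lik")
    sigma <- n / max(n)
    grid <- seq(-4, 4, length.out = 120)
    best_grid <- -Inf
    for (t1 in grid) for (t2 in grid) {
      t3 <- -(n[1] * t1 + n[2] * t2) / n[3]
      best_grid <- max(best_grid, tint_loglik(m, c(t1, t2, t3), sigma))
    }
    expect_gte(ll_fit, best_grid - 1e-6)
  }
})

test_that("fits on simulated matrices recover the generating order", {
  sim <- simulate_tints(small_sim_config(seed = 31))
  m <- filter_types(build_tint_matrix(detect_tints(sim$hits),
                                      group_elements(sim$hits)))
  est <- fit_activity(m, seed = 1)
  expect_identical(est$type, c("AluJo", "AluSx", "AluY"))
})

test_that("likelihood at the generating parameters beats single-coordinate perturbations", {
  cfg <- small_sim_config(seed = 61)
  sim <- simulate_tints(cfg)
  m <- build_tint_matrix(detect_tints(sim$hits), group_elements(sim$hits),
                         types = cfg$types$name)
  peak <- cfg$types$peak; sigma <- cfg$types$sigma
  w <- cfg$types$copy_number * cfg$types$consensus_length
  l0 <- tint_loglik(m, peak, sigma, weights = w)
  deltas <- numeric(0)
  for (j in seq_along(peak)) for (s in c(-0.5, 0.5)) {
    p2 <- peak; p2[j] <- p2[j] + s * sigma[j]
    deltas <- c(deltas, tint_loglik(m, p2, sigma, weights = w) - l0)
  }
  expect_lt(mean(deltas), 0)
})

test_that("fitting fewer than two subtypes is an error", {
  m <- mk_matrix(matrix(0L, 1, 1), n = 10)
  expect_error(fit_activity(m), class = "tint_data_error")
})

test_that("activity tables round-trip through serialization with metadata", {
  m <- mk_matrix(matrix(c(0, 8, 3, 0), 2, 2, byrow = TRUE), n = c(300, 200))
  est <- fit_activity(m, seed = 9, restarts = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_activity(est, f)
  back <- read_activity(f)
  expect_equal(back$peak, est$peak, tolerance = 1e-9)
  expect_identical(attr(back, "seed"), 9L)
  expect_equal(attr(back, "log_lik"), attr(est, "log_lik"), tolerance = 1e-9)
})
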