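test_that("cell-type labels follow the abundance vector", {
  expect_equal(sample_cell_labels(1, 5, seed = 1), rep(1L, 5))

  n <- 20000
  lab <- sample_cell_labels(c(0.5, 0.5), n, seed = 2)
  expect_lt(abs(sum(lab == 1) - n / 2), 4 * sqrt(n * 0.25))

  n <- 100000
  p <- c(0.2, 0.3, 0.5)
  freq <- tabulate(sample_cell_labels(p, n, seed = 3), 3) / n
  expect_true(all(abs(freq - p) < 0.01))
})

test_that("invalid abundance vectors are rejected with the offending index", {
  expect_error(sample_cell_labels(c(0.5, -0.1, 0.6), 10), "index 2")
  expect_error(sample_cell_labels(c(0, 0), 10), "sum")
  expect_error(sample_cell_labels(c(0.2, 0.2), 10), "sum to 1")
})

test_that("latent draws respect degenerate and mixture structure", {
  g0 <- cell_type_gmm(1, matrix(c(2, 3), 1), list(matrix(0, 2, 2)))
  X <- sample_latent_expressions(g0, 4, seed = 1)
  expect_equal(unname(X), matrix(c(2, 3), 4, 2, byrow = TRUE))

  g1 <- cell_type_gmm(c(1, 0), rbind(c(0, 0), c(50, 50)),
                      list(diag(0.5, 2), diag(0.5, 2)))
  X <- sample_latent_expressions(g1, 1000, seed = 2)
  expect_true(all(abs(colMeans(X)) < 4 * sqrt(0.5 / 1000)))

  g2 <- cell_type_gmm(c(0.5, 0.5), rbind(-5, 5),
                      list(matrix(0.01), matrix(0.01)))
  X <- sample_latent_expressions(g2, 10000, seed = 3)
  expect_lt(abs(mean(X > 0) - 0.5), 0.02)
})

test_that("truncation clips negatives to exactly zero and nothing else", {
  expect_equal(truncate_below_zero(rbind(c(-1, 2), c(0.5, -0.3))),
               rbind(c(0, 2), c(0.5, 0)))
  x <- matrix(abs(rnorm(20)), 4)
  expect_identical(truncate_below_zero(x), x)
  expect_equal(truncate_below_zero(-x), matrix(0, 4, 5))
})

test_that("machine noise is zero-mean with the requested scale", {
  x <- matrix(rnorm(100), 10)
  expect_identical(add_machine_noise(x, noise_model(0), seed = 1), x)

  z <- matrix(0, 10000, 1)
  y <- add_machine_noise(z, noise_model(0.1), seed = 2)
  expect_lt(abs(sd(y) - 0.1), 0.005)

  y2 <- add_machine_noise(z, noise_model(0.5), seed = 3)
  expect_lt(abs(mean(y2)), 4 * 0.5 / sqrt(10000))
})

test_that("assembly with all effects off reproduces the degenerate mixture", {
  g <- cell_type_gmm(1, matrix(c(1, 2), 1), list(matrix(0, 2, 2)))
  m <- reference_model(list(only = g), 1)
  sim <- simulate_cells(m, 50, seed = 1)
  expect_equal(unname(as.matrix(sim[, 1:2])),
               matrix(c(1, 2), 50, 2, byrow = TRUE))
  expect_equal(sim$cell_type, rep("only", 50))
})

test_that("batch interactions shift per-type means additively", {
  M <- 4
  g1 <- cell_type_gmm(1, matrix(10, 1, M), list(diag(0.2, M)))
  g2 <- cell_type_gmm(1, matrix(14, 1, M), list(diag(0.2, M)))
  m <- reference_model(list(A = g1, B = g2), c(0.5, 0.5))
  be <- batch_effects(2, 2, M, sigma_psi = 0.3, sigma = 0.5, seed = 7)
  n <- 40000
  base <- simulate_cells(m, n, seed = 11)
  wb <- simulate_cells(m, c(n, n), batch_effects = be, seed = 11)
  for (b in 1:2) for (p in 1:2) {
    tp <- c("A", "B")[p]
    got <- colMeans(as.matrix(wb[wb$batch == b & wb$cell_type == tp, 1:M])) -
      colMeans(as.matrix(base[base$cell_type == tp, 1:M]))
    want <- be$psi[b] + be$Psi[b, p, ]
    se <- sqrt(0.2) * sqrt(1 / (n / 2) + 1 / (n / 2))
    expect_true(all(abs(got - want) < 4 * se))
  }
})

test_that("a linear temporal ramp is recovered by regression on acquisition order", {
  M <- 3
  g <- cell_type_gmm(1, matrix(5, 1, M), list(diag(0.04, M)))
  m <- reference_model(list(A = g), 1)
  tf <- temporal_polynomial(c(0, 1), end_sd = 1, seed = 5)  # f(t) = e * t
  e <- tf$params$end
  n <- 20000
  sim <- simulate_cells(m, n, temporal = tf, seed = 6)
  t_acq <- seq_len(n) / n
  slope <- coef(lm(sim$ch01 ~ t_acq))[2]
  expect_lt(abs(slope - e) / abs(e), 0.05)
})

test_that("per-type moments match a brute-force truncated-mixture oracle", {
  w <- c(0.6, 0.4)
  mu <- rbind(c(1, -0.5, 2), c(3, 1, 0.2))
  S <- list(diag(c(0.5, 0.8, 0.3)), diag(c(0.4, 0.2, 0.6)))
  g <- cell_type_gmm(w, mu, S)
  m <- reference_model(list(A = g), 1)
  n <- 100000
  sim <- simulate_cells(m, n, seed = 21)
  got <- colMeans(as.matrix(sim[, 1:3]))
  ora <- oracle_truncated_mixture(w, mu, S, n, seed = 22)
  expect_true(all(abs(got - ora$mean) < 4 * sqrt(2) * ora$se))
  got_cov <- cov(as.matrix(sim[, 1:3]))
  expect_lt(max(abs(got_cov - ora$cov)), 0.02)
})

test_that("simulation output is non-negative without noise and reproducible", {
  m <- create_model(3, 6, seed = 4)
  sim1 <- simulate_cells(m, 5000, noise = 0, seed = 9)
  expect_gte(min(as.matrix(sim1[, 1:6])), 0)
  sim2 <- simulate_cells(m, 5000, noise = 0, seed = 9)
  expect_identical(sim1, sim2)

  noisy <- simulate_cells(m, 10000, noise = 0.2, seed = 10)
  expect_gte(min(as.matrix(noisy[, 1:6])), -6 * 0.2)
})

test_that("mismatched trajectory cell types are reported as a set difference", {
  m1 <- create_model(3, 6, seed = 1)
  m2 <- create_model(4, 6, seed = 1)
  tr <- build_trajectory(m2, seed = 1)
  expect_error(simulate_cells(m1, 100, trajectory = tr, seed = 1),
               "only in trajectory")
})
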