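test_that("mean and covariance distances satisfy their hand-computed identities", {
  x <- matrix(rnorm(200), 50, 4)
  expect_equal(l2_mean_distance(x, x), 0)
  expect_equal(frobenius_cov_distance(x, x), 0)

  a <- rbind(c(1, 2), c(1, 2)); b <- rbind(c(1, 4), c(1, 4))
  expect_equal(l2_mean_distance(a, b), 2)

  shifted <- x + 3
  expect_equal(l2_mean_distance(shifted, x), 3 * sqrt(4))
  expect_equal(frobenius_cov_distance(shifted, x), 0)  # shifts leave cov alone

  # cov I vs 2I in 2-D: Frobenius distance sqrt(2)
  set.seed(1)
  u <- MASS::mvrnorm(60000, c(0, 0), diag(2), empirical = TRUE)
  v <- MASS::mvrnorm(60000, c(0, 0), 2 * diag(2), empirical = TRUE)
  expect_equal(frobenius_cov_distance(u, v), sqrt(2), tolerance = 1e-6)

  expect_equal(frobenius_cov_distance(x[sample(50), ], x), 0)
  expect_error(l2_mean_distance(x[0, , drop = FALSE], x), "empty")
  expect_error(frobenius_cov_distance(x[1, , drop = FALSE], x), "2 rows")
})

test_that("the kNN KL estimator is near zero for identical distributions", {
  set.seed(2)
  ests <- vapply(1:3, function(i) {
    p <- matrix(rnorm(3 * 5000), ncol = 3)
    q <- matrix(rnorm(3 * 5000), ncol = 3)
    kl_divergence_knn(p, q)
  }, 0)
  expect_lt(abs(mean(ests)), 0.05)
  p <- matrix(rnorm(30), ncol = 3)
  expect_error(kl_divergence_knn(p, p[, 1:2]), "dimension")
})

test_that("the kNN KL estimator tracks closed-form Gaussian divergences", {
  set.seed(3)
  n <- 20000
  cases <- list(
    list(p = matrix(rnorm(n), ncol = 1), q = matrix(rnorm(n, 1), ncol = 1),
         mu0 = 0, S0 = diag(1), mu1 = 1, S1 = diag(1)),
    list(p = matrix(rnorm(2 * n), ncol = 2), q = matrix(rnorm(2 * n, 0, 2), ncol = 2),
         mu0 = c(0, 0), S0 = diag(2), mu1 = c(0, 0), S1 = 4 * diag(2)))
  for (cs in cases) {
    truth <- oracle_gaussian_kl(cs$mu0, cs$S0, cs$mu1, cs$S1)
    est <- kl_divergence_knn(cs$p, cs$q)
    expect_lt(abs(est - truth) / truth, 0.1)
  }
})

test_that("pMSE behaves at the null, the separable limit, and under permutation", {
  set.seed(4)
  x <- matrix(rnorm(2000 * 3), ncol = 3)
  y <- x  # exact copy: propensities ~ 0.5 everywhere
  k <- pmse_n_predictors(3)
  expect_lt(pmse(y, x), 3 * k * 0.25 / 4000)
  expect_lt(pmse(y, x, terms = "main"), 3 * 3 * 0.25 / 4000)

  far <- x + 50
  expect_equal(pmse(far, x), 0.25, tolerance = 1e-3)

  expect_equal(pmse(x[sample(2000), ], x + 0.2), pmse(x, x + 0.2),
               tolerance = 1e-8)
})

test_that("relative efficiency is a plain pMSE ratio", {
  expect_equal(relative_efficiency(0.02, 0.04), 0.5)
  expect_equal(relative_efficiency(0.03, 0.03), 1)
  expect_equal(relative_efficiency(0.04, 0.02), 2)
  expect_error(relative_efficiency(0.1, 0), "positive")
})

test_that("aggregation is an abundance-weighted mean", {
  expect_equal(aggregate_metric(5, 1), 5)
  expect_equal(aggregate_metric(c(1, 3), c(0.5, 0.5)), 2)
  expect_equal(aggregate_metric(c(1, 3), c(0.9, 0.1)), 1.2)
  expect_error(aggregate_metric(c(a = 1, b = 3), c(a = 0.5, z = 0.5)), "differ")
})

test_that("evaluate_simulation scores per type and aggregates with weights", {
  ref <- make_two_type_reference(n_per_type = 1500, seed = 5)
  sim <- simulate_cells(ref$model, 3000, seed = 6)
  ev <- evaluate_simulation(sim, ref$data)
  expect_s3_class(ev, "cytosim_eval")
  expect_equal(nrow(ev$by_type), 2)
  expect_equal(sum(ev$by_type$weight), 1)
  expect_equal(unname(ev$aggregate["mean_l2"]),
               sum(ev$by_type$weight * ev$by_type$mean_l2))
  # independent resample from the same generator: all metrics near zero
  expect_lt(ev$aggregate["mean_l2"], 0.1)
  expect_lt(ev$aggregate["cov_frobenius"], 0.1)
  expect_lt(abs(ev$aggregate["kl_divergence"]), 0.1)
  # per-type null level: k predictors over ~3000 stacked rows
  expect_lt(ev$aggregate["pmse"], 5 * pmse_n_predictors(4) * 0.25 / 3000)

  bad <- sim
  bad$cell_type[bad$cell_type == "A"] <- "C"
  expect_error(evaluate_simulation(bad, ref$data), "differ")

  tdy <- tidy(ev)
  expect_equal(nrow(tdy), 8)
  expect_named(glance(ev),
               c("mean_l2", "cov_frobenius", "kl_divergence", "pmse"))
})

test_that("metric reports serialize to JSON and tidy CSV", {
  ref <- make_two_type_reference(n_per_type = 300, seed = 7)
  sim <- simulate_cells(ref$model, 600, seed = 8)
  ev <- evaluate_simulation(sim, ref$data)
  out <- file.path(withr::local_tempdir(), "report")
  write_metric_report(ev, out)
  js <- jsonlite::read_json(paste0(out, ".json"))
  expect_equal(js$aggregate$mean_l2, unname(ev$aggregate["mean_l2"]),
               tolerance = 1e-9)
  csv <- readr::read_csv(paste0(out, ".csv"), show_col_types = FALSE)
  expect_equal(nrow(csv), 8)
  expect_named(csv, c("cell_type", "metric", "value", "weight"))
})
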