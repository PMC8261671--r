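# differential: pairwise fold-changes, shuffle null, FDR grid, linear
# model, FDR assignment

test_that("pairwise fold-changes enumerate ordered cross-condition pairs", {
  # constant shift: all 9 pairwise FCs equal 2
  norm <- fake_norm(untreated_log2 = c(3, 3, 3), stress_log2 = c(5, 5, 5))
  pw <- compute_pairwise_fcs(norm)
  expect_equal(ncol(pw$fc), 9)
  expect_equal(unname(pw$fc[1, ]), rep(2, 9))
  expect_equal(unname(pw$avg_fc), 2)

  # 2x2 design, hand enumeration: FCs {1, -1, 3, 1}, mean 1
  norm <- fake_norm(untreated_log2 = rbind(c(3, 5)),
                    stress_log2 = rbind(c(4, 6)))
  pw <- compute_pairwise_fcs(norm)
  expect_setequal(unname(pw$fc[1, ]), c(1, -1, 3, 1))
  expect_equal(unname(pw$avg_fc), 1)

  # identical conditions -> exactly zero
  norm <- fake_norm(untreated_log2 = rbind(c(2, 7, 4)),
                    stress_log2 = rbind(c(2, 7, 4)))
  expect_equal(unname(compute_pairwise_fcs(norm)$avg_fc), 0)
})

test_that("swapping condition labels negates every avg_fc exactly", {
  set.seed(8)
  u <- matrix(runif(60, 0, 12), 20, 3)
  s <- matrix(runif(60, 0, 12), 20, 3)
  a <- compute_pairwise_fcs(fake_norm(u, s))
  b <- compute_pairwise_fcs(fake_norm(s, u))
  expect_identical(unname(a$avg_fc), unname(-b$avg_fc))
})

test_that("shuffle null: pooling, determinism, sizes, degenerate pool", {
  set.seed(21)
  u <- matrix(rnorm(30, 8), 10, 3)
  s <- matrix(rnorm(30, 8), 10, 3)
  pw <- compute_pairwise_fcs(fake_norm(u, s))
  nm <- build_null_distribution(pw, n_experiments = 500, seed = 3)
  expect_length(nm$null_means, 500)
  expect_equal(length(nm$pooled_fcs), 90)
  nm2 <- build_null_distribution(pw, n_experiments = 500, seed = 3)
  expect_identical(nm$null_means, nm2$null_means)

  # constant pool -> every null mean equals the constant
  cpw <- compute_pairwise_fcs(fake_norm(matrix(3, 5, 3), matrix(5, 5, 3)))
  cnm <- build_null_distribution(cpw, n_experiments = 100, seed = 1)
  expect_equal(cnm$null_means, rep(2, 100))

  # pool smaller than one experiment's draw is an error
  empty <- structure(list(fc = matrix(numeric(0), 0, 9)),
                     class = "pairwise_fc")
  expect_error(build_null_distribution(empty, 10, 1), "smaller")
  # a 1-protein table: pool size == draw size, still legal
  tiny <- structure(list(fc = matrix(1, 1, 9)), class = "pairwise_fc")
  expect_length(build_null_distribution(tiny, 10, 1)$null_means, 10)
})

test_that("FDR grid matches direct counting and the stated grids", {
  nm <- c(-1.2, -0.3, 0.4, 2.1)
  expect_equal(compute_fdr_grid(nm, thresholds = 1, "folded"), 50)
  expect_equal(compute_fdr_grid(nm, thresholds = 0, "folded"), 100)
  expect_length(default_thresholds("signed"), 41)
  expect_length(default_thresholds("folded"), 21)
  expect_error(compute_fdr_grid(nm, thresholds = c(2, 1)), "ascending")

  # brute-force oracle over random pools, exact equality
  set.seed(99)
  for (i in 1:5) {
    x <- rnorm(200, sd = 2)
    th <- default_thresholds("folded")
    oracle <- sapply(th, function(t) 100 * (sum(abs(x) >= t) / length(x)))
    expect_identical(compute_fdr_grid(x, th, "folded"), oracle)
    ths <- default_thresholds("signed")
    oracle_s <- sapply(ths, function(t) 100 * (sum(x >= t) / length(x)))
    expect_identical(compute_fdr_grid(x, ths, "signed"), oracle_s)
  }
})

test_that("linear model fit matches the closed-form normal equations", {
  cf <- fit_fdr_model(c(0, 1, 2), c(50, 30, 10))
  expect_equal(unname(cf), c(50, -20))
  cf <- fit_fdr_model(0:10, rep(100, 11))
  expect_equal(unname(cf), c(100, 0))
  expect_error(fit_fdr_model(rep(1, 5), rep(2, 5)), "singular")

  set.seed(7)
  for (i in 1:10) {
    t <- sort(runif(15, -10, 10))
    g <- pmin(pmax(100 - 10 * t + rnorm(15), 0), 100)
    cf <- fit_fdr_model(t, g)
    # normal equations oracle
    slope <- sum((t - mean(t)) * (g - mean(g))) / sum((t - mean(t))^2)
    intercept <- mean(g) - slope * mean(t)
    expect_equal(unname(cf), c(intercept, slope), tolerance = 1e-8)
  }
})

test_that("folded grids are non-increasing and give non-positive slopes", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(500, sd = runif(1, 0.2, 3))
    grid <- compute_fdr_grid(x, tail_mode = "folded")
    expect_true(all(diff(grid) <= 0))
    cf <- fit_fdr_model(default_thresholds("folded"), grid)
    expect_lte(cf[["slope"]], 0)
    expect_true(all(grid >= 0 & grid <= 100))
  }
})

test_that("assign_fdr: plug-in arithmetic, clamping, direction", {
  m <- fake_model(intercept = 50, slope = -20)
  row <- assign_fdr(c(A = 3), m)
  expect_equal(row$fdr_percent, 0)  # raw -10 clamped to 0
  expect_true(row$significant)
  expect_equal(row$direction, "more")

  row <- assign_fdr(c(A = 0), m)
  expect_equal(row$fdr_percent, 50)
  expect_false(row$significant)
  expect_true(is.na(row$direction))

  row <- assign_fdr(c(A = 1.5), m)
  expect_equal(row$fdr_percent, 20)
  expect_false(row$significant)

  # mirrored model: negative fold-change uses |avg_fc|
  expect_equal(assign_fdr(c(A = -3), m)$fdr_percent, 0)
  expect_equal(assign_fdr(c(A = -3), m)$direction, "less")

  # fdr always within [0, 100]
  wild <- assign_fdr(setNames(seq(-20, 20, 0.5),
                              paste0("x", 1:81)), m)
  expect_true(all(wild$fdr_percent >= 0 & wild$fdr_percent <= 100))
  expect_identical(wild$significant, wild$fdr_percent <= 5)
})

test_that("call_differential is deterministic and handles the degenerate
           equal-condition case", {
  set.seed(14)
  vals <- matrix(runif(45, 5, 12), 15, 3)
  norm <- fake_norm(vals, vals)  # stress column-copied from untreated
  res <- call_differential(norm, n_experiments = 1000, seed = 2)
  expect_true(all(res$table$avg_fc == 0))
  if (res$null_model$intercept > 5) {
    expect_equal(sum(res$table$significant), 0)
  }

  u <- matrix(runif(45, 5, 12), 15, 3)
  s <- matrix(runif(45, 5, 12), 15, 3)
  a <- call_differential(fake_norm(u, s), n_experiments = 500, seed = 9)
  b <- call_differential(fake_norm(u, s), n_experiments = 500, seed = 9)
  expect_identical(a$table, b$table)
  expect_identical(a$null_model$null_means, b$null_model$null_means)
})

test_that("sign-flip null variant preserves size and determinism", {
  set.seed(5)
  pw <- compute_pairwise_fcs(fake_norm(matrix(rnorm(30, 8), 10, 3),
                                       matrix(rnorm(30, 8), 10, 3)))
  a <- build_null_distribution_signflip(pw, 200, seed = 4)
  b <- build_null_distribution_signflip(pw, 200, seed = 4)
  expect_identical(a$null_means, b$null_means)
  expect_length(a$null_means, 200)
  # every null mean is a +/- recombination of one protein's FCs
  expect_true(all(abs(a$null_means) <= max(abs(pw$fc)) + 1e-12))
})
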