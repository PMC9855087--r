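alternating_Z <- function(M = 10) {
  Z <- matrix(0, M, 2)
  Z[seq(1, M, by = 2), 1] <- 1
  Z[seq(2, M, by = 2), 2] <- 1
  Z
}

test_that("identical non-trivial selections give phi = 1", {
  Z <- matrix(rep(c(1, 1, 0, 0, 0), 10), 10, 5, byrow = TRUE)
  expect_equal(nogueira_stability(Z), 1)
  ci <- stability_ci(Z, B = 200, seed = 1)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
})

test_that("alternating two-feature selections give the hand-derived -1/9", {
  Z <- alternating_Z(10)
  expect_equal(nogueira_stability(Z), -1 / 9)
  ci <- stability_ci(Z, B = 500, seed = 2)
  expect_lte(ci$ci_low, -1 / 9)
  expect_gte(ci$ci_high, -1 / 9)
})

test_that("random fixed-k selections are unbiased around 0", {
  # Monte-Carlo null: k=5 of d=50, M=200, 500 repetitions
  withr::with_seed(42, {
    phis <- vapply(1:500, function(r) {
      Z <- t(vapply(1:200, function(m) {
        z <- numeric(50); z[sample.int(50, 5)] <- 1; z
      }, numeric(50)))
      nogueira_stability(Z)
    }, 0.0)
  })
  expect_lt(abs(mean(phis)), 0.02)
})

test_that("phi is invariant to row/column permutation, 1 iff rows identical", {
  withr::with_seed(8, {
    Z <- matrix(rbinom(20 * 12, 1, 0.3), 20, 12)
    phi <- nogueira_stability(Z)
    expect_equal(nogueira_stability(Z[sample(20), sample(12)]), phi)
  })
  expect_lt(phi <- nogueira_stability(rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))), 1)
})

test_that("degenerate selections are reported as undefined, not a number", {
  expect_true(is.na(nogueira_stability(matrix(0, 5, 3))))
  expect_match(attr(nogueira_stability(matrix(1, 5, 3)), "reason"), "undefined")
  expect_error(nogueira_stability(matrix(0, 1, 3)), "2 resamples")
  expect_error(nogueira_stability(matrix(2, 5, 3)), "binary")
})

test_that("CI width shrinks with more resamples", {
  make_Z <- function(M, seed) {
    withr::with_seed(seed, {
      base <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
      t(vapply(seq_len(M), function(m) {
        z <- base
        if (runif(1) < 0.3) z <- z[c(2:10, 1)] # occasional drift
        z
      }, numeric(10)))
    })
  }
  w <- function(M) {
    ci <- stability_ci(make_Z(M, 5), B = 400, seed = 9)
    ci$ci_high - ci$ci_low
  }
  expect_lt(w(200), w(20))
})

test_that("harness is deterministic and behaves on planted-truth data", {
  cfg <- small_sim_config(seed = 2, noise_sd = 0)
  ds <- simulate_dataset(cfg)
  expr <- normalize_expression(ds$expr)
  Y <- compute_activities(ds$collection, expr)
  rc <- relevance_config(ds$truth$kdt_genes, n_trees = 40, cv_folds = 3,
                         seed = 1, background_size = 20)
  h1 <- run_stability_harness(expr, Y, rc, M = 5, seed = 3, ci_reps = 100,
                              null_draws = 100)
  h2 <- run_stability_harness(expr, Y, rc, M = 5, seed = 3, ci_reps = 100,
                              null_draws = 100)
  expect_identical(h1$Z, h2$Z) # same config + seed -> identical Z
  expect_identical(dim(h1$Z), c(5L, length(ds$truth$kdt_genes)))
  rep <- h1$report
  if (!is.na(rep$phi_hat)) {
    expect_lte(rep$ci_low, rep$phi_hat + 1e-12)
    expect_gte(rep$ci_high, rep$phi_hat - 1e-12)
    expect_lte(rep$phi_hat, 1)
  }
})

test_that("pure-noise response leaves the selection degenerate (documented)", {
  # With the floor rule and near-zero R^2, no circuit selects any KDT, so
  # the stability of a pure-noise pipeline is undefined rather than ~0; the
  # harness must say so instead of inventing a number.
  withr::with_seed(77, {
    expr <- matrix(runif(60 * 8), 60, 8,
                   dimnames = list(paste0("s", 1:60), paste0("g", 1:8)))
    Y <- matrix(runif(60 * 4), 60, 4,
                dimnames = list(paste0("s", 1:60), paste0("c", 1:4)))
  })
  rc <- relevance_config(paste0("g", 1:8), n_trees = 30, cv_folds = 3, seed = 1)
  h <- run_stability_harness(expr, Y, rc, M = 4, seed = 5, ci_reps = 50,
                             null_draws = 50)
  expect_true(is.na(h$report$phi_hat))
  expect_match(h$report$undefined_reason, "undefined")
})
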