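test_that("imputation is the identity on complete matrices", {
  x <- gaussian_log2(50, 6, seed = 1)
  out <- impute(x, impute_config(seed = 2))
  expect_identical(unclass(out$matrix), unclass(x))
  expect_equal(out$report$n_bottom_tail + out$report$n_lls +
                 out$report$n_fallback, 0L)
})

test_that("bottom-tail draws sit in the low tail at the configured downshift", {
  x <- gaussian_log2(2000, 6, seed = 3, n_full_missing = 40)
  res <- impute_bottom_tail(x, impute_config(seed = 9))
  filled <- unclass(res$matrix)
  obs_rows <- 41:2000
  # observed cells bit-identical
  expect_identical(filled[obs_rows, ], unclass(x)[obs_rows, ])
  expect_false(anyNA(filled))
  for (j in seq_len(ncol(x))) {
    obs <- unclass(x)[obs_rows, j]
    imp <- filled[1:40, j]
    target <- mean(obs) - 1.8 * sd(obs)
    se <- 0.3 * sd(obs) / sqrt(length(imp))
    expect_lt(abs(mean(imp) - target), 3 * se)
    # far below the bulk of the observed distribution
    expect_true(all(imp < quantile(obs, 0.25)))
  }
  # seeded determinism
  res2 <- impute_bottom_tail(x, impute_config(seed = 9))
  expect_identical(unclass(res2$matrix), filled)
})

test_that("bottom-tail imputation validates scale and sample support", {
  lin <- make_am(2^c(1, 2, 3, 4), 2, 2, scale = "linear")
  expect_error(impute_bottom_tail(lin, impute_config()),
               class = "state_error")
  x <- make_am(c(NA, 20, NA, NA, NA, 21), 3, 2)  # s1 has 1 observed value
  expect_error(impute_bottom_tail(x, impute_config()),
               "fewer than 2 observed", class = "validation_error")
})

test_that("LLS reproduces an exactly proportional neighbor", {
  x <- make_am(c(2, 1, 4, 2, NA, 3), 2, 3)
  out <- impute_lls(x, impute_config(k = 1, min_overlap = 2))
  expect_equal(unclass(out$matrix)["P001", "s3"], 6)
  expect_equal(out$report$n_lls, 1L)
})

test_that("LLS recovers masked cells of a noiseless rank-1 matrix", {
  set.seed(11)
  u <- runif(60, 1, 3)
  w <- runif(8, 5, 9)
  v <- outer(u, w)
  dimnames(v) <- list(sprintf("P%03d", 1:60), sprintf("s%d", 1:8))
  mask <- matrix(runif(length(v)) < 0.05, nrow(v))
  mask[rowSums(!mask) < 2, ] <- FALSE      # keep every row partially observed
  truth <- v
  v[mask] <- NA
  out <- suppressWarnings(impute_lls(AbundanceMatrix(v, "log2"),
                                     impute_config(k = 3, min_overlap = 2)))
  rel_err <- abs(unclass(out$matrix)[mask] - truth[mask]) / truth[mask]
  expect_lt(max(rel_err), 1e-9)
})

test_that("LLS falls back to the row mean without usable neighbors", {
  # second row is constant over its observed cells; no complete neighbor
  # correlates (the only complete row is constant too, sd 0)
  v <- matrix(c(5, 5, 5, 5,
                7, 7, 7, NA), 2, 4, byrow = TRUE,
              dimnames = list(c("A", "B"), sprintf("s%d", 1:4)))
  out <- impute_lls(AbundanceMatrix(v, "log2"),
                    impute_config(k = 2, min_overlap = 2))
  expect_equal(unclass(out$matrix)["B", "s4"], 7)
  expect_equal(out$report$n_fallback, 1L)
})

test_that("LLS error on a noisy low-rank matrix stays below the noise level", {
  set.seed(21)
  n <- 300; k <- 9; noise_sd <- 0.25
  # rank-1 structure with loadings bounded away from zero, so every row
  # carries enough shared signal for neighbors to be informative
  load <- matrix(sample(c(-1, 1), n, replace = TRUE) * runif(n, 1, 2), n, 1)
  fact <- matrix(rnorm(k, 0, 1.5), 1, k)
  truth <- 22 + load %*% fact
  v <- truth + matrix(rnorm(n * k, 0, noise_sd), n, k)
  dimnames(v) <- list(sprintf("P%03d", 1:n), sprintf("s%d", 1:k))
  mask <- matrix(runif(n * k) < 0.05, n, k)
  mask[rowSums(!mask) < 3, ] <- FALSE
  obs <- v
  obs[mask] <- NA
  out <- suppressWarnings(impute_lls(AbundanceMatrix(obs, "log2"),
                                     impute_config()))
  err <- abs(unclass(out$matrix)[mask] - v[mask])
  expect_lt(median(err), noise_sd)
})

test_that("two-case dispatch conserves observed cells and fills everything", {
  x <- gaussian_log2(400, 9, seed = 5, n_full_missing = 6)
  v <- unclass(x)
  set.seed(99)
  v[sample(which(!is.na(v)), 150)] <- NA
  x <- AbundanceMatrix(v, "log2")
  n_miss <- sum(is.na(x))
  out <- suppressWarnings(impute(x, impute_config(seed = 31)))
  expect_false(anyNA(out$matrix))
  expect_identical(unclass(out$matrix)[!is.na(v)], v[!is.na(v)])
  expect_gt(out$report$n_bottom_tail, 0L)
  expect_gt(out$report$n_lls, 0L)
  expect_equal(out$report$n_bottom_tail + out$report$n_lls +
                 out$report$n_fallback, n_miss)
  # seed determinism end to end
  out2 <- suppressWarnings(impute(x, impute_config(seed = 31)))
  expect_identical(unclass(out2$matrix), unclass(out$matrix))
})
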