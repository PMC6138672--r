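test_that("Student t matches the closed form and the stats oracle", {
  res <- unpaired_t(c(1, 2, 3), c(4, 5, 6))
  # pooled sd 1, se sqrt(2/3), diff -3
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-3)
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4L)
  expect_lt(abs(res$p_value - 0.0214), 1e-3)
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)
})

test_that("Student t symmetry and degenerate cases", {
  a <- c(2.2, 3.1, 4.4); b <- c(1.8, 2.4, 2.6, 3.9)
  expect_equal(unpaired_t(a, b)$statistic, -unpaired_t(b, a)$statistic)
  expect_equal(unpaired_t(a, b)$p_value, unpaired_t(b, a)$p_value)
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  const <- unpaired_t(c(2, 2), c(2, 2))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  expect_error(unpaired_t(1, c(1, 2)), class = "validation_error")
})

test_that("moderated d reduces to t at s0 = 0 and shrinks with s0", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(moderated_d(a, b, s0 = 0), unpaired_t(a, b)$statistic)
  expect_equal(moderated_d(c(2, 2), c(1, 1), s0 = 0.5), 2)
  grid <- seq(0, 2, by = 0.25)
  mags <- abs(vapply(grid, function(s0) moderated_d(a, b, s0), 0))
  expect_true(all(diff(mags) <= 0))
})

test_that("null simulations keep the q<0.05 fraction controlled", {
  x <- gaussian_log2(1000, 6, seed = 31, noise_sd = 0.25)
  d <- SampleDesign(sample = colnames(x),
                    group = rep(c("control", "siRNA1"), each = 3),
                    control = "control")
  r <- permutation_fdr(x, d, "siRNA1", test_config(statistic = "moderated_d"))
  frac <- mean(r$q_value < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(frac, 0.05 + 3 * mc_se)
})

test_that("a strongly shifted protein attains the minimum q", {
  x <- gaussian_log2(1000, 6, seed = 37, noise_sd = 0.25)
  v <- unclass(x)
  v["P0500", 4:6] <- v["P0500", 4:6] - 8 * 0.25   # 8-sd knockdown
  x <- AbundanceMatrix(v, "log2")
  d <- SampleDesign(sample = colnames(x),
                    group = rep(c("control", "siRNA1"), each = 3),
                    control = "control")
  r <- permutation_fdr(x, d, "siRNA1", test_config(statistic = "moderated_d"))
  expect_equal(r$q_value[r$protein_id == "P0500"], min(r$q_value))
  expect_identical(r$direction[r$protein_id == "P0500"], "negative")
})

test_that("sampled permutations approximate the exhaustive q-values", {
  x <- gaussian_log2(200, 6, seed = 41, noise_sd = 0.3)
  d <- SampleDesign(sample = colnames(x),
                    group = rep(c("control", "siRNA1"), each = 3),
                    control = "control")
  r_ex <- permutation_fdr(x, d, "siRNA1", test_config())
  r_s <- permutation_fdr(x, d, "siRNA1",
                         test_config(permutations = 10000, perm_seed = 5))
  expect_lt(max(abs(r_ex$q_value - r_s$q_value)), 0.02)
  expect_error(test_config(permutations = 1000), "perm_seed",
               class = "validation_error")
})

test_that("q-values never increase with statistic strength within a tail", {
  x <- gaussian_log2(500, 6, seed = 43)
  d <- SampleDesign(sample = colnames(x),
                    group = rep(c("control", "siRNA1"), each = 3),
                    control = "control")
  r <- permutation_fdr(x, d, "siRNA1", test_config(statistic = "moderated_d"))
  for (sgn in c(-1, 1)) {
    i <- which(sign(r$statistic) == sgn)
    o <- i[order(sgn * r$statistic[i])]
    expect_true(all(diff(r$q_value[o]) <= 1e-12))
  }
})

fake_contrast <- function(ids, mean_diff, q) {
  structure(data.frame(protein_id = ids, mean_diff = mean_diff,
                       statistic = mean_diff, p_value = q, q_value = q,
                       direction = "none", stringsAsFactors = FALSE),
            n_permutations = 20L,
            class = c("ContrastResult", "data.frame"))
}

test_that("intersection keeps only concordant significant calls", {
  ids <- c("A", "B", "C", "D")
  r1 <- fake_contrast(ids, c(-1, -1, -1,  1), c(0.01, 0.01, 0.20, 0.01))
  r2 <- fake_contrast(ids, c(-1,  1, -1,  1), c(0.01, 0.01, 0.01, 0.01))
  aff <- call_affected(list(r1, r2), alpha = 0.05)
  expect_identical(aff$negatively_affected, "A")  # B flips sign, C ns in r1
  expect_identical(aff$positively_affected, "D")
  expect_length(intersect(aff$negatively_affected,
                          aff$positively_affected), 0L)
  r3 <- fake_contrast(c("A", "B"), c(-1, -1), c(0.01, 0.01))
  expect_error(call_affected(list(r1, r3)), "universe",
               class = "validation_error")
})

test_that("volcano tables floor q before the log transform", {
  r <- fake_contrast(c("A", "B", "C"), c(-2, 0, 1), c(0.05, 1, 0))
  v <- volcano_table(r)
  expect_equal(nrow(v), 3L)
  expect_equal(v$neg_log10_q[1], 1.301, tolerance = 1e-3)
  expect_equal(v$neg_log10_q[2], 0)
  expect_equal(v$neg_log10_q[3], -log10(1 / (20 * 3)))  # floored, finite
})
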