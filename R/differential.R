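#' Test configuration for differential abundance analysis
#'
#' @param alpha FDR level for significance calls (default 0.05).
#' @param statistic `"student_t"` (pooled-variance two-sample t, the default)
#'   or `"moderated_d"` (significance-analysis-of-microarrays style
#'   `d = (mean_a - mean_b) / (s + s0)` with a variance-stabilizing fudge
#'   factor `s0`).
#' @param s0 fudge factor for `moderated_d`; `NULL` selects the percentile of
#'   the pooled standard errors that minimizes the coefficient of variation
#'   of the statistic's spread across standard-error bins (see
#'   [select_s0()]).
#' @param permutations `"exhaustive"` for all distinct relabelings of the
#'   contrast's samples, or an integer `B` for sampled permutations (then
#'   `perm_seed` is required).
#' @param perm_seed seed for sampled permutations.
#' @param pool_null pool null statistics across proteins when estimating the
#'   FDR (default `TRUE`; overcomes the 20-split granularity of a
#'   3-versus-3 design). `FALSE` keeps per-protein nulls for audit.
#' @return list of class `test_config`.
#' @export
test_config <- function(alpha = 0.05,
                        statistic = c("student_t", "moderated_d"),
                        s0 = NULL, permutations = "exhaustive",
                        perm_seed = NULL, pool_null = TRUE) {
  statistic <- match.arg(statistic)
  stopifnot(alpha > 0, alpha < 1)
  if (is.numeric(permutations)) {
    stopifnot(permutations >= 2)
    if (is.null(perm_seed))
      .tc_stop("sampled permutations need 'perm_seed'", "validation_error")
  } else if (!identical(permutations, "exhaustive")) {
    .tc_stop("'permutations' must be \"exhaustive\" or a count",
             "validation_error")
  }
  structure(list(alpha = alpha, statistic = statistic, s0 = s0,
                 permutations = permutations, perm_seed = perm_seed,
                 pool_null = isTRUE(pool_null)),
            class = "test_config")
}

#' Two-sample unpaired Student t-test
#'
#' Pooled-variance two-sample t with `n_a + n_b - 2` degrees of freedom and a
#' two-sided p-value. The degenerate case of zero pooled variance returns
#' statistic 0 and p 1 when the means agree, and an infinite statistic with
#' p 0 otherwise.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @return list with `statistic` (sign of `mean(group_a) - mean(group_b)`),
#'   `p_value`, `df`, `mean_diff`.
#' @export
#' @examples
#' unpaired_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p ~ 0.0214
unpaired_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    .tc_stop("both groups need >= 2 values", "validation_error")
  na <- length(group_a); nb <- length(group_b)
  df <- na + nb - 2L
  diff <- mean(group_a) - mean(group_b)
  sp2 <- (sum((group_a - mean(group_a))^2) +
            sum((group_b - mean(group_b))^2)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  if (se == 0) {
    stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    stat <- diff / se
    p <- 2 * stats::pt(-abs(stat), df)
  }
  list(statistic = stat, p_value = p, df = df, mean_diff = diff)
}

#' Moderated d-statistic
#'
#' The significance-analysis-of-microarrays statistic
#' `d = (mean_a - mean_b) / (s + s0)`, where `s` is the pooled standard error
#' of the mean difference. With `s0 = 0` it equals the Student t statistic;
#' `s0 > 0` keeps the statistic bounded for near-zero-variance proteins.
#'
#' @inheritParams unpaired_t
#' @param s0 non-negative fudge factor.
#' @return the statistic (numeric scalar).
#' @export
moderated_d <- function(group_a, group_b, s0 = 0) {
  stopifnot(s0 >= 0)
  if (length(group_a) < 2L || length(group_b) < 2L)
    .tc_stop("both groups need >= 2 values", "validation_error")
  na <- length(group_a); nb <- length(group_b)
  diff <- mean(group_a) - mean(group_b)
  sp2 <- (sum((group_a - mean(group_a))^2) +
            sum((group_b - mean(group_b))^2)) / (na + nb - 2L)
  s <- sqrt(sp2 * (1 / na + 1 / nb))
  if (s + s0 == 0) return(if (diff == 0) 0 else sign(diff) * Inf)
  diff / (s + s0)
}

# vectorized per-row mean difference and pooled standard error
.row_diff_se <- function(v, ia, ib) {
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(v[, ia, drop = FALSE])
  mb <- rowMeans(v[, ib, drop = FALSE])
  ssa <- rowSums((v[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((v[, ib, drop = FALSE] - mb)^2)
  sp2 <- (ssa + ssb) / (na + nb - 2L)
  list(diff = ma - mb, se = sqrt(sp2 * (1 / na + 1 / nb)))
}

.row_stat <- function(diff, se, s0) {
  denom <- se + s0
  stat <- diff / denom
  z <- denom == 0
  stat[z] <- ifelse(diff[z] == 0, 0, sign(diff[z]) * Inf)
  stat
}

#' Select the moderated-d fudge factor s0
#'
#' Scans percentiles of the pooled standard errors and picks the candidate
#' minimizing the coefficient of variation of the statistic's median absolute
#' deviation across standard-error decile bins, so that the spread of `d` is
#' as independent of `s` as possible.
#'
#' @param diff per-protein mean differences.
#' @param se per-protein pooled standard errors.
#' @return the selected `s0` value.
#' @export
select_s0 <- function(diff, se) {
  stopifnot(length(diff) == length(se), length(diff) >= 10L)
  cand <- unique(stats::quantile(se, seq(0, 1, by = 0.05), names = FALSE))
  bins <- cut(rank(se, ties.method = "first"), breaks = 10L, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- .row_stat(diff, se, s0)
    mads <- tapply(d, bins, stats::mad)
    if (mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, 0)
  cand[which.min(cv)]
}

# all (or B sampled) assignments of pseudo-target columns among the
# contrast's samples; columns index into the n = na + nb contrast samples.
# When the requested sample size covers the whole (enumerable) split space,
# sampling degenerates to exhaustive enumeration; otherwise distinct splits
# are drawn without replacement where the space is small enough to list.
.perm_sets <- function(n, na, permutations, perm_seed) {
  n_distinct <- choose(n, na)
  if (identical(permutations, "exhaustive")) {
    sets <- utils::combn(n, na)
  } else {
    B <- as.integer(permutations)
    if (n_distinct <= max(B, 1e5)) {
      all_sets <- utils::combn(n, na)
      if (B >= n_distinct) {
        sets <- all_sets
      } else {
        set.seed(perm_seed)
        sets <- all_sets[, sample.int(ncol(all_sets), B), drop = FALSE]
      }
    } else {
      set.seed(perm_seed)
      sets <- replicate(B, sort(sample.int(n, na)))
    }
  }
  if (ncol(sets) < 2L)
    .tc_stop("fewer than 2 distinct permutations available", "validation_error")
  sets
}

#' Per-contrast differential test with permutation FDR
#'
#' For one targeting group versus the control, computes a per-protein
#' statistic (Student t or moderated d) on the complete normalized log2
#' matrix, builds a null distribution by relabeling the contrast's samples
#' (all `choose(n, n_target)` splits in exhaustive mode, e.g. 20 for a
#' 3-versus-3 design), and converts it into permutation-based q-values.
#' Tails are treated directionally, as in the
#' significance-analysis-of-microarrays procedure with asymmetric cutoffs:
#' the threshold for a down-regulated protein counts null and observed
#' statistics in the matching (negative) tail only, and symmetrically for
#' up-regulation. The estimated false discovery rate at a threshold is
#' `pi0 * median_b(#null_b beyond threshold) / #observed beyond threshold`,
#' with `pi0` estimated from the fraction of observed statistics inside the
#' central 50% of the pooled null. q-values are monotonized so that a
#' stronger statistic never has a larger q.
#'
#' @param x complete log2-scale [AbundanceMatrix()] (imputed, normalized).
#' @param design a [SampleDesign()] covering the matrix's samples.
#' @param target_group the targeting group of this contrast.
#' @param config a [test_config()].
#' @return A `ContrastResult` data.frame with one row per protein: `protein_id`,
#'   `mean_diff` (log2 targeting minus control), `statistic`, `p_value`,
#'   `q_value`, `direction` (`negative` / `positive` / `none`); attributes
#'   `n_permutations`, `pi0`, `s0`, `contrast`.
#' @export
permutation_fdr <- function(x, design, target_group, config = test_config()) {
  .assert_scale(x, "log2", "permutation_fdr")
  if (anyNA(x))
    .tc_stop("matrix has missing cells: impute before testing", "state_error")
  .match_design(x, design)
  if (!target_group %in% targeting_groups(design))
    .tc_stop(sprintf("'%s' is not a targeting group", target_group),
             "validation_error")
  v <- unclass(x)
  cols_t <- design$sample[design$group == target_group]
  cols_c <- design$sample[design$group == control_group(design)]
  sub <- v[, c(cols_t, cols_c), drop = FALSE]
  nt <- length(cols_t); nc <- length(cols_c); n <- nt + nc
  ia <- seq_len(nt); ib <- nt + seq_len(nc)

  obs <- .row_diff_se(sub, ia, ib)
  s0 <- 0
  if (config$statistic == "moderated_d")
    s0 <- if (is.null(config$s0)) select_s0(obs$diff, obs$se) else config$s0
  d_obs <- .row_stat(obs$diff, obs$se, s0)

  sets <- .perm_sets(n, nt, config$permutations, config$perm_seed)
  B <- ncol(sets)
  m <- nrow(sub)
  null_stats <- matrix(NA_real_, m, B)
  for (b in seq_len(B)) {
    pa <- sets[, b]
    pb <- setdiff(seq_len(n), pa)
    pe <- .row_diff_se(sub, pa, pb)
    null_stats[, b] <- .row_stat(pe$diff, pe$se, s0)
  }

  abs_obs <- abs(d_obs)
  pooled_null <- as.vector(null_stats)
  qs <- stats::quantile(pooled_null, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d_obs >= qs[1] & d_obs <= qs[2]) / (0.5 * m))
  # directional (asymmetric-tail) FDR, one side at a time: the threshold for
  # a down-regulated protein counts only the matching null and observed tail
  q <- rep(1, m)
  for (sgn in c(-1, 1)) {
    i <- which(sgn * d_obs > 0)
    if (!length(i)) next
    cuts <- sgn * d_obs[i]
    sd_obs <- sort(sgn * d_obs)
    den <- pmax(1L, m - findInterval(cuts, sd_obs, left.open = TRUE))
    if (config$pool_null) {
      cnt <- matrix(0L, length(i), B)
      for (b in seq_len(B)) {
        s_null <- sort(sgn * null_stats[, b])
        cnt[, b] <- m - findInterval(cuts, s_null, left.open = TRUE)
      }
      num <- apply(cnt, 1L, stats::median)
      q[i] <- pmin(1, pi0 * num / den)
    } else {
      per_protein <- rowMeans(sgn * null_stats[i, , drop = FALSE] >=
                                cuts)
      q[i] <- pmin(1, pi0 * per_protein * m / den)
    }
    # monotonize: q_i = min over all thresholds that still call protein i
    ord <- i[order(sgn * d_obs[i], rownames(v)[i])]
    q[ord] <- cummin(q[ord])
    q[i] <- stats::ave(q[i], match(d_obs[i], d_obs[i]), FUN = min)
  }

  p <- if (config$statistic == "student_t") {
    df <- n - 2L
    2 * stats::pt(-abs_obs, df)
  } else {
    # pooled permutation p-value
    s_all <- sort(abs(pooled_null))
    (length(s_all) - findInterval(abs_obs, s_all, left.open = TRUE)) /
      length(s_all)
  }

  direction <- rep("none", m)
  direction[q < config$alpha & obs$diff < 0] <- "negative"
  direction[q < config$alpha & obs$diff > 0] <- "positive"
  res <- data.frame(protein_id = rownames(v), mean_diff = obs$diff,
                    statistic = d_obs, p_value = p, q_value = q,
                    direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, n_permutations = B, pi0 = pi0, s0 = s0,
            contrast = paste0(target_group, "_vs_", control_group(design)),
            class = c("ContrastResult", "data.frame"))
}

#' Intersect per-contrast calls into affected protein sets
#'
#' A protein is negatively (positively) affected only if it is significant at
#' `alpha` with a negative (positive) log2 mean difference in every targeting
#' contrast — the intersection rule that filters single-siRNA off-target
#' artifacts.
#'
#' @param contrast_results list of `ContrastResult` objects over the same
#'   protein universe (one per targeting siRNA).
#' @param alpha FDR level for calls.
#' @return list of class `AffectedSets` with character vectors
#'   `negatively_affected`, `positively_affected` and the per-contrast call
#'   tables.
#' @export
call_affected <- function(contrast_results, alpha = 0.05) {
  stopifnot(length(contrast_results) >= 1L)
  ids <- contrast_results[[1L]]$protein_id
  for (r in contrast_results)
    if (!identical(r$protein_id, ids))
      .tc_stop("contrast results cover different protein universes",
               "validation_error")
  neg <- pos <- rep(TRUE, length(ids))
  for (r in contrast_results) {
    sig <- r$q_value < alpha
    neg <- neg & sig & r$mean_diff < 0
    pos <- pos & sig & r$mean_diff > 0
  }
  structure(list(negatively_affected = ids[neg],
                 positively_affected = ids[pos],
                 per_contrast = contrast_results,
                 alpha = alpha),
            class = "AffectedSets")
}

#' @export
print.AffectedSets <- function(x, ...) {
  cat(sprintf("AffectedSets (alpha = %g, %d contrasts intersected)\n",
              x$alpha, length(x$per_contrast)))
  cat(sprintf("  negatively affected: %d\n", length(x$negatively_affected)))
  cat(sprintf("  positively affected: %d\n", length(x$positively_affected)))
  invisible(x)
}

#' Volcano plot table for a contrast
#'
#' One row per protein with the log2 mean difference and `-log10(q)`.
#' q-values are floored at `1 / (n_permutations * n_proteins)` before the
#' logarithm so that zero estimates do not produce infinities.
#'
#' @param contrast_result a `ContrastResult` from [permutation_fdr()].
#' @return data.frame with columns `protein_id`, `mean_diff`,
#'   `neg_log10_q`.
#' @export
volcano_table <- function(contrast_result) {
  stopifnot(inherits(contrast_result, "ContrastResult"))
  floor_q <- 1 / (attr(contrast_result, "n_permutations") *
                    nrow(contrast_result))
  data.frame(protein_id = contrast_result$protein_id,
             mean_diff = contrast_result$mean_diff,
             neg_log10_q = -log10(pmax(contrast_result$q_value, floor_q)),
             stringsAsFactors = FALSE)
}
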