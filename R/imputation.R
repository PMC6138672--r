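#' Imputation configuration
#'
#' Parameters for the two-case missing-value scheme used on log2 LFQ
#' matrices: proteins with no valid data point receive random draws from a
#' downshifted bottom-tail distribution (the Perseus-style strategy);
#' proteins with at least one valid point are completed by local least
#' squares (LLS) regression on their most correlated neighbor proteins.
#'
#' @param downshift bottom-tail center, in standard deviations below the
#'   observed per-sample mean (default 1.8, the canonical Perseus value).
#' @param width bottom-tail standard deviation as a fraction of the observed
#'   per-sample standard deviation (default 0.3).
#' @param k number of neighbor proteins in the LLS regression.
#' @param min_overlap minimum number of observed samples a target protein
#'   needs before neighbors are considered; below it the row-mean fallback is
#'   used.
#' @param seed integer seed for the bottom-tail draws (`NULL` = leave RNG
#'   state alone).
#' @param pooled_tail if `TRUE`, draw bottom-tail values from the pooled
#'   distribution over all samples instead of per-sample distributions.
#' @return list of class `impute_config`.
#' @export
impute_config <- function(downshift = 1.8, width = 0.3, k = 10L,
                          min_overlap = 3L, seed = NULL,
                          pooled_tail = FALSE) {
  stopifnot(downshift >= 0, width > 0, k >= 1, min_overlap >= 2)
  structure(list(downshift = downshift, width = width, k = as.integer(k),
                 min_overlap = as.integer(min_overlap), seed = seed,
                 pooled_tail = isTRUE(pooled_tail)),
            class = "impute_config")
}

# observed per-sample (or pooled) location/spread of a log2 matrix
.tail_params <- function(x, pooled) {
  if (pooled) {
    v <- x[!is.na(x)]
    if (length(v) < 2L)
      .tc_stop("fewer than 2 observed values overall: tail distribution undefined",
               "validation_error")
    data.frame(sample = colnames(x), mean = mean(v), sd = stats::sd(v),
               stringsAsFactors = FALSE)
  } else {
    m <- apply(x, 2L, function(col) {
      v <- col[!is.na(col)]
      if (length(v) < 2L)
        .tc_stop("a sample has fewer than 2 observed values: tail distribution undefined",
                 "validation_error")
      c(mean(v), stats::sd(v))
    })
    data.frame(sample = colnames(x), mean = m[1L, ], sd = m[2L, ],
               row.names = NULL, stringsAsFactors = FALSE)
  }
}

#' Bottom-tail imputation for fully missing proteins
#'
#' Fills proteins without any valid data point by drawing, for each missing
#' cell in sample `j`, from `Normal(mean_j - downshift * sd_j,
#' (width * sd_j)^2)` where `mean_j`, `sd_j` describe the observed log2
#' intensity distribution of sample `j`. This mirrors the
#' missing-not-at-random regime of LFQ data, where absent proteins sit in the
#' low-abundance tail.
#'
#' @param x log2-scale [AbundanceMatrix()].
#' @param config an [impute_config()].
#' @param cells optional logical matrix selecting the cells to fill; defaults
#'   to all cells of fully missing proteins.
#' @return list with elements `matrix` (imputed [AbundanceMatrix()]) and
#'   `report` (counts and the per-sample distribution parameters used).
#' @export
impute_bottom_tail <- function(x, config = impute_config(), cells = NULL) {
  .assert_scale(x, "log2", "impute_bottom_tail")
  if (is.null(cells)) {
    full <- rowSums(!is.na(x)) == 0L
    cells <- is.na(x) & full
  }
  stopifnot(identical(dim(cells), dim(x)))
  if (!any(cells)) {
    report <- list(n_bottom_tail = 0L, n_lls = 0L, n_fallback = 0L,
                   tail_params = NULL)
    return(list(matrix = x, report = report))
  }
  params <- .tail_params(unclass(x), config$pooled_tail)
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- unclass(x)
  for (j in seq_len(ncol(x))) {
    idx <- which(cells[, j])
    if (!length(idx)) next
    out[idx, j] <- stats::rnorm(length(idx),
                                mean = params$mean[j] - config$downshift * params$sd[j],
                                sd = config$width * params$sd[j])
  }
  list(matrix = .with_values(x, out),
       report = list(n_bottom_tail = sum(cells), n_lls = 0L, n_fallback = 0L,
                     tail_params = params))
}

#' Local least squares imputation for partially observed proteins
#'
#' For each protein with at least one observed and one missing value,
#' candidate neighbors are proteins fully observed in the target's columns
#' (both its observed and its missing ones); they are ranked by absolute
#' Pearson correlation with the target over the target's observed columns,
#' ties broken by protein id. The top `k` neighbors enter an ordinary least
#' squares regression (with intercept) of the target on the neighbors over
#' the observed columns, and the fit predicts the missing cells. Targets with
#' too few observed values (`< min_overlap`) or no eligible neighbor fall
#' back to their observed row mean.
#'
#' @inheritParams impute_bottom_tail
#' @param neighbor_pool optional logical vector over proteins marking rows
#'   allowed to serve as neighbors (used by [impute()] to exclude
#'   bottom-tail-imputed rows from the pool).
#' @return list with `matrix` and `report` as in [impute_bottom_tail()].
#' @export
impute_lls <- function(x, config = impute_config(), neighbor_pool = NULL) {
  .assert_scale(x, "log2", "impute_lls")
  v <- unclass(x)
  na <- is.na(v)
  n_obs <- rowSums(!na)
  targets <- which(n_obs > 0L & n_obs < ncol(v))
  if (is.null(neighbor_pool)) neighbor_pool <- rep(TRUE, nrow(v))
  # a target's needed columns (observed plus missing) span the whole row, so
  # eligible neighbors are the fully complete rows of the allowed pool
  complete <- which(rowSums(na) == 0L & neighbor_pool)
  ids <- rownames(v)
  n_lls <- 0L; n_fallback <- 0L; short_k <- 0L
  if (length(targets)) {
    pat <- vapply(targets, function(i) paste(which(na[i, ]), collapse = ","),
                  "")
    for (p in unique(pat)) {
      tg <- targets[pat == p]
      M <- as.integer(strsplit(p, ",", fixed = TRUE)[[1L]])
      O <- setdiff(seq_len(ncol(v)), M)
      tg_sd0 <- vapply(tg, function(i) stats::sd(v[i, O]) == 0, TRUE)
      elig <- integer()
      if (length(O) >= max(config$min_overlap, 2L) && length(complete)) {
        Vo <- v[complete, O, drop = FALSE]
        sds2 <- rowSums((Vo - rowMeans(Vo))^2)
        elig <- complete[sds2 > 0]
      }
      do_fallback <- !length(elig) | tg_sd0
      for (i in tg[do_fallback]) v[i, M] <- mean(v[i, O])
      n_fallback <- n_fallback + sum(do_fallback) * length(M)
      fit_tg <- tg[!do_fallback]
      if (!length(fit_tg)) next
      CC <- abs(stats::cor(t(v[elig, O, drop = FALSE]),
                           t(v[fit_tg, O, drop = FALSE])))
      for (ti in seq_along(fit_tg)) {
        i <- fit_tg[ti]
        ord <- elig[order(-CC[, ti], ids[elig])]
        # cap the regression size to keep residual degrees of freedom: a fit
        # saturated to the observed points interpolates noise and
        # extrapolates wildly on the missing columns
        k_eff <- min(config$k, length(ord), max(1L, length(O) - 4L))
        if (k_eff < config$k) short_k <- short_k + 1L
        nb <- ord[seq_len(k_eff)]
        fit <- stats::lm.fit(cbind(1, t(v[nb, O, drop = FALSE])), v[i, O])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        v[i, M] <- drop(cbind(1, t(v[nb, M, drop = FALSE])) %*% beta)
        n_lls <- n_lls + length(M)
      }
    }
  }
  if (short_k > 0L)
    warning(sprintf("LLS used fewer than k = %d neighbors for %d protein(s)",
                    config$k, short_k))
  list(matrix = .with_values(x, v),
       report = list(n_bottom_tail = 0L, n_lls = n_lls,
                     n_fallback = n_fallback, tail_params = NULL))
}

#' Two-case imputation of a log2 LFQ matrix
#'
#' Dispatches fully missing proteins to [impute_bottom_tail()] and partially
#' missing proteins to [impute_lls()]; bottom-tail-imputed rows are excluded
#' from the LLS neighbor pool to avoid circularity. The result has no missing
#' cells and the report partitions every originally missing cell by
#' mechanism.
#'
#' @inheritParams impute_bottom_tail
#' @return list with `matrix` (complete [AbundanceMatrix()]) and `report`
#'   with counts `n_bottom_tail`, `n_lls`, `n_fallback` summing to the
#'   initial number of missing cells.
#' @export
impute <- function(x, config = impute_config()) {
  .assert_scale(x, "log2", "impute")
  n_missing <- sum(is.na(x))
  full_rows <- rowSums(!is.na(x)) == 0L
  bt <- impute_bottom_tail(x, config)
  ll <- impute_lls(bt$matrix, config, neighbor_pool = !full_rows)
  out <- ll$matrix
  stopifnot(sum(is.na(out)) == 0L)
  report <- list(n_bottom_tail = bt$report$n_bottom_tail,
                 n_lls = ll$report$n_lls,
                 n_fallback = ll$report$n_fallback,
                 tail_params = bt$report$tail_params)
  stopifnot(report$n_bottom_tail + report$n_lls + report$n_fallback ==
              n_missing)
  list(matrix = out, report = report)
}
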