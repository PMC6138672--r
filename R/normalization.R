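#' Log2 transform of a linear-scale abundance matrix
#'
#' @param x linear-scale [AbundanceMatrix()] with all present values > 0.
#' @return log2-scale [AbundanceMatrix()]; missing cells stay missing.
#' @export
log2_transform <- function(x) {
  .assert_scale(x, "linear", "log2_transform")
  bad <- which(!is.na(x) & unclass(x) <= 0, arr.ind = TRUE)
  if (nrow(bad))
    .tc_stop(sprintf("non-positive intensity at protein '%s', sample '%s'",
                     rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]),
             "domain_error")
  structure(log2(unclass(x)), scale = "log2",
            class = c("AbundanceMatrix", "matrix", "array"))
}

#' Quantile normalization of a complete log2 matrix
#'
#' Classical quantile normalization: in `sample` mode, the i-th smallest
#' value within each sample is replaced by the across-sample reference (mean,
#' by default) of the i-th smallest values, so that afterwards every sample
#' shares an identical sorted value vector. Tied values receive the mean of
#' the reference values at their tied ranks. `gene` mode applies the same
#' procedure along rows instead of columns, equalizing the distribution of
#' each protein across samples.
#'
#' @param x complete (imputed) log2-scale [AbundanceMatrix()].
#' @param mode `"sample"` (equalize sample distributions; default, the
#'   cross-sample comparability the downstream tests require) or `"gene"`.
#' @param reference `"mean"` or `"median"` of the sorted vectors.
#' @return normalized log2-scale [AbundanceMatrix()].
#' @export
quantile_normalize <- function(x, mode = c("sample", "gene"),
                               reference = c("mean", "median")) {
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  .assert_scale(x, "log2", "quantile_normalize")
  if (anyNA(x))
    .tc_stop("matrix has missing cells: impute before quantile normalization",
             "state_error")
  v <- unclass(x)
  norm <- if (mode == "sample") .qnorm_columns(v, reference)
          else t(.qnorm_columns(t(v), reference))
  dimnames(norm) <- dimnames(v)
  .with_values(x, norm)
}

.qnorm_columns <- function(v, reference) {
  sorted <- apply(v, 2L, sort)
  ref <- if (reference == "mean") rowMeans(sorted)
         else apply(sorted, 1L, stats::median)
  out <- v
  for (j in seq_len(ncol(v))) {
    o <- order(v[, j])
    # ties share the mean of the reference values over their tied ranks
    out[o, j] <- stats::ave(ref, match(v[o, j], v[o, j]), FUN = mean)
  }
  out
}
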