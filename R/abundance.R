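#' Protein abundance matrix with explicit missingness
#'
#' Container for a proteins-by-samples intensity grid in the style of
#' label-free quantification (LFQ) output. Missing quantifications are stored
#' as `NA`, never as zero: MaxQuant-style exports use 0 for "not quantified",
#' so zeros are converted to `NA` on construction in linear scale. A scale
#' flag records whether values are raw intensities (`"linear"`) or
#' log2-transformed.
#'
#' @param values numeric matrix with unique, non-empty rownames (protein ids)
#'   and colnames (sample ids). `NA` marks missing cells.
#' @param scale `"linear"` or `"log2"`.
#' @return An `AbundanceMatrix`: the matrix with attributes `scale`.
#' @export
#' @examples
#' m <- matrix(c(100, 200, 0, 400), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' am <- AbundanceMatrix(m)        # the 0 becomes NA
#' sum(is.na(am))
AbundanceMatrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    .tc_stop("'values' must be a numeric matrix", "validation_error")
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid) || anyNA(pid) || anyNA(sid) ||
      any(pid == "") || any(sid == ""))
    .tc_stop("matrix must carry non-empty protein and sample ids", "validation_error")
  if (anyDuplicated(pid))
    .tc_stop(paste0("duplicate protein ids: ",
                    paste(unique(pid[duplicated(pid)]), collapse = ", ")),
             "validation_error")
  if (anyDuplicated(sid))
    .tc_stop(paste0("duplicate sample ids: ",
                    paste(unique(sid[duplicated(sid)]), collapse = ", ")),
             "validation_error")
  if (scale == "linear") {
    values[!is.na(values) & values == 0] <- NA_real_
    if (any(values < 0, na.rm = TRUE))
      .tc_stop("negative intensity in linear scale", "validation_error")
  }
  structure(values, scale = scale, class = c("AbundanceMatrix", "matrix", "array"))
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  cat(sprintf("AbundanceMatrix: %d proteins x %d samples [%s scale], %d missing cells\n",
              nrow(x), ncol(x), abundance_scale(x), sum(is.na(x))))
  if (nrow(x) > 0) {
    show <- unclass(x)[seq_len(min(5L, nrow(x))), , drop = FALSE]
    attr(show, "scale") <- NULL
    print(show, ...)
    if (nrow(x) > 5L) cat(sprintf("... and %d more proteins\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' @rdname AbundanceMatrix
#' @param x an `AbundanceMatrix`.
#' @export
abundance_scale <- function(x) attr(x, "scale")

#' @rdname AbundanceMatrix
#' @export
is_abundance_matrix <- function(x) inherits(x, "AbundanceMatrix")

# keep class and scale through subsetting used internally
.with_values <- function(x, values) {
  structure(values, scale = abundance_scale(x),
            class = c("AbundanceMatrix", "matrix", "array"))
}

.assert_scale <- function(x, scale, what) {
  if (!is_abundance_matrix(x))
    .tc_stop(paste0(what, ": input must be an AbundanceMatrix"), "state_error")
  if (!identical(abundance_scale(x), scale))
    .tc_stop(sprintf("%s requires a %s-scale matrix (got %s)",
                     what, scale, abundance_scale(x)), "state_error")
  invisible(TRUE)
}

#' Sample design: group and replicate structure of an LFQ experiment
#'
#' Maps each sample to its siRNA treatment group and replicate index. Exactly
#' one group is the non-targeting control; every other group is a targeting
#' (knockdown) group contrasted against it.
#'
#' @param sample character vector of sample ids.
#' @param group character vector of group labels, same length.
#' @param control the control group label (must occur in `group`).
#' @param replicate optional integer replicate indices; derived per group if
#'   omitted.
#' @return A `SampleDesign` data.frame with columns `sample`, `group`,
#'   `replicate` and attribute `control`.
#' @export
#' @examples
#' SampleDesign(sample = paste0("s", 1:9),
#'              group = rep(c("ctrl", "siRNA1", "siRNA2"), each = 3),
#'              control = "ctrl")
SampleDesign <- function(sample, group, control, replicate = NULL) {
  sample <- as.character(sample)
  group <- as.character(group)
  if (length(sample) != length(group))
    .tc_stop("'sample' and 'group' lengths differ", "validation_error")
  if (anyDuplicated(sample))
    .tc_stop("duplicate sample ids in design", "validation_error")
  if (!control %in% group)
    .tc_stop(sprintf("control group '%s' absent from design", control),
             "validation_error")
  if (length(unique(group)) < 2L)
    .tc_stop("design needs at least one targeting group besides the control",
             "validation_error")
  if (any(table(group) < 2L))
    .tc_stop("every group needs >= 2 replicates for testing", "validation_error")
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(group), group, FUN = seq_along)
  out <- data.frame(sample = sample, group = group,
                    replicate = as.integer(replicate),
                    stringsAsFactors = FALSE)
  structure(out, control = control, class = c("SampleDesign", "data.frame"))
}

#' @rdname SampleDesign
#' @param design a `SampleDesign`.
#' @export
control_group <- function(design) attr(design, "control")

#' @rdname SampleDesign
#' @export
targeting_groups <- function(design)
  setdiff(unique(design$group), control_group(design))

# check that a design covers exactly the samples of a matrix
.match_design <- function(x, design) {
  if (!setequal(design$sample, colnames(x)) ||
      length(design$sample) != ncol(x))
    .tc_stop("design samples do not match matrix samples one-to-one",
             "validation_error")
  invisible(TRUE)
}
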