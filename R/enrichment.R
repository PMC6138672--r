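#' Annotation-category enrichment of an affected set
#'
#' Enrichment factor of a binary annotation category in an affected protein
#' set relative to the quantified background:
#' `factor = (k / n) / (K / N)` with `k` of `n` affected proteins annotated
#' and `K` of `N` background proteins annotated. Significance is the
#' upper-tail hypergeometric probability of drawing at least `k` annotated
#' proteins in `n` draws from the background. The paper-style summary reports
#' only the fold factor; the test is an addition of this implementation and
#' is labelled as such in the output column name `p_hypergeometric`.
#'
#' @param affected_ids character vector of affected proteins (must be a
#'   subset of `background_ids`).
#' @param background_ids character vector: the quantified background
#'   universe.
#' @param annotations data.frame with `protein_id` and logical category
#'   columns, as from [read_annotation_table()]. Proteins absent from the
#'   table count as unannotated.
#' @param category name of the category column.
#' @return one-row data.frame with `category`, `k`, `n`, `K`, `N`, `factor`,
#'   `p_hypergeometric`.
#' @export
enrichment_factor <- function(affected_ids, background_ids, annotations,
                              category) {
  if (length(affected_ids) == 0L || length(background_ids) == 0L)
    .tc_stop("affected and background sets must be non-empty",
             "validation_error")
  if (!all(affected_ids %in% background_ids))
    .tc_stop("affected set is not a subset of the background",
             "validation_error")
  if (!category %in% setdiff(names(annotations), "protein_id"))
    .tc_stop(sprintf("category '%s' not in annotation vocabulary", category),
             "validation_error")
  annotated <- annotations$protein_id[annotations[[category]] %in% TRUE]
  n <- length(unique(affected_ids))
  N <- length(unique(background_ids))
  k <- sum(unique(affected_ids) %in% annotated)
  K <- sum(unique(background_ids) %in% annotated)
  if (K == 0L) {
    fac <- NA_real_
    p <- 1
  } else {
    fac <- (k / n) / (K / N)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  }
  data.frame(category = category, k = k, n = n, K = K, N = N,
             factor = fac, p_hypergeometric = p, stringsAsFactors = FALSE)
}

#' Enrichment report over categories and affected sets
#'
#' One enrichment record per annotation category and per affected set
#' (negative and positive), with Benjamini-Hochberg correction across the
#' whole table.
#'
#' @param affected_sets an `AffectedSets` from [call_affected()], or a named
#'   list of protein id vectors.
#' @param background_ids the quantified background universe.
#' @param annotations data.frame as in [enrichment_factor()].
#' @param categories category columns to test; default every annotation
#'   column.
#' @return data.frame of enrichment records with an added `set` column and
#'   `p_adjusted` (BH).
#' @export
enrichment_report <- function(affected_sets, background_ids, annotations,
                              categories = NULL) {
  if (inherits(affected_sets, "AffectedSets"))
    affected_sets <- list(negative = affected_sets$negatively_affected,
                          positive = affected_sets$positively_affected)
  stopifnot(is.list(affected_sets), !is.null(names(affected_sets)))
  if (is.null(categories))
    categories <- setdiff(names(annotations), "protein_id")
  rows <- list()
  for (set_name in names(affected_sets)) {
    ids <- affected_sets[[set_name]]
    for (cat in categories) {
      if (length(ids) == 0L) {
        rec <- data.frame(category = cat, k = 0L, n = 0L,
                          K = NA_integer_, N = length(unique(background_ids)),
                          factor = NA_real_, p_hypergeometric = 1,
                          stringsAsFactors = FALSE)
      } else {
        rec <- enrichment_factor(ids, background_ids, annotations, cat)
      }
      rec$set <- set_name
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_hypergeometric, method = "BH")
  out
}
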