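#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values for the 20 standard amino acids, from the
#' classic Kyte-Doolittle propensity scale (isoleucine 4.5 down to
#' arginine -4.5). Positive values are hydrophobic.
#'
#' @format Named numeric vector of length 20.
#' @export
kyte_doolittle <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

.check_seq <- function(sequence, scale_letters = .AA20) {
  if (any(is.na(sequence)) || any(nchar(sequence) == 0L))
    .tc_stop("empty sequence", "validation_error")
  chars <- strsplit(sequence, "")
  for (i in seq_along(chars)) {
    bad <- setdiff(chars[[i]], scale_letters)
    if (length(bad))
      .tc_stop(sprintf("sequence %d: non-standard residue(s) %s",
                       i, paste(bad, collapse = ", ")), "validation_error")
  }
  chars
}

#' Glycine-plus-proline content of a sequence
#'
#' The fraction of residues that are glycine or proline, as a percentage of
#' sequence length. High GP content is used as a proxy for low helix
#' propensity of signal peptides; sequences above the 15% threshold are
#' candidate TRAP clients (see [classify_gp()]).
#'
#' @param sequence character vector of amino-acid sequences (uppercase,
#'   standard 20-letter alphabet).
#' @return numeric vector in `[0, 100]`, full precision (round for display
#'   with [round_half_up()]).
#' @export
#' @examples
#' gp_content("GPGP")   # 100
#' gp_content("MKVA")   # 0
gp_content <- function(sequence) {
  chars <- .check_seq(sequence)
  vapply(chars, function(ch) 100 * sum(ch %in% c("G", "P")) / length(ch), 0)
}

#' Mean hydrophobicity of a sequence
#'
#' Arithmetic mean of per-residue hydropathy values over the full sequence
#' length, by default on the Kyte-Doolittle scale. Order-invariant.
#'
#' @param sequence character vector of amino-acid sequences.
#' @param scale named numeric vector mapping every residue that occurs in
#'   `sequence` to a hydropathy value; defaults to [kyte_doolittle].
#' @return numeric vector bounded by `range(scale)`.
#' @export
#' @examples
#' hydrophobicity("LLLL")  # 3.8
hydrophobicity <- function(sequence, scale = kyte_doolittle) {
  chars <- .check_seq(sequence, scale_letters = names(scale))
  vapply(chars, function(ch) mean(scale[ch]), 0)
}

#' Classify sequences by GP content
#'
#' Strict threshold rule: `high_gp` iff GP content exceeds `threshold`
#' (default 15%); a value exactly at the threshold is `low_gp`.
#'
#' @param gp_percent numeric GP content values (0-100), e.g. from
#'   [gp_content()] or the `gp_percent` column of [read_sp_table()] output.
#' @param threshold classification cutoff in percent.
#' @return factor with levels `low_gp`, `high_gp`.
#' @export
classify_gp <- function(gp_percent, threshold = 15) {
  stopifnot(is.numeric(gp_percent), all(gp_percent >= 0 & gp_percent <= 100))
  factor(ifelse(gp_percent > threshold, "high_gp", "low_gp"),
         levels = c("low_gp", "high_gp"))
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test: exact by enumeration for
#' small tie-free samples (total n <= 12), otherwise the normal approximation
#' with tie correction and continuity correction (as in [stats::wilcox.test()],
#' which provides the machinery).
#'
#' @param values_a,values_b numeric vectors, each non-empty.
#' @return list with `statistic` (rank-sum W of group a), `p_value`, `n_a`,
#'   `n_b`.
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    .tc_stop("both groups must be non-empty", "validation_error")
  exact <- (length(values_a) + length(values_b)) <= 12L &&
    !anyDuplicated(c(values_a, values_b))
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(values_a), n_b = length(values_b))
}

#' Compare a sequence feature between client and background cohorts
#'
#' Summarizes a physicochemical feature (GP content or hydrophobicity) in a
#' client set versus a background set: group sizes, means, medians, the
#' client/background mean ratio, and a two-sided Wilcoxon rank-sum p-value.
#'
#' @param records_clients,records_background data.frames of signal-peptide
#'   records as returned by [read_sp_table()].
#' @param feature `"gp_percent"` or `"hydrophobicity"`.
#' @return one-row data.frame (a feature comparison record).
#' @export
feature_report <- function(records_clients, records_background,
                           feature = c("gp_percent", "hydrophobicity")) {
  feature <- match.arg(feature)
  a <- records_clients[[feature]]
  b <- records_background[[feature]]
  if (is.null(a) || is.null(b) || length(a) == 0L || length(b) == 0L)
    .tc_stop("both record sets must be non-empty and carry the feature",
             "validation_error")
  w <- wilcoxon_rank_sum(a, b)
  data.frame(feature = feature,
             n_clients = length(a), n_background = length(b),
             mean_clients = mean(a), mean_background = mean(b),
             median_clients = stats::median(a),
             median_background = stats::median(b),
             mean_ratio = mean(a) / mean(b),
             statistic = w$statistic, p_value = w$p_value,
             stringsAsFactors = FALSE)
}
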