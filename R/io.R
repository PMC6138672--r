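#' Read a protein intensity table
#'
#' Reads a TSV in the shape of MaxQuant-style LFQ output: a header row of
#' sample ids, first column of protein ids, remaining cells intensities.
#' Blank cells, the declared missing tokens, and literal zeros all become
#' missing (`NA`): LFQ exports write 0 for "not quantified", and the pipeline
#' treats absences, not zeros.
#'
#' @param path TSV file path.
#' @param missing_tokens character tokens (besides numeric 0) that mark a
#'   missing cell.
#' @return A linear-scale [AbundanceMatrix()].
#' @export
read_abundance_table <- function(path, missing_tokens = c("", "NA", "NaN")) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L || !grepl("\t", lines[[1L]]))
    .tc_stop(sprintf("%s: malformed header at line 1 (no tab-separated sample ids)",
                     path), "parse_error")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  if (length(samples) < 1L || any(samples == ""))
    .tc_stop(sprintf("%s: malformed header at line 1 (empty sample id)", path),
             "parse_error")
  n <- length(lines) - 1L
  values <- matrix(NA_real_, nrow = n, ncol = length(samples))
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    # trailing empty fields are dropped by strsplit; pad them back
    length(f) <- length(header)
    f[is.na(f)] <- ""
    ids[i] <- f[[1L]]
    cells <- f[-1L]
    miss <- cells %in% missing_tokens
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(!miss & is.na(num))
    if (length(bad))
      .tc_stop(sprintf("%s: non-numeric cell '%s' at line %d, column '%s'",
                       path, cells[bad[1L]], i + 1L, samples[bad[1L]]),
               "parse_error")
    num[miss] <- NA_real_
    values[i, ] <- num
  }
  if (anyDuplicated(ids))
    .tc_stop(sprintf("%s: duplicate protein ids: %s", path,
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "validation_error")
  dimnames(values) <- list(ids, samples)
  AbundanceMatrix(values, scale = "linear")
}

#' Write an abundance matrix as TSV
#'
#' Missing cells are written as the empty string; a round trip through
#' [read_abundance_table()] restores values, missingness and ordering.
#'
#' @param x an [AbundanceMatrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(is_abundance_matrix(x))
  cells <- format(unclass(x), digits = 15, trim = TRUE, scientific = FALSE)
  cells[is.na(x)] <- ""
  lines <- c(paste(c("protein_id", colnames(x)), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i)
               paste(c(rownames(x)[i], cells[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample`, `group` and optionally `replicate`.
#' @param control label of the control (non-targeting siRNA) group.
#' @return A [SampleDesign()].
#' @export
read_sample_design <- function(path, control) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(d)))
    .tc_stop(sprintf("%s: design needs 'sample' and 'group' columns", path),
             "parse_error")
  SampleDesign(d$sample, d$group, control = control,
               replicate = if ("replicate" %in% names(d)) d$replicate)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.validate_sequences <- function(seqs, ids) {
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (is.na(s) || nchar(s) == 0L)
      .tc_stop(sprintf("record '%s': empty sequence", ids[[i]]),
               "validation_error")
    ch <- strsplit(s, "")[[1L]]
    bad <- setdiff(ch, .AA20)
    if (length(bad))
      .tc_stop(sprintf("record '%s': non-standard residue(s) %s", ids[[i]],
                       paste(bad, collapse = ", ")), "validation_error")
  }
  invisible(TRUE)
}

#' Read a signal-peptide / transmembrane-helix sequence table
#'
#' Accepts either a TSV with columns `protein_id` (or `id`), `gene`,
#' `sequence`, `kind` (`SP` or `TMH`), `tm`, `nglyc`, or a FASTA file whose
#' headers carry `id|gene|kind|tm|nglyc`. Sequences are validated against the
#' 20-letter amino-acid alphabet; GP content and Kyte-Doolittle
#' hydrophobicity are computed on load.
#'
#' @param path TSV or FASTA file.
#' @param format `"auto"` (by extension/content), `"tsv"` or `"fasta"`.
#' @return data.frame of signal-peptide records with computed columns
#'   `gp_percent` and `hydrophobicity`.
#' @export
read_sp_table <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      .tc_stop("FASTA input requires the Biostrings package", "state_error")
    aa <- Biostrings::readAAStringSet(path)
    if (length(aa) == 0L) {
      warning("empty sequence file: ", path)
      return(.sp_records(character(), character(), character(),
                         character(), logical(), logical()))
    }
    parts <- strsplit(names(aa), "|", fixed = TRUE)
    if (any(lengths(parts) < 5L))
      .tc_stop(sprintf("%s: FASTA headers must be 'id|gene|kind|tm|nglyc'",
                       path), "parse_error")
    f <- function(k) vapply(parts, `[[`, "", k)
    return(.sp_records(f(1), f(2), as.character(aa), f(3),
                       toupper(f(4)) %in% c("TRUE", "+", "1"),
                       toupper(f(5)) %in% c("TRUE", "+", "1")))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) {
    warning("empty sequence file: ", path)
    return(.sp_records(character(), character(), character(),
                       character(), logical(), logical()))
  }
  if ("id" %in% names(d) && !"protein_id" %in% names(d))
    names(d)[names(d) == "id"] <- "protein_id"
  need <- c("protein_id", "gene", "sequence", "kind", "tm", "nglyc")
  if (!all(need %in% names(d)))
    .tc_stop(sprintf("%s: sequence table needs columns %s", path,
                     paste(need, collapse = ", ")), "parse_error")
  .sp_records(d$protein_id, d$gene, d$sequence, d$kind,
              as.logical(d$tm), as.logical(d$nglyc))
}

.sp_records <- function(id, gene, sequence, kind, tm, nglyc) {
  if (length(id) && !all(kind %in% c("SP", "TMH")))
    .tc_stop("kind must be 'SP' or 'TMH'", "validation_error")
  .validate_sequences(sequence, id)
  data.frame(protein_id = id, gene = gene, sequence = sequence, kind = kind,
             tm_flag = tm, nglyc_flag = nglyc,
             gp_percent = if (length(id)) gp_content(sequence) else numeric(),
             hydrophobicity = if (length(id)) hydrophobicity(sequence) else numeric(),
             stringsAsFactors = FALSE)
}

#' Read a binary annotation table
#'
#' @param path TSV with a `protein_id` column and one logical/0-1 column per
#'   annotation category (e.g. `signal_peptide`, `membrane`, `nglyc`,
#'   `secretory_pathway`).
#' @return data.frame with `protein_id` and logical category columns.
#' @export
read_annotation_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(d))
    .tc_stop(sprintf("%s: annotation table needs a 'protein_id' column", path),
             "parse_error")
  if (anyDuplicated(d$protein_id))
    .tc_stop(sprintf("%s: duplicate protein ids in annotation table", path),
             "validation_error")
  for (cc in setdiff(names(d), "protein_id")) d[[cc]] <- as.logical(d[[cc]])
  d
}

#' Write result tables with a manifest
#'
#' Writes each table as TSV with a fixed column order (the data.frame's own
#' order) and returns a manifest of files, row counts and content hashes.
#' Re-running on identical input yields byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @return data.frame manifest with columns `file`, `rows`, `md5`.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    .tc_stop(sprintf("cannot create output directory '%s'", out_dir), "io_error")
  files <- file.path(out_dir, paste0(names(tables), ".tsv"))
  for (i in seq_along(tables)) {
    utils::write.table(tables[[i]], files[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  data.frame(file = basename(files),
             rows = vapply(tables, nrow, 0L),
             md5 = unname(tools::md5sum(files)),
             row.names = NULL, stringsAsFactors = FALSE)
}
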