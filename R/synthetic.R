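#' Configuration for the synthetic LFQ dataset generator
#'
#' Describes a knockdown-style label-free proteomics experiment: one control
#' group and two targeting-siRNA groups, three replicates each. Protein
#' baselines are log-normal (normal in log2), replicate noise is additive in
#' log2 (multiplicative in intensity), knockdown effects are shared by both
#' targeting groups, off-target decoys are specific to a single targeting
#' group, and compensatory proteins move up. Missingness is
#' missing-not-at-random via a logistic model in log2 intensity, the regime
#' bottom-tail imputation assumes.
#'
#' @param n_proteins number of proteins.
#' @param groups targeting group labels (the control is `control`).
#' @param control control group label.
#' @param n_replicates replicates per group.
#' @param baseline_mean,baseline_sd log2 baseline distribution across
#'   proteins.
#' @param noise_sd replicate noise standard deviation in log2 units.
#' @param n_clients,client_log2fc planted knockdown clients shared by both
#'   targeting groups (default 60 clients at -1 log2 fold change).
#' @param n_offtarget,offtarget_log2fc decoys planted per targeting group
#'   only in that group.
#' @param n_positive,positive_log2fc compensatory proteins planted with a
#'   positive fold change in both targeting groups (default +0.5, emulating
#'   SRP-receptor-style up-regulation).
#' @param miss_midpoint,miss_slope logistic missingness:
#'   `P(missing | x) = plogis((miss_midpoint - x) / miss_slope)` for log2
#'   intensity `x`. Defaults: midpoint two baseline standard deviations below
#'   the baseline mean, slope 1. `miss_slope = 0` disables missingness.
#' @param seed integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 2000L,
                         groups = c("siRNA1", "siRNA2"),
                         control = "control",
                         n_replicates = 3L,
                         baseline_mean = 25, baseline_sd = 2,
                         noise_sd = 0.25,
                         n_clients = 60L, client_log2fc = -1,
                         n_offtarget = 20L, offtarget_log2fc = -1,
                         n_positive = 15L, positive_log2fc = 0.5,
                         miss_midpoint = baseline_mean - 2 * baseline_sd,
                         miss_slope = 1,
                         seed = 1L) {
  stopifnot(n_proteins >= 1, n_replicates >= 2, baseline_sd > 0,
            noise_sd > 0, length(groups) >= 1, miss_slope >= 0,
            n_clients >= 0, n_offtarget >= 0, n_positive >= 0)
  if (n_clients + n_positive + n_offtarget * length(groups) > n_proteins)
    .tc_stop("planted protein classes exceed n_proteins", "validation_error")
  cfg <- mget(names(formals()))
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic LFQ knockdown dataset
#'
#' @param config a [synth_config()].
#' @return list with `matrix` (linear-scale [AbundanceMatrix()] with `NA`
#'   missingness), `design` (a [SampleDesign()]) and `truth` (data.frame with
#'   per-protein class — `null`, `client_negative`, `compensatory_positive`,
#'   or `offtarget_<group>` — and true per-group log2 fold changes).
#'   Identical config (including seed) gives an identical dataset.
#' @export
generate_lfq_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  cg <- config$groups
  ids <- sprintf("PROT%05d", seq_len(config$n_proteins))
  cls <- rep("null", config$n_proteins)
  at <- 0L
  take <- function(n) {
    idx <- at + seq_len(n)
    at <<- at + n
    idx
  }
  cls[take(config$n_clients)] <- "client_negative"
  cls[take(config$n_positive)] <- "compensatory_positive"
  for (g in cg) cls[take(config$n_offtarget)] <- paste0("offtarget_", g)

  fc <- matrix(0, config$n_proteins, length(cg),
               dimnames = list(ids, cg))
  fc[cls == "client_negative", ] <- config$client_log2fc
  fc[cls == "compensatory_positive", ] <- config$positive_log2fc
  for (g in cg)
    fc[cls == paste0("offtarget_", g), g] <- config$offtarget_log2fc

  all_groups <- c(config$control, cg)
  samples <- paste(rep(all_groups, each = config$n_replicates),
                   seq_len(config$n_replicates), sep = "_")
  design <- SampleDesign(sample = samples,
                         group = rep(all_groups, each = config$n_replicates),
                         control = config$control)

  baseline <- stats::rnorm(config$n_proteins, config$baseline_mean,
                           config$baseline_sd)
  log2v <- matrix(NA_real_, config$n_proteins, length(samples),
                  dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    g <- design$group[j]
    eff <- if (g == config$control) 0 else fc[, g]
    log2v[, j] <- baseline + eff +
      stats::rnorm(config$n_proteins, 0, config$noise_sd)
  }
  if (config$miss_slope > 0) {
    p_miss <- stats::plogis((config$miss_midpoint - log2v) / config$miss_slope)
    miss <- matrix(stats::runif(length(log2v)) < p_miss, nrow(log2v))
    log2v[miss] <- NA_real_
  }
  linear <- 2^log2v
  truth <- data.frame(protein_id = ids, class = cls, fc,
                      row.names = NULL, stringsAsFactors = FALSE)
  names(truth)[-(1:2)] <- paste0("fc_", cg)
  list(matrix = AbundanceMatrix(linear, scale = "linear"),
       design = design, truth = truth)
}

# approximate human amino-acid background frequencies, glycine and proline
# removed and renormalized; used for non-GP positions of synthetic peptides
.bg_residues <- local({
  f <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, E = 7.1, Q = 4.8,
         H = 2.6, I = 4.3, L = 10.0, K = 5.7, M = 2.1, F = 3.7, S = 8.3,
         T = 5.4, W = 1.2, Y = 2.7, V = 6.0)
  f / sum(f)
})

#' Generate a synthetic signal-peptide cohort
#'
#' Sequences with a controlled expected GP content: each position is glycine
#' or proline with probability `gp_target_percent / 100` (equal split),
#' otherwise a residue drawn from a fixed non-GP background frequency table.
#' Useful for testing feature comparisons with a known planted effect.
#'
#' @param n number of records.
#' @param length_range integer range of sequence lengths (uniform).
#' @param gp_target_percent expected GP content in percent.
#' @param seed integer seed.
#' @param prefix id prefix for the synthetic records.
#' @return data.frame of signal-peptide records with computed features.
#' @export
generate_sp_cohort <- function(n, length_range = c(15L, 40L),
                               gp_target_percent = 15, seed = 1L,
                               prefix = "SYNSP") {
  if (gp_target_percent < 0 || gp_target_percent > 100)
    .tc_stop("gp_target_percent must be in [0, 100]", "validation_error")
  set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    is_gp <- stats::runif(L) < gp_target_percent / 100
    ch <- character(L)
    ch[is_gp] <- sample(c("G", "P"), sum(is_gp), replace = TRUE)
    ch[!is_gp] <- sample(names(.bg_residues), sum(!is_gp), replace = TRUE,
                         prob = .bg_residues)
    paste(ch, collapse = "")
  }, "")
  .sp_records(id = sprintf("%s%04d", prefix, seq_len(n)),
              gene = sprintf("%s%04d", prefix, seq_len(n)),
              sequence = seqs, kind = rep("SP", n),
              tm = rep(FALSE, n), nglyc = rep(FALSE, n))
}

.scenarios <- c("null", "default_knockdown", "offtarget_stress")

.scenario_config <- function(scenario, seed) {
  switch(scenario,
    null = synth_config(n_clients = 0L, n_offtarget = 0L, n_positive = 0L,
                        seed = seed),
    default_knockdown = synth_config(seed = seed),
    offtarget_stress = synth_config(n_offtarget = 60L,
                                    offtarget_log2fc = -1.5, seed = seed),
    .tc_stop(sprintf("unknown scenario '%s' (use %s)", scenario,
                     paste(.scenarios, collapse = ", ")),
             "validation_error"))
}

#' Write a ready-to-run synthetic fixture bundle
#'
#' Generates a scenario dataset and writes every input the pipeline needs:
#' intensity matrix, sample design, annotations, signal-peptide table, the
#' ground truth, and a YAML run configuration. Regeneration with the same
#' scenario and seed is byte-identical.
#'
#' Scenarios: `"null"` (no planted effects), `"default_knockdown"` (the
#' standard study shape: 60 clients at -1 log2FC shared by both targeting
#' groups, 20 off-target decoys per group, 15 compensatory positives), and
#' `"offtarget_stress"` (more and stronger decoys).
#'
#' @param scenario scenario name.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return invisible character vector of the files written.
#' @export
end_to_end_fixture <- function(scenario, out_dir, seed = 1L) {
  cfg <- .scenario_config(scenario, seed)
  ds <- generate_lfq_dataset(cfg)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  write_abundance_table(ds$matrix, file.path(out_dir, "matrix.tsv"))
  utils::write.table(as.data.frame(ds$design),
                     file.path(out_dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # annotations: clients are enriched for secretory-pathway categories
  set.seed(.stage_seed(seed, "annotations"))
  ids <- ds$truth$protein_id
  client <- ds$truth$class == "client_negative"
  p_cat <- function(p_client, p_bg) ifelse(client, p_client, p_bg)
  ann <- data.frame(
    protein_id = ids,
    signal_peptide = stats::runif(length(ids)) < p_cat(0.65, 0.10),
    membrane = stats::runif(length(ids)) < p_cat(0.40, 0.15),
    nglyc = stats::runif(length(ids)) < p_cat(0.50, 0.10),
    secretory_pathway = stats::runif(length(ids)) < p_cat(0.70, 0.25),
    stringsAsFactors = FALSE)
  utils::write.table(ann, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # signal peptides: high-GP cohort for clients, baseline cohort otherwise
  n_cl <- sum(client)
  sp_cl <- if (n_cl > 0)
    generate_sp_cohort(n_cl, gp_target_percent = 22.5,
                       seed = .stage_seed(seed, "sp_clients"))
  sp_bg <- generate_sp_cohort(300L, gp_target_percent = 15,
                              seed = .stage_seed(seed, "sp_background"))
  if (n_cl > 0) {
    sp_cl$protein_id <- ids[client]
    sp_cl$gene <- ids[client]
  }
  sp <- rbind(sp_cl, sp_bg)
  names(sp)[names(sp) == "tm_flag"] <- "tm"
  names(sp)[names(sp) == "nglyc_flag"] <- "nglyc"
  utils::write.table(sp, file.path(out_dir, "sp_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  run_cfg <- list(
    seed = seed,
    input = list(matrix = "matrix.tsv", design = "design.tsv",
                 control = cfg$control, annotations = "annotations.tsv",
                 sp_table = "sp_table.tsv"),
    impute = list(downshift = 1.8, width = 0.3, k = 10L, min_overlap = 3L,
                  pooled_tail = FALSE),
    normalize = list(mode = "sample", reference = "mean"),
    diff = list(alpha = 0.05, statistic = "student_t",
                permutations = "exhaustive"),
    features = list(threshold = 15))
  yaml::write_yaml(run_cfg, file.path(out_dir, "run.yaml"))

  invisible(file.path(out_dir, c("matrix.tsv", "design.tsv", "truth.tsv",
                                 "annotations.tsv", "sp_table.tsv",
                                 "run.yaml")))
}
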