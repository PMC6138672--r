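# small builders shared across the suite

make_am <- function(values, nr, nc, scale = "log2",
                    ids = sprintf("P%03d", seq_len(nr)),
                    samples = sprintf("s%d", seq_len(nc))) {
  m <- matrix(values, nr, nc, dimnames = list(ids, samples))
  AbundanceMatrix(m, scale = scale)
}

# Gaussian log2 matrix with per-protein baselines, optional fully missing rows
gaussian_log2 <- function(n, k, seed, baseline_mean = 25, baseline_sd = 2,
                          noise_sd = 0.25, n_full_missing = 0) {
  set.seed(seed)
  base <- rnorm(n, baseline_mean, baseline_sd)
  v <- base + matrix(rnorm(n * k, 0, noise_sd), n, k)
  dimnames(v) <- list(sprintf("P%04d", seq_len(n)), sprintf("s%d", seq_len(k)))
  if (n_full_missing > 0) v[seq_len(n_full_missing), ] <- NA_real_
  AbundanceMatrix(v, scale = "log2")
}

design_3x3 <- function(groups = c("control", "siRNA1", "siRNA2")) {
  SampleDesign(sample = paste(rep(groups, each = 3), 1:3, sep = "_"),
               group = rep(groups, each = 3), control = "control")
}

run_knockdown_pipeline <- function(seed, scenario_cfg = synth_config(seed = seed),
                                   statistic = "moderated_d") {
  ds <- generate_lfq_dataset(scenario_cfg)
  imp <- suppressWarnings(impute(log2_transform(ds$matrix),
                                 impute_config(seed = seed + 5000L)))
  nm <- quantile_normalize(imp$matrix)
  tc <- test_config(statistic = statistic)
  contrasts <- lapply(targeting_groups(ds$design), function(g)
    permutation_fdr(nm, ds$design, g, tc))
  names(contrasts) <- targeting_groups(ds$design)
  list(dataset = ds, contrasts = contrasts,
       affected = call_affected(contrasts))
}

# curated printed peptide tables shipped with the package
peptide_table <- function() {
  read.delim(system.file("extdata", "trap_client_peptides.tsv",
                         package = "trapclient"),
             stringsAsFactors = FALSE)
}
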