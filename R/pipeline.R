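#' Run the full client-calling pipeline
#'
#' Orchestrates one reproducible run: load (or synthesize) an intensity
#' matrix, log2 transform, impute, quantile normalize, test each targeting
#' contrast with permutation FDR, intersect the calls into affected sets,
#' and — when the inputs are provided — compare signal-peptide features
#' between called clients and the background and compute annotation
#' enrichment factors. All result tables are written as TSV with a manifest
#' of files, row counts and md5 hashes; identical config and seed give an
#' identical manifest.
#'
#' One global seed deterministically derives per-stage seeds so that stages
#' can be re-run in isolation.
#'
#' @param config run configuration: a YAML file path or an equivalent nested
#'   list with sections `input` (paths `matrix`, `design`, `control`, and
#'   optionally `annotations`, `sp_table`; or `scenario` for synthetic
#'   input), `impute`, `normalize`, `diff`, `features`, and a global `seed`.
#' @param out_dir output directory for result tables and the manifest.
#' @param quiet suppress stage messages.
#' @return list of class `trap_run` with elements `affected`
#'   ([call_affected()] output), `contrasts`, `tables`, `report` (imputation
#'   report), `manifest` and `manifest_hash`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
    config$.base <- base
  }
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  resolve <- function(p)
    if (!is.null(config$.base) && !file.exists(p))
      file.path(config$.base, p) else p

  inp <- config$input
  if (!is.null(inp$scenario)) {
    ds <- generate_lfq_dataset(.scenario_config(inp$scenario,
                                                .stage_seed(seed, "synth")))
    mat <- ds$matrix; design <- ds$design
    annotations <- NULL; sp <- NULL
    say("synth: scenario '%s', %d proteins x %d samples", inp$scenario,
        nrow(mat), ncol(mat))
  } else {
    mat <- read_abundance_table(resolve(inp$matrix))
    design <- read_sample_design(resolve(inp$design), control = inp$control)
    annotations <- if (!is.null(inp$annotations))
      read_annotation_table(resolve(inp$annotations))
    sp <- if (!is.null(inp$sp_table)) read_sp_table(resolve(inp$sp_table))
    say("load: %d proteins x %d samples (%d missing cells)",
        nrow(mat), ncol(mat), sum(is.na(mat)))
  }
  .match_design(mat, design)

  icfg <- do.call(impute_config, c(config$impute,
                                   list(seed = .stage_seed(seed, "impute"))))
  imp <- impute(log2_transform(mat), icfg)
  say("impute: %d bottom-tail, %d LLS, %d fallback cells",
      imp$report$n_bottom_tail, imp$report$n_lls, imp$report$n_fallback)

  ncfg <- config$normalize
  norm <- quantile_normalize(imp$matrix,
                             mode = if (is.null(ncfg$mode)) "sample" else ncfg$mode,
                             reference = if (is.null(ncfg$reference)) "mean" else ncfg$reference)

  dcfg <- config$diff
  tcfg <- test_config(
    alpha = if (is.null(dcfg$alpha)) 0.05 else dcfg$alpha,
    statistic = if (is.null(dcfg$statistic)) "student_t" else dcfg$statistic,
    s0 = dcfg$s0,
    permutations = if (is.null(dcfg$permutations)) "exhaustive" else dcfg$permutations,
    perm_seed = if (is.numeric(dcfg$permutations)) .stage_seed(seed, "perm"))
  contrasts <- lapply(targeting_groups(design), function(g) {
    r <- permutation_fdr(norm, design, g, tcfg)
    say("diff %s: %d negative, %d positive calls at q < %g",
        attr(r, "contrast"), sum(r$direction == "negative"),
        sum(r$direction == "positive"), tcfg$alpha)
    r
  })
  names(contrasts) <- targeting_groups(design)
  affected <- call_affected(contrasts, alpha = tcfg$alpha)
  say("intersect: %d negatively, %d positively affected",
      length(affected$negatively_affected),
      length(affected$positively_affected))

  tables <- list()
  for (g in names(contrasts)) {
    tables[[paste0("contrast_", g)]] <- as.data.frame(contrasts[[g]])
    tables[[paste0("volcano_", g)]] <- volcano_table(contrasts[[g]])
  }
  tables$affected <- data.frame(
    protein_id = c(affected$negatively_affected,
                   affected$positively_affected),
    direction = rep(c("negative", "positive"),
                    c(length(affected$negatively_affected),
                      length(affected$positively_affected))),
    stringsAsFactors = FALSE)

  fcfg <- config$features
  if (!is.null(sp) && nrow(sp)) {
    thr <- if (is.null(fcfg$threshold)) 15 else fcfg$threshold
    sp$gp_class <- classify_gp(sp$gp_percent, threshold = thr)
    tables$sp_features <- sp
    clients <- sp[sp$protein_id %in% affected$negatively_affected, ,
                  drop = FALSE]
    if (nrow(clients)) {
      tables$feature_comparison <- rbind(
        feature_report(clients, sp, "gp_percent"),
        feature_report(clients, sp, "hydrophobicity"))
      say("features: %d client peptides vs %d background; GP mean ratio %.2f",
          nrow(clients), nrow(sp),
          tables$feature_comparison$mean_ratio[1L])
    }
  }

  if (!is.null(annotations)) {
    tables$enrichment <- enrichment_report(affected, rownames(mat),
                                           annotations)
    say("enrich: %d records", nrow(tables$enrichment))
  }

  manifest <- write_results(tables, out_dir)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  structure(list(affected = affected, contrasts = contrasts,
                 tables = tables, report = imp$report, manifest = manifest,
                 manifest_hash = unname(tools::md5sum(manifest_path))),
            class = "trap_run")
}

#' @export
print.trap_run <- function(x, ...) {
  cat("trapclient pipeline run\n")
  print(x$affected)
  cat(sprintf("  tables: %s\n", paste(x$manifest$file, collapse = ", ")))
  cat(sprintf("  manifest hash: %s\n", x$manifest_hash))
  invisible(x)
}
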