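#' Pipeline configuration
#'
#' Collects every stage's parameters in one nested list so a run is fully
#' described by (config, seed). Omitted values take the module defaults. The
#' config round-trips through YAML unchanged ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param sim a [sim_config()].
#' @param seq a [seq_config()].
#' @param thresholds a [quality_thresholds()].
#' @param caller a [caller_config()].
#' @param density polymorphic sites per kb for the simulator.
#' @param indel_fraction fraction of polymorphic sites that are indels.
#' @param n_genes,n_pathways synthetic annotation shape.
#' @param flank extended-gene flank in bp.
#' @param min_homopolymer_run homopolymer flagging threshold.
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @export
pipeline_config <- function(sim = sim_config(), seq = seq_config(),
                            thresholds = quality_thresholds(),
                            caller = caller_config(),
                            density = 2, indel_fraction = 0.05,
                            n_genes = 20L, n_pathways = 3L, flank = 2000L,
                            min_homopolymer_run = 5L, seed = 1L) {
  structure(list(sim = sim, seq = seq, thresholds = thresholds,
                 caller = caller, density = density,
                 indel_fraction = indel_fraction,
                 n_genes = as.integer(n_genes),
                 n_pathways = as.integer(n_pathways),
                 flank = as.integer(flank),
                 min_homopolymer_run = as.integer(min_homopolymer_run),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  strip <- function(x) if (is.list(x)) lapply(x, strip) else x
  yaml::write_yaml(strip(plain), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  tg <- y$sim$selection_targets
  if (!is.null(tg)) tg <- as.data.frame(tg, stringsAsFactors = FALSE)
  pipeline_config(
    sim = sim_config(n_founders = y$sim$n_founders,
                     genome_length = y$sim$genome_length,
                     n_arms = y$sim$n_arms, pop_size = y$sim$pop_size,
                     generations = y$sim$generations,
                     selection_targets = tg,
                     pool_males = y$sim$pool_males,
                     pool_females = y$sim$pool_females),
    seq = do.call(seq_config, y$seq),
    thresholds = do.call(quality_thresholds, y$thresholds),
    caller = do.call(caller_config, y$caller),
    density = y$density, indel_fraction = y$indel_fraction,
    n_genes = y$n_genes, n_pathways = y$n_pathways, flank = y$flank,
    min_homopolymer_run = y$min_homopolymer_run, seed = y$seed)
}

# derived per-stage seeds: one knob (config$seed) reproduces the whole run
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, annotate_sim = 211L, scan = 307L,
               annotate = 401L, enrich = 503L)
  (as.integer(seed) + 1000003L * offsets[[stage]]) %% 2147483647L
}

#' Run the full pipeline: simulate, scan, annotate, enrich, report
#'
#' Executes every stage in order into `outdir`, writing: `reference.fasta`,
#' `genes.gff3`, `pathways.tsv`, `pools.tsv`, `truth.tsv` (simulate);
#' `snps.tsv`, `indels.tsv`, `fdr.tsv`, `mask.tsv` (scan);
#' `assignments.tsv`, `coding_effects.tsv` (annotate); `density.tsv`,
#' `enrichment.tsv` (enrich); and `report.txt`. Re-running with the same
#' config and seed reproduces byte-identical outputs. A stage failure aborts
#' with the stage named and leaves a `FAILED` marker file in `outdir`.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(outdir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)), failed)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list(config = config)

  res$sim <- stage("simulate", {
    set.seed(.stage_seed(config$seed, "annotate_sim"))
    arms <- .arm_names(config$sim$n_arms)
    ref0 <- .random_reference(arms, config$sim$genome_length)
    ann <- generate_annotation(ref0, config$n_genes,
                               n_pathways = config$n_pathways)
    sim <- simulate_experiment(config$sim, config$seq,
                               polymorphic_site_density = config$density,
                               reference = ann$reference,
                               indel_fraction = config$indel_fraction,
                               fix_threshold = config$caller$fix_threshold,
                               rare_threshold = config$caller$rare_threshold,
                               seed = .stage_seed(config$seed, "simulate"))
    Biostrings::writeXStringSet(ann$reference,
                                file.path(outdir, "reference.fasta"))
    write_gene_models(ann$models, file.path(outdir, "genes.gff3"))
    write_pathway_sets(ann$pathways, file.path(outdir, "pathways.tsv"))
    write_pool_table(sim$table, file.path(outdir, "pools.tsv"))
    write_truth_table(sim$truth, file.path(outdir, "truth.tsv"))
    c(sim, list(annotation = ann))
  })

  res$scan <- stage("scan", {
    set.seed(.stage_seed(config$seed, "scan"))
    mask <- evaluable_mask(res$sim$table, config$thresholds)
    snps <- call_snps(res$sim$table, mask, config$caller)
    indels <- call_indels(res$sim$table, mask, config$caller,
                          config$thresholds)
    indels <- flag_homopolymer(indels, res$sim$annotation$reference,
                               config$min_homopolymer_run)
    fdr <- estimate_fdr_reciprocal(res$sim$table, mask, config$caller,
                                   called_snps = nrow(snps))
    write_calls(snps, file.path(outdir, "snps.tsv"))
    write_calls(indels, file.path(outdir, "indels.tsv"))
    write.table(mask$by_arm, file.path(outdir, "mask.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(reciprocal_false_loci = fdr$reciprocal_false_loci,
                           called_snps = fdr$called_snps,
                           evaluable_loci = fdr$evaluable_loci,
                           fdr = fdr$fdr),
                file.path(outdir, "fdr.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    list(mask = mask, snps = snps, indels = indels, fdr = fdr)
  })

  res$annotate <- stage("annotate", {
    index <- build_extended_index(res$sim$annotation$models, config$flank)
    calls <- rbind(res$scan$snps[, c("arm", "pos")],
                   res$scan$indels[, c("arm", "pos")])
    asn <- assign_regions(calls, index)
    effects <- classify_coding(res$scan$snps, index,
                               res$sim$annotation$reference)
    write.table(asn, file.path(outdir, "assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(effects, file.path(outdir, "coding_effects.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(index = index, assignments = asn, effects = effects)
  })

  res$enrich <- stage("enrich", {
    dens <- compute_density_stats(res$annotate$assignments, res$annotate$index)
    calls <- rbind(res$scan$snps[, c("arm", "pos")],
                   res$scan$indels[, c("arm", "pos")])
    enr <- enrich_pathways(calls, res$annotate$index,
                           res$sim$annotation$pathways,
                           universe_genes = res$annotate$index$genes$gene_id)
    write.table(dens$genes, file.path(outdir, "density.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(density = dens, enrichment = enr)
  })

  writeLines(pipeline_report(res), file.path(outdir, "report.txt"))
  invisible(res)
}

#' Render a human-readable pipeline report
#'
#' Summarizes configuration (every numeric threshold echoed for
#' auditability), per-arm evaluable fractions, call counts per arm and
#' region, the FDR estimate, density statistics, enrichment results, and -
#' when a truth table is available - the confusion matrix of called vs
#' truly selected loci with precision and recall.
#'
#' @param res the list returned by [run_pipeline()].
#' @return character vector of report lines.
#' @export
pipeline_report <- function(res) {
  cfg <- res$config
  out <- c("== poolscan pipeline report ==", "",
           "-- configuration --",
           sprintf("seed: %d", cfg$seed),
           sprintf("founders: %d  pop_size: %d  generations: %d",
                   cfg$sim$n_founders, cfg$sim$pop_size, cfg$sim$generations),
           sprintf("arms: %d x %d bp  site density: %g/kb  indel fraction: %g",
                   cfg$sim$n_arms, cfg$sim$genome_length, cfg$density,
                   cfg$indel_fraction),
           sprintf("pool: %d males + %d females", cfg$sim$pool_males,
                   cfg$sim$pool_females),
           sprintf("mean depth: %g  base error: %g", cfg$seq$mean_depth,
                   cfg$seq$base_error),
           sprintf("mask: depth >= %d, baseq >= %d, bestq >= %d",
                   cfg$thresholds$min_depth, cfg$thresholds$min_baseq,
                   cfg$thresholds$min_bestq),
           sprintf("caller: fix >= %g, rare <= %g, identity required: %s, control indel reads <= %d",
                   cfg$caller$fix_threshold, cfg$caller$rare_threshold,
                   cfg$caller$require_h_identity,
                   cfg$caller$control_absence_max_reads),
           sprintf("flank: %d bp  homopolymer run: >= %d", cfg$flank,
                   cfg$min_homopolymer_run),
           "")
  if (is.null(res$scan)) return(c(out, "-- scan: stage not run --"))
  ba <- res$scan$mask$by_arm
  out <- c(out, "-- evaluable loci --",
           sprintf("%s: %d / %d (%.1f%%)", ba$arm, ba$n_evaluable, ba$n_sites,
                   100 * ba$fraction), "")
  snps <- res$scan$snps
  indels <- res$scan$indels
  out <- c(out, "-- calls --",
           sprintf("SNPs: %d  indels: %d", nrow(snps), nrow(indels)))
  if (nrow(snps) > 0) {
    t_arm <- table(snps$arm)
    out <- c(out, sprintf("SNPs on %s: %d", names(t_arm), as.integer(t_arm)),
             sprintf("H1/H2 allele identity: %.3f", mean(snps$h_identity)))
  }
  fdr <- res$scan$fdr
  out <- c(out, sprintf(
    "FDR (reciprocal): %d / %d = %.3g", fdr$reciprocal_false_loci,
    if (fdr$denominator == "called") fdr$called_snps else fdr$evaluable_loci,
    fdr$fdr), "")
  if (!is.null(res$annotate)) {
    asn <- res$annotate$assignments
    t_reg <- table(asn$region)
    out <- c(out, "-- regions --",
             sprintf("%s: %d", names(t_reg), as.integer(t_reg)), "")
  } else out <- c(out, "-- annotate: stage not run --")
  if (!is.null(res$enrich)) {
    out <- c(out, "-- density --",
             sprintf("mu = %.4g polymorphisms/kb over %.4g kb",
                     res$enrich$density$mu, res$enrich$density$total_kb))
    if (nrow(snps) + nrow(indels) > 0) {
      e <- res$enrich$enrichment
      out <- c(out, "-- enrichment --",
               sprintf("%s: N=%g K=%g n=%g k=%g p=%.3g q=%.3g",
                       e$set, e$N, e$K, e$n, e$k, e$p, e$q), "")
    } else out <- c(out, "(no calls; enrichment omitted)", "")
  } else out <- c(out, "-- enrich: stage not run --")
  if (!is.null(res$sim$truth)) {
    truth <- res$sim$truth
    called_key <- unique(c(paste(snps$arm, snps$pos),
                           paste(indels$arm, indels$pos)))
    truth_key <- paste(truth$arm, truth$pos)
    called <- truth_key %in% called_key
    tp <- sum(called & truth$selected)
    fp <- sum(called & !truth$selected)
    fn <- sum(!called & truth$selected)
    tn <- sum(!called & !truth$selected)
    out <- c(out, "-- truth comparison --",
             sprintf("TP: %d  FP: %d  FN: %d  TN: %d", tp, fp, fn, tn),
             sprintf("precision: %s  recall: %s",
                     ifelse(tp + fp > 0, sprintf("%.3f", tp / (tp + fp)), "NA"),
                     ifelse(tp + fn > 0, sprintf("%.3f", tp / (tp + fn)), "NA")))
  }
  out
}
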