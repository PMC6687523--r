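## End-to-end pipeline driver: predict -> scan -> multiscan -> mappability
## filter -> replication -> enrichment, with a JSON manifest of counts per
## stage. The run configuration is a flat list of paths and thresholds;
## every referenced path is validated before any compute.

#' Build a pipeline run configuration
#'
#' @param dosages path to genotype dosages (VCF or dosage TSV).
#' @param expression path to the observed expression TSV.
#' @param weights character vector of weight-store paths (TSV or SQLite).
#' @param annotation path to gene annotation (GTF/BED/TSV).
#' @param out_dir output directory.
#' @param genome optional genome FASTA for mappability QC.
#' @param summaries optional two-column TSV (`gene_id`, `summary`) of gene
#'   summary text for the keyword blacklist.
#' @param replication_dosages,replication_expression optional replication
#'   cohort inputs.
#' @param gene_sets optional GMT file for enrichment.
#' @param reference optional trans-eQTL reference TSV (`snp_id, gene_id,
#'   fdr`).
#' @param fdr discovery FDR threshold (default 0.05).
#' @param replication_p replication p threshold (default 0.05).
#' @param cond_max eigenvalue ratio bound for the multi-tissue reduction
#'   (default 30).
#' @param mappability_min gene mappability threshold (default 0.8).
#' @param min_overlap minimum gene-set overlap (default 5).
#' @param master_min master-regulator target threshold (default 50).
#' @param perms permutations for the overlap null (default 1000).
#' @param maf_min variant MAF filter (default 0.05).
#' @param seed RNG seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(dosages, expression, weights, annotation, out_dir,
                       genome = NULL, summaries = NULL,
                       replication_dosages = NULL,
                       replication_expression = NULL, gene_sets = NULL,
                       reference = NULL, fdr = 0.05, replication_p = 0.05,
                       cond_max = 30, mappability_min = 0.8, min_overlap = 5,
                       master_min = 50, perms = 1000, maf_min = 0.05,
                       seed = 1L) {
  cfg <- list(dosages = dosages, expression = expression, weights = weights,
              annotation = annotation, out_dir = out_dir, genome = genome,
              summaries = summaries,
              replication_dosages = replication_dosages,
              replication_expression = replication_expression,
              gene_sets = gene_sets, reference = reference, fdr = fdr,
              replication_p = replication_p, cond_max = cond_max,
              mappability_min = mappability_min, min_overlap = min_overlap,
              master_min = master_min, perms = perms, maf_min = maf_min,
              seed = as.integer(seed))
  stopifnot(fdr > 0, replication_p > 0, cond_max > 0, mappability_min > 0,
            min_overlap > 0, master_min > 0, perms > 0)
  paths <- unlist(cfg[c("dosages", "expression", "weights", "annotation",
                        "genome", "summaries", "replication_dosages",
                        "replication_expression", "gene_sets", "reference")])
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("input path(s) not found: ", paste(missing, collapse = ", "))
  structure(cfg, class = "run_config")
}

pipeline_stage <- function(name, manifest, expr) {
  t0 <- Sys.time()
  message("[", name, "] starting")
  res <- tryCatch(force(expr), error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done (%.1fs)", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full trans-mapping pipeline
#'
#' Executes predict, single-tissue scan, multi-tissue scan, optional
#' mappability filtering, optional replication, and optional enrichment /
#' reference-overlap stages, writing each stage's table under
#' `cfg$out_dir` plus a JSON manifest of counts. Re-running with the same
#' configuration and inputs reproduces identical outputs.
#'
#' @param cfg a [run_config()].
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, thresholds = cfg[c(
    "fdr", "replication_p", "cond_max", "mappability_min", "min_overlap",
    "master_min", "perms", "maf_min")], outputs = list(), counts = list())
  set.seed(cfg$seed)

  annot <- pipeline_stage("annotation", manifest, read_annotation(cfg$annotation))
  G <- pipeline_stage("genotypes", manifest, {
    g <- read_genotypes(cfg$dosages)
    filter_variants(g, cfg$maf_min)
  })
  expr <- pipeline_stage("expression", manifest,
                         read_expression(cfg$expression, gene_table(annot)))
  stores <- pipeline_stage("weights", manifest,
                           lapply(cfg$weights, read_weights))
  grex <- pipeline_stage("predict", manifest, predict_all(G, stores))
  manifest$counts$variants <- ncol(G$dosages)
  manifest$counts$genes_predicted <-
    vapply(grex, function(g) ncol(g$values), integer(1))

  single <- pipeline_stage("scan", manifest,
                           scan_tissue(grex[[1]], expr, annot))
  p_single <- file.path(cfg$out_dir, "scan_single.tsv")
  write_associations(single, p_single)
  manifest$outputs$scan_single <- basename(p_single)
  manifest$counts$pairs_single <- nrow(single)
  manifest$counts$significant_single <- sum(single$fdr_q < cfg$fdr)

  multi <- pipeline_stage("multiscan", manifest,
                          multiscan(grex, expr, annot,
                                    condition_max = cfg$cond_max))
  p_multi <- file.path(cfg$out_dir, "scan_multi.tsv")
  write_associations(multi, p_multi)
  manifest$outputs$scan_multi <- basename(p_multi)
  manifest$counts$pairs_multi <- nrow(multi)
  manifest$counts$significant_multi <- sum(multi$fdr_q < cfg$fdr)

  masters <- find_master_regulators(multi, cfg$master_min, cfg$fdr)
  manifest$counts$master_regulators <- nrow(masters)

  if (!is.null(cfg$genome)) {
    mapres <- pipeline_stage("mapfilter", manifest, {
      genome <- read_genome(cfg$genome)
      mcfg <- mappability_config(gene_score_min = cfg$mappability_min)
      mtab <- mappability_table(annot, genome, mcfg)
      xtab <- crossmap_table(annot, genome, mcfg)
      summaries <- NULL
      if (!is.null(cfg$summaries)) {
        s <- utils::read.delim(cfg$summaries, stringsAsFactors = FALSE)
        summaries <- stats::setNames(s[[2]], s[[1]])
      }
      sig <- as.data.frame(multi[multi$fdr_q < cfg$fdr, , drop = FALSE])
      filter_analysis_set(unique(annot$gene_id), sig, mtab, xtab,
                          summaries, mcfg)
    })
    p_map <- file.path(cfg$out_dir, "scan_multi_mapfiltered.tsv")
    write_associations(mapres$kept_pairs, p_map)
    manifest$outputs$mapfiltered <- basename(p_map)
    manifest$counts$pairs_after_mapfilter <- nrow(mapres$kept_pairs)
    manifest$counts$map_exclusions <- nrow(mapres$exclusion_log)
  }

  if (!is.null(cfg$replication_expression)) {
    repres <- pipeline_stage("replicate", manifest, {
      Gr <- filter_variants(read_genotypes(cfg$replication_dosages),
                            cfg$maf_min)
      exr <- read_expression(cfg$replication_expression, gene_table(annot))
      grex_r <- predict_all(Gr, stores)
      rep_single <- scan_tissue(grex_r[[1]], exr, annot)
      replicate_pairs(single, rep_single, cfg$fdr, cfg$replication_p)
    })
    p_rep <- file.path(cfg$out_dir, "replication.tsv")
    utils::write.table(repres$pairs, p_rep, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$outputs$replication <- basename(p_rep)
    manifest$counts$replication <- repres$summary
  }

  if (!is.null(cfg$gene_sets)) {
    enr <- pipeline_stage("enrich", manifest, {
      sets <- read_gene_sets(cfg$gene_sets)
      sig <- as.data.frame(multi[multi$fdr_q < cfg$fdr, , drop = FALSE])
      background <- sort(unique(multi$trans_gene))
      hypergeom_enrich(unique(sig$trans_gene), sets, background,
                       cfg$min_overlap)
    })
    p_enr <- file.path(cfg$out_dir, "enrichment.tsv")
    utils::write.table(enr, p_enr, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$outputs$enrichment <- basename(p_enr)
    manifest$counts$enriched_sets <- sum(enr$adjusted_p < cfg$fdr)
  }

  if (!is.null(cfg$reference)) {
    ovl <- pipeline_stage("overlap", manifest, {
      ref <- utils::read.delim(cfg$reference, stringsAsFactors = FALSE)
      sig <- as.data.frame(multi[multi$fdr_q < cfg$fdr, , drop = FALSE])
      genes <- gene_table(annot)
      pred_pool <- genes[genes$gene_id %in% unique(multi$trans_gene), ]
      obs_pool <- genes[genes$gene_id %in% unique(multi$target_gene), ]
      if (nrow(sig) > 0)
        permutation_overlap_p(sig, pred_pool, obs_pool, stores, ref,
                              B = cfg$perms, seed = cfg$seed)
      else NULL
    })
    if (!is.null(ovl)) {
      manifest$counts$overlap <- list(observed = ovl$observed_overlap,
                                      empirical_p = ovl$empirical_p)
    }
  }

  p_manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
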