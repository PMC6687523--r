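## Synthetic multi-tissue genotype-transcriptome cohort generator with known
## cis and trans architecture. Dosages are Hardy-Weinberg binomial draws at
## unlinked variants; each gene has a sparse set of cis variants whose
## effect sizes are correlated across tissues (shared cis regulation); a
## trans edge makes a target gene's observed expression respond linearly to
## the regulator's expression in a designated "active" tissue. Expression is
## simulated directly on the normalized Gaussian scale the pipeline assumes.

#' Simulation configuration
#'
#' Defaults describe a mid-sized expression cohort: 500 samples, 20 genes
#' on 5 chromosomes with 5 cis variants each, 10 tissues with cis effect
#' sizes correlated at rho = 0.5 across tissues, cis heritability 0.4 of
#' regulator expression, and one trans edge of 0.5 sd target expression per
#' sd regulator expression against unit residual noise.
#'
#' @param n_samples samples in the cohort.
#' @param n_genes genes (assigned to chromosomes round-robin so
#'   cross-chromosome pairing is always well-defined).
#' @param n_tissues tissues with prediction models.
#' @param snps_per_gene cis variants per gene.
#' @param maf_range variant MAF drawn uniformly from this range.
#' @param cis_h2 proportion of regulator-expression variance explained by
#'   its cis genotype, in `[0, 1)`.
#' @param tissue_sharing correlation rho of cis effect sizes across tissues.
#' @param trans_effect beta: sd units of target expression per sd of
#'   regulator expression.
#' @param trans_edges data.frame `regulator, target, beta, active_tissue`
#'   (gene indices or ids); NULL for the default single edge gene 1 ->
#'   gene 2, beta = `trans_effect`, active in tissue 1.
#' @param noise_sd residual sd of target expression around the trans
#'   effect.
#' @param n_chroms chromosomes for the round-robin assignment.
#' @param observed_tissue tissue whose expression the cohort "measures".
#' @param weight_noise_sd sd of estimation noise added to the true weights
#'   stored in the emitted weight stores (default 0: stores carry the true
#'   weights so prediction is exact and tests isolate downstream
#'   statistics).
#' @param ld_rho optional AR(1) correlation between adjacent variants of a
#'   gene (default 0: unlinked), to exercise LD-driven false positives.
#' @param seed RNG seed; the same seed reproduces the cohort byte for byte.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500, n_genes = 20, n_tissues = 10,
                       snps_per_gene = 5, maf_range = c(0.05, 0.5),
                       cis_h2 = 0.4, tissue_sharing = 0.5,
                       trans_effect = 0.5, trans_edges = NULL, noise_sd = 1,
                       n_chroms = 5, observed_tissue = 1,
                       weight_noise_sd = 0, ld_rho = 0, seed = 1L) {
  stopifnot(cis_h2 >= 0, cis_h2 < 1, tissue_sharing >= 0, tissue_sharing <= 1,
            n_genes >= 2, n_chroms >= 2)
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_tissues = n_tissues, snps_per_gene = snps_per_gene,
                 maf_range = maf_range, cis_h2 = cis_h2,
                 tissue_sharing = tissue_sharing, trans_effect = trans_effect,
                 trans_edges = trans_edges, noise_sd = noise_sd,
                 n_chroms = min(n_chroms, n_genes),
                 observed_tissue = observed_tissue,
                 weight_noise_sd = weight_noise_sd, ld_rho = ld_rho,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genotype-transcriptome cohort with known architecture
#'
#' @param cfg a [sim_config()].
#' @param truth optionally, the `truth` element of a previous simulation:
#'   reuses its variants, cis weights and trans edges and draws a fresh
#'   cohort (new genotypes and noise) from the same architecture, which is
#'   how a replication cohort is generated.
#' @return List of class `sim_cohort`: `genotypes` ([genotype_matrix()]),
#'   `expression` ([expression_matrix()], the observed/study tissue),
#'   `stores` (list of `weight_store`), `annot` (gene table), `grex_true`
#'   (list per tissue of true GReX matrices), `truth` (edges, per-tissue
#'   true weights, maf, gene chromosomes), and `cfg`.
#' @export
simulate_cohort <- function(cfg, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  genes <- sprintf("gene_%02d", seq_len(cfg$n_genes))
  chrom <- paste0("chr", ((seq_len(cfg$n_genes) - 1L) %% cfg$n_chroms) + 1L)
  names(chrom) <- genes

  if (is.null(truth)) {
    nv <- cfg$n_genes * cfg$snps_per_gene
    maf <- stats::runif(nv, cfg$maf_range[1], cfg$maf_range[2])
    vgene <- rep(genes, each = cfg$snps_per_gene)
    vid <- paste0("rs_", vgene, "_", rep(seq_len(cfg$snps_per_gene),
                                         times = cfg$n_genes))
    # cis weights: shared component across tissues at correlation rho
    rho <- cfg$tissue_sharing
    u <- stats::rnorm(nv)
    weights <- lapply(seq_len(cfg$n_tissues), function(t) {
      raw <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(nv)
      # scale per gene so var(GReX) = cis_h2 under HWE
      v2 <- raw^2 * 2 * maf * (1 - maf)
      sc <- sqrt(cfg$cis_h2 / tapply(v2, vgene, sum)[vgene])
      raw * sc
    })
    edges <- cfg$trans_edges
    if (is.null(edges))
      edges <- data.frame(regulator = genes[1], target = genes[2],
                          beta = cfg$trans_effect, active_tissue = 1L,
                          stringsAsFactors = FALSE)
    if (is.numeric(edges$regulator)) edges$regulator <- genes[edges$regulator]
    if (is.numeric(edges$target)) edges$target <- genes[edges$target]
    if (any(chrom[edges$regulator] == chrom[edges$target]))
      stop("infeasible chromosome assignment: a trans edge is intra-chromosomal")
    truth <- list(edges = edges, weights = weights, maf = maf,
                  variant_id = vid, variant_gene = vgene, chrom = chrom)
  } else {
    maf <- truth$maf; vid <- truth$variant_id; vgene <- truth$variant_gene
    weights <- truth$weights; edges <- truth$edges; chrom <- truth$chrom
    nv <- length(maf)
  }

  samples <- sprintf("S%04d", seq_len(n))
  if (cfg$ld_rho > 0) {
    # AR(1)-correlated latent Gaussians per gene block, thresholded to HWE
    dos <- matrix(0L, n, nv)
    for (g in genes) {
      j <- which(vgene == g)
      z1 <- matrix(stats::rnorm(n * length(j)), n)
      z2 <- matrix(stats::rnorm(n * length(j)), n)
      for (k in 2:length(j)) {
        z1[, k] <- cfg$ld_rho * z1[, k - 1] + sqrt(1 - cfg$ld_rho^2) * z1[, k]
        z2[, k] <- cfg$ld_rho * z2[, k - 1] + sqrt(1 - cfg$ld_rho^2) * z2[, k]
      }
      thr <- stats::qnorm(maf[j])
      dos[, j] <- (sweep(z1, 2, thr, "<") + sweep(z2, 2, thr, "<"))
    }
  } else {
    dos <- matrix(stats::rbinom(n * nv, 2L, rep(maf, each = n)), nrow = n)
  }
  rownames(dos) <- samples
  meta <- data.frame(variant_id = vid, chrom = chrom[vgene],
                     pos = seq_len(nv) * 1000L, ref = "A", alt = "G",
                     maf = maf, stringsAsFactors = FALSE)
  G <- genotype_matrix(dos, meta)

  # per-tissue regulator-level expression E_t = GReX_t + residual
  grex_true <- lapply(seq_len(cfg$n_tissues), function(t) {
    wm <- matrix(0, nv, cfg$n_genes, dimnames = list(vid, genes))
    wm[cbind(seq_len(nv), match(vgene, genes))] <- weights[[t]]
    dos %*% wm
  })
  expr_t <- lapply(grex_true, function(gx)
    gx + matrix(stats::rnorm(n * cfg$n_genes, 0, sqrt(1 - cfg$cis_h2)),
                n, cfg$n_genes))

  Y <- expr_t[[cfg$observed_tissue]]
  for (i in seq_len(nrow(edges))) {
    reg <- edges$regulator[i]; tgt <- edges$target[i]
    a <- edges$active_tissue[i]
    Y[, tgt] <- edges$beta[i] * expr_t[[a]][, reg] +
      stats::rnorm(n, 0, cfg$noise_sd)
  }

  annot <- data.frame(gene_id = genes, chrom = chrom[genes],
                      start = 1L + (seq_len(cfg$n_genes) - 1L) * 10000L,
                      end = (seq_len(cfg$n_genes)) * 10000L, strand = "+",
                      stringsAsFactors = FALSE)
  stores <- lapply(seq_len(cfg$n_tissues), function(t) {
    w <- weights[[t]]
    if (cfg$weight_noise_sd > 0)
      w <- w + stats::rnorm(nv, 0, cfg$weight_noise_sd)
    weight_store(data.frame(rsid = vid, gene = vgene, weight = w,
                            ref_allele = "A", eff_allele = "G",
                            stringsAsFactors = FALSE),
                 tissue = sprintf("tissue_%02d", t))
  })
  structure(list(
    genotypes = G,
    expression = expression_matrix(Y, annot),
    stores = stores, annot = annot, grex_true = grex_true,
    expression_by_tissue = expr_t,
    truth = truth, cfg = cfg),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort: ", x$cfg$n_samples, " samples, ", x$cfg$n_genes,
      " genes, ", x$cfg$n_tissues, " tissues, ",
      nrow(x$truth$edges), " trans edge(s)\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk in the pipeline's standard formats
#'
#' Emits `dosages.tsv`, `expression.tsv`, one `weights_<tissue>.tsv` per
#' tissue, `annotation.tsv`, and `truth.json`.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(sim$genotypes, file.path(dir, "dosages.tsv"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  for (s in sim$stores)
    write_weights(s, file.path(dir, paste0("weights_", s$tissue, ".tsv")))
  utils::write.table(cbind(sim$annot, feature = "exon"),
                     file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(edges = sim$truth$edges,
         maf = sim$truth$maf,
         variant_id = sim$truth$variant_id,
         variant_gene = sim$truth$variant_gene,
         chrom = as.list(sim$truth$chrom),
         seed = sim$cfg$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Build a synthetic external trans-eQTL reference from simulation truth
#'
#' For a `coverage` fraction of the true trans edges (rounded to the nearest
#' count, chosen at random), emits one row (a model eSNP of the regulator,
#' the edge's target gene, fdr below threshold); remaining rows are decoys
#' with fabricated SNP ids and random gene targets that can never match a
#' model variant.
#'
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @param stores the cohort's weight stores.
#' @param coverage fraction of true edges represented in the reference.
#' @param n_decoys decoy rows appended.
#' @param fdr FDR value written on every row.
#' @param seed RNG seed.
#' @return data.frame `snp_id, gene_id, fdr`.
#' @export
simulate_reference <- function(truth, stores, coverage = 1, n_decoys = 20,
                               fdr = 0.01, seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1)
  set.seed(seed)
  edges <- truth$edges
  n_cov <- round(coverage * nrow(edges))
  rows <- NULL
  if (n_cov > 0) {
    pick <- sample(seq_len(nrow(edges)), n_cov)
    rows <- do.call(rbind, lapply(pick, function(i) {
      snps <- unique(unlist(lapply(stores, function(s)
        s$weights$rsid[s$weights$gene == edges$regulator[i]])))
      data.frame(snp_id = sample(snps, 1), gene_id = edges$target[i],
                 fdr = fdr, stringsAsFactors = FALSE)
    }))
  }
  genes <- unique(truth$variant_gene)
  decoys <- data.frame(
    snp_id = sprintf("decoy_rs%04d", sample.int(9999, n_decoys)),
    gene_id = sample(genes, n_decoys, replace = TRUE),
    fdr = fdr, stringsAsFactors = FALSE)
  out <- rbind(rows, decoys)
  rownames(out) <- NULL
  out
}
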