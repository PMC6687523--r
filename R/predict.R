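## Predicting the cis genetic component of expression (GReX) from dosages
## and per-tissue elastic-net weight tables.

#' Predict GReX for one tissue
#'
#' For each gene g with model weights w, computes
#' `GReX[s, g] = sum_v w_gv * d_sv`, where `d_sv` is the dosage of the
#' model's effect allele in sample s. When the genotype file counts the
#' model's reference allele (swapped ref/alt orientation) the dosage is
#' flipped to `2 - d`. Variants absent from the genotypes contribute
#' nothing; strand-ambiguous variants (A/T, C/G) are excluded by default;
#' missing dosages are mean-imputed with `2 * MAF`. Genes with zero usable
#' variants are dropped with a warning, never emitted as all-zero columns.
#'
#' @param G a [genotype_matrix()].
#' @param W a `weight_store`.
#' @param keep_ambiguous keep strand-ambiguous variants (default FALSE).
#' @return An object of class `grex_matrix`: `values` (samples x genes),
#'   `tissue`, and `coverage` (per-gene data.frame of variants used vs. in
#'   model).
#' @export
predict_tissue <- function(G, W, keep_ambiguous = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(W, "weight_store"))
  w <- W$weights
  meta <- G$variant_meta
  idx <- match(w$rsid, meta$variant_id)
  present <- !is.na(idx)

  ref <- toupper(meta$ref[idx]); alt <- toupper(meta$alt[idx])
  eff <- toupper(w$eff_allele);  oth <- toupper(w$ref_allele)
  aligned <- present & eff == alt & oth == ref
  flipped <- present & eff == ref & oth == alt
  ambiguous <- present & is_strand_ambiguous(oth, eff)
  mismatch <- present & !aligned & !flipped
  if (any(mismatch))
    warning(sum(mismatch), " model variant(s) skipped: allele mismatch")
  if (!keep_ambiguous && any(ambiguous & (aligned | flipped)))
    warning(sum(ambiguous & (aligned | flipped)),
            " strand-ambiguous model variant(s) excluded")
  use <- (aligned | flipped) & (keep_ambiguous | !ambiguous)

  dos <- G$dosages
  if (anyNA(dos)) {
    fill <- 2 * meta$maf
    for (j in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, j]), j] <- fill[j]
  }

  genes <- unique(w$gene)
  n <- nrow(dos)
  used_w <- w[use, , drop = FALSE]
  used_idx <- idx[use]
  used_flip <- flipped[use]
  # effective weights on the genotype file's counted allele:
  #   w * d_eff = w * d          (aligned)
  #   w * (2 - d) = 2w - w * d   (flipped): linear part -w, offset 2w
  eff_weight <- ifelse(used_flip, -used_w$weight, used_w$weight)
  offset_by_gene <- tapply(2 * used_w$weight[used_flip],
                           used_w$gene[used_flip], sum)

  kept_genes <- intersect(genes, unique(used_w$gene))
  if (length(kept_genes) == 0)
    warning("no model variants present in genotypes; empty GReX")
  dropped <- setdiff(genes, kept_genes)
  if (length(dropped) > 0)
    warning(length(dropped), " gene(s) dropped: no usable model variants")

  wm <- matrix(0, nrow = ncol(dos), ncol = length(kept_genes),
               dimnames = list(colnames(dos), kept_genes))
  if (nrow(used_w) > 0) {
    gcol <- match(used_w$gene, kept_genes)
    keep2 <- !is.na(gcol)
    wm[cbind(used_idx[keep2], gcol[keep2])] <- eff_weight[keep2]
  }
  values <- dos %*% wm
  if (length(kept_genes) > 0) {
    off <- offset_by_gene[kept_genes]
    off[is.na(off)] <- 0
    values <- sweep(values, 2, off, "+")
  }

  n_model <- table(w$gene)
  coverage <- data.frame(
    gene_id = kept_genes,
    n_used = as.integer(table(factor(used_w$gene, levels = kept_genes))),
    n_model = as.integer(n_model[kept_genes]),
    stringsAsFactors = FALSE)
  structure(list(values = values, tissue = W$tissue, coverage = coverage),
            class = "grex_matrix")
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' @export
print.grex_matrix <- function(x, ...) {
  cat("grex_matrix '", x$tissue, "': ", nrow(x$values), " samples x ",
      ncol(x$values), " genes\n", sep = "")
  invisible(x)
}

#' Predict GReX for every tissue model
#'
#' @param G a [genotype_matrix()].
#' @param stores list of `weight_store` objects (one per tissue).
#' @param verbose log per-tissue predicted gene counts to stderr.
#' @param ... passed to [predict_tissue()].
#' @return Named list of `grex_matrix`, one per store.
#' @export
predict_all <- function(G, stores, verbose = FALSE, ...) {
  stopifnot(length(stores) >= 1)
  out <- lapply(stores, function(W) predict_tissue(G, W, ...))
  names(out) <- vapply(stores, function(W) W$tissue, character(1))
  if (verbose)
    for (nm in names(out))
      message(sprintf("tissue %-30s %d genes predicted", nm,
                      ncol(out[[nm]]$values)))
  out
}
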