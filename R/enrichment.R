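## Hypergeometric gene-set enrichment, overlap with an external trans-eQTL
## reference, the chromosome-matched permutation null for that overlap, and
## fold-enrichment arithmetic.

#' Hypergeometric gene-set enrichment
#'
#' For background size M, K set members in the background, N selected genes
#' and overlap x, the enrichment p-value is the upper hypergeometric tail
#' `P(X >= x) = sum_{j >= x} C(K, j) C(M - K, N - j) / C(M, N)`. Sets whose
#' overlap with the selected genes is below `min_overlap` (default 5) are
#' omitted from testing; BH adjustment runs across the tested sets only.
#'
#' @param selected character vector of selected genes (must be a subset of
#'   `background`).
#' @param collection named list of gene sets (e.g. [read_gene_sets()]).
#' @param background character vector of background genes; collection sets
#'   are intersected with it before testing.
#' @param min_overlap minimum selected-gene overlap for a set to be tested.
#' @return data.frame `set_name, M, K, N, x, p, adjusted_p`, sorted by p.
#' @export
hypergeom_enrich <- function(selected, collection, background,
                             min_overlap = 5) {
  selected <- unique(selected)
  background <- unique(background)
  offenders <- setdiff(selected, background)
  if (length(offenders) > 0)
    stop("selected genes not in background: ",
         paste(utils::head(offenders, 10), collapse = ", "))
  M <- length(background)
  N <- length(selected)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(unique(collection[[nm]]), background)
    K <- length(members)
    x <- length(intersect(members, selected))
    if (x < min_overlap) return(NULL)
    p <- stats::phyper(x - 1, K, M - K, N, lower.tail = FALSE)
    data.frame(set_name = nm, M = M, K = K, N = N, x = x, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(set_name = character(0), M = integer(0), K = integer(0),
                      N = integer(0), x = integer(0), p = numeric(0),
                      adjusted_p = numeric(0)))
  out$adjusted_p <- bh_fdr(out$p)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match trans pairs against an external trans-eQTL reference
#'
#' A pair (A -> B) matches when some variant carrying a nonzero weight in
#' any used prediction model of A appears in the reference as a trans-eSNP
#' whose reference target gene is B. The reference is first filtered to
#' rows with `fdr < fdr_max`.
#'
#' @param pairs data.frame with columns `trans_gene, target_gene`.
#' @param stores a `weight_store` or list of them (the models used).
#' @param reference data.frame `snp_id, gene_id, fdr` of reference
#'   trans-eQTLs (eSNP, its target gene, FDR).
#' @param fdr_max reference FDR filter (default 0.05).
#' @return List `matched_pairs` (subset of `pairs` with `matched` flag set,
#'   plus a `matched` column on the full table) and `match_table` (one row
#'   per supporting (pair, eSNP)).
#' @export
overlap_with_reference <- function(pairs, stores, reference, fdr_max = 0.05) {
  if (inherits(stores, "weight_store")) stores <- list(stores)
  ref <- reference[reference$fdr < fdr_max, , drop = FALSE]
  w <- do.call(rbind, lapply(stores, function(s)
    s$weights[, c("gene", "rsid")]))
  w <- unique(w)
  # join: model SNP of trans gene == reference eSNP, reference target == target
  ref_key <- paste(ref$snp_id, ref$gene_id, sep = "\r")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    snps <- w$rsid[w$gene == pairs$trans_gene[i]]
    if (length(snps) == 0) return(NULL)
    hit <- snps[paste(snps, pairs$target_gene[i], sep = "\r") %in% ref_key]
    if (length(hit) == 0) return(NULL)
    data.frame(trans_gene = pairs$trans_gene[i],
               target_gene = pairs$target_gene[i], esnp = hit,
               stringsAsFactors = FALSE)
  })
  match_table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(match_table))
    match_table <- data.frame(trans_gene = character(0),
                              target_gene = character(0),
                              esnp = character(0))
  matched_key <- unique(paste(match_table$trans_gene,
                              match_table$target_gene, sep = "\r"))
  pairs$matched <- paste(pairs$trans_gene, pairs$target_gene,
                         sep = "\r") %in% matched_key
  list(matched_pairs = pairs[pairs$matched, , drop = FALSE],
       pairs = pairs, match_table = match_table,
       n_matched = sum(pairs$matched))
}

#' Chromosome-matched permutation null for reference overlap
#'
#' Generates B random sets of trans-acting/target gene pairs, each the same
#' size and with the same per-chromosome composition as the observed pairs
#' (the chromosome distributions of the trans-gene list and of the
#' target-gene list are preserved marginally; pairing within an iteration
#' is random subject to the cross-chromosome rule), counts each set's
#' reference overlap, and reports the empirical p-value
#' `#(permuted overlap > observed overlap) / B` ("exceeded" read strictly;
#' the exceed count is returned so `>=` or `(count+1)/(B+1)` variants can
#' be recomputed).
#'
#' @param pairs observed pairs (`trans_gene, target_gene`).
#' @param predicted_pool data.frame `gene_id, chrom` of genes eligible as
#'   trans genes.
#' @param observed_pool data.frame `gene_id, chrom` of genes eligible as
#'   targets.
#' @param stores weight store(s) used for the observed pairs.
#' @param reference reference trans-eQTL table (`snp_id, gene_id, fdr`).
#' @param annot annotation giving each observed pair gene its chromosome
#'   (`gene_id, chrom`); defaults to the union of the pools.
#' @param B number of permutations (default 1000).
#' @param seed RNG seed.
#' @param fdr_max reference FDR filter.
#' @return An object of class `overlap_null`: `observed_overlap`,
#'   `permuted_overlaps` (length B), `exceed_count`, `empirical_p`, `B`,
#'   `rng_seed`.
#' @export
permutation_overlap_p <- function(pairs, predicted_pool, observed_pool,
                                  stores, reference, annot = NULL, B = 1000,
                                  seed = 1L, fdr_max = 0.05) {
  if (is.null(annot))
    annot <- unique(rbind(predicted_pool[, c("gene_id", "chrom")],
                          observed_pool[, c("gene_id", "chrom")]))
  chrom_of <- stats::setNames(as.character(annot$chrom), annot$gene_id)
  tchrom <- chrom_of[pairs$trans_gene]
  ochrom <- chrom_of[pairs$target_gene]
  if (anyNA(tchrom) || anyNA(ochrom))
    stop("pair gene(s) missing chromosome annotation")
  t_counts <- table(tchrom)
  o_counts <- table(ochrom)
  for (ch in names(t_counts))
    if (sum(predicted_pool$chrom == ch) < t_counts[[ch]])
      stop("predicted pool too small for chromosome stratum ", ch)
  for (ch in names(o_counts))
    if (sum(observed_pool$chrom == ch) < o_counts[[ch]])
      stop("observed pool too small for chromosome stratum ", ch)

  observed <- overlap_with_reference(pairs, stores, reference,
                                     fdr_max)$n_matched
  ref <- reference[reference$fdr < fdr_max, , drop = FALSE]
  w <- unique(do.call(rbind, lapply(
    if (inherits(stores, "weight_store")) list(stores) else stores,
    function(s) s$weights[, c("gene", "rsid")])))
  ref_key <- paste(ref$snp_id, ref$gene_id, sep = "\r")
  snps_of <- split(w$rsid, w$gene)

  set.seed(seed)
  perm <- integer(B)
  for (b in seq_len(B)) {
    tg <- unlist(lapply(names(t_counts), function(ch)
      sample(predicted_pool$gene_id[predicted_pool$chrom == ch],
             t_counts[[ch]])), use.names = FALSE)
    og <- unlist(lapply(names(o_counts), function(ch)
      sample(observed_pool$gene_id[observed_pool$chrom == ch],
             o_counts[[ch]])), use.names = FALSE)
    og <- pair_cross_chromosome(tg, og, chrom_of)
    # invariant: permuted set preserves per-chromosome counts
    stopifnot(identical(as.vector(table(chrom_of[tg])[names(t_counts)]),
                        as.vector(t_counts)),
              identical(as.vector(table(chrom_of[og])[names(o_counts)]),
                        as.vector(o_counts)))
    hits <- 0L
    for (i in seq_along(tg)) {
      snps <- snps_of[[tg[i]]]
      if (is.null(snps)) next
      if (any(paste(snps, og[i], sep = "\r") %in% ref_key)) hits <- hits + 1L
    }
    perm[b] <- hits
  }
  exceed <- sum(perm > observed)
  structure(list(observed_overlap = observed, permuted_overlaps = perm,
                 exceed_count = exceed, empirical_p = exceed / B, B = B,
                 rng_seed = seed),
            class = "overlap_null")
}

## Randomly pair target genes to trans genes so that no pair shares a
## chromosome, keeping both gene lists (hence chromosome counts) fixed.
pair_cross_chromosome <- function(tg, og, chrom_of, max_tries = 200) {
  for (try in seq_len(max_tries)) {
    og2 <- sample(og)
    bad <- which(chrom_of[tg] == chrom_of[og2])
    for (pass in 1:20) {
      if (length(bad) == 0) break
      for (i in bad) {
        j <- sample(seq_along(og2), 1)
        if (chrom_of[og2[j]] != chrom_of[tg[i]] &&
            chrom_of[og2[i]] != chrom_of[tg[j]]) {
          tmp <- og2[i]; og2[i] <- og2[j]; og2[j] <- tmp
        }
      }
      bad <- which(chrom_of[tg] == chrom_of[og2])
    }
    if (length(bad) == 0) return(og2)
  }
  stop("could not pair gene lists under the cross-chromosome rule")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf("observed overlap %d | %d/%d permutations exceeded | empirical p %s\n",
              x$observed_overlap, x$exceed_count, x$B,
              if (x$exceed_count == 0) sprintf("< %g", 1 / x$B)
              else format(x$empirical_p)))
  invisible(x)
}

#' Fold enrichment of reference trans-eQTLs among top pairs
#'
#' Ratio of the reference-match rate among top (significant) pairs to the
#' rate among all tested pairs. With `rounding = "printed"` the numerator
#' percentage is rounded to the nearest integer and the denominator
#' percentage to 2 decimals before the ratio is taken (the convention used
#' when such enrichments are quoted from printed percentages, e.g.
#' 9/0.01 = 900); `rounding = "exact"` uses the unrounded percentages.
#'
#' @param top_matched,top_total matches among and size of the top pair set.
#' @param all_matched,all_total matches among and size of all tested pairs.
#' @param rounding `"printed"` or `"exact"`.
#' @return Fold enrichment (numeric).
#' @export
fold_enrichment <- function(top_matched, top_total, all_matched, all_total,
                            rounding = c("printed", "exact")) {
  rounding <- match.arg(rounding)
  stopifnot(top_total > 0, all_total > 0,
            top_matched <= top_total, all_matched <= all_total)
  num <- 100 * top_matched / top_total
  den <- 100 * all_matched / all_total
  if (rounding == "printed") {
    num <- round(num)
    den <- round(den, 2)
  }
  if (den == 0)
    stop("reference rate underflow at chosen precision")
  num / den
}
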