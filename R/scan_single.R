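## Single-tissue trans scan: standardized correlation between predicted
## (cis-genetic) expression and observed expression of genes on other
## chromosomes, with per-tissue Benjamini-Hochberg FDR.

#' Standardize a vector to mean 0, sd 1
#'
#' Sample standard deviation (denominator n-1). Standardizing both variables
#' lets the correlation scan run as a single matrix product, as in Matrix
#' eQTL-style fast scans.
#'
#' @param v numeric vector, length >= 3, nonconstant.
#' @return Standardized numeric vector.
#' @export
standardize <- function(v) {
  if (length(v) < 3) stop("need at least 3 observations")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("constant vector")
  (v - mean(v)) / s
}

## Smallest p-value we report; smaller values are floored and flagged.
P_FLOOR <- .Machine$double.xmin

#' Benjamini-Hochberg adjusted q-values
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")`:
#' `q_i = min_{p_j >= p_i} (m * p_j / rank_j)`, clipped at 1, input order
#' preserved.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Single-tissue trans scan (correlation of GReX with observed expression)
#'
#' For every predicted gene a and observed gene b on different chromosomes,
#' computes `r = <a~, b~> / (n - 1)` of the standardized vectors,
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, and a two-sided Student-t p-value
#' on n-2 df, via one matrix product of the standardized blocks. q-values
#' are BH-adjusted over all pairs tested within the tissue. Pairs whose
#' genes share a chromosome, or where either gene lacks a placed
#' chromosome, are never tested. Samples are aligned by id (intersection,
#' order harmonized); constant observed genes are skipped with a warning.
#'
#' @param grex a `grex_matrix` from [predict_tissue()].
#' @param expr an [expression_matrix()] of observed expression.
#' @param annot gene annotation covering the predicted genes: data.frame
#'   with `gene_id`, `chrom` (interval-level annotation accepted). Defaults
#'   to the expression matrix's own gene_meta.
#' @return data.frame of class `transx_scan` with columns `trans_gene,
#'   target_gene, model, n, r, t_stat, effect_direction, p, p_underflow,
#'   fdr_q`.
#' @export
scan_tissue <- function(grex, expr, annot = NULL) {
  stopifnot(inherits(grex, "grex_matrix"), inherits(expr, "expression_matrix"))
  if (is.null(annot)) annot <- expr$gene_meta
  genes <- gene_table(annot)
  chrom_of <- stats::setNames(as.character(genes$chrom), genes$gene_id)

  shared <- intersect(rownames(grex$values), rownames(expr$values))
  if (length(shared) == 0) stop("no shared samples between GReX and expression")
  n <- length(shared)
  if (n < 3) stop("need at least 3 shared samples")
  A <- grex$values[shared, , drop = FALSE]
  B <- expr$values[shared, , drop = FALSE]

  keep_a <- apply(A, 2, stats::sd) > 0
  if (any(!keep_a)) {
    warning(sum(!keep_a), " constant predicted gene(s) skipped")
    A <- A[, keep_a, drop = FALSE]
  }
  keep_b <- apply(B, 2, stats::sd) > 0
  if (any(!keep_b)) {
    warning(sum(!keep_b), " constant observed gene(s) skipped")
    B <- B[, keep_b, drop = FALSE]
  }
  ca <- chrom_of[colnames(A)]
  cb <- chrom_of[colnames(B)]
  keep_a2 <- !is.na(ca)
  keep_b2 <- !is.na(cb)
  A <- A[, keep_a2, drop = FALSE]; ca <- ca[keep_a2]
  B <- B[, keep_b2, drop = FALSE]; cb <- cb[keep_b2]
  if (ncol(A) == 0 || ncol(B) == 0)
    return(empty_scan_records(grex$tissue))

  As <- scale(A)  # mean 0, sd 1 (n-1 denominator)
  Bs <- scale(B)
  R <- crossprod(As, Bs) / (n - 1)

  cross <- outer(ca, cb, "!=")
  idx <- which(cross, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_scan_records(grex$tissue))
  r <- R[idx]
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  underflow <- p < P_FLOOR | !is.finite(tt)
  p <- pmax(p, P_FLOOR)

  rec <- data.frame(
    trans_gene = colnames(A)[idx[, 1]],
    target_gene = colnames(B)[idx[, 2]],
    model = grex$tissue,
    n = n,
    r = r,
    t_stat = tt,
    effect_direction = ifelse(r > 0, "activator", "repressor"),
    p = p,
    p_underflow = underflow,
    fdr_q = bh_fdr(p),
    stringsAsFactors = FALSE)
  rec <- rec[order(rec$p, rec$trans_gene, rec$target_gene), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("transx_scan", "data.frame")
  rec
}

empty_scan_records <- function(tissue) {
  rec <- data.frame(trans_gene = character(0), target_gene = character(0),
                    model = character(0), n = integer(0), r = numeric(0),
                    t_stat = numeric(0), effect_direction = character(0),
                    p = numeric(0), p_underflow = logical(0),
                    fdr_q = numeric(0), stringsAsFactors = FALSE)
  class(rec) <- c("transx_scan", "data.frame")
  rec
}

#' @export
print.transx_scan <- function(x, fdr = 0.05, ...) {
  cat("trans scan (", if (nrow(x)) x$model[1] else "empty", "): ",
      nrow(x), " cross-chromosome pairs tested, ",
      sum(x$fdr_q < fdr), " at FDR < ", fdr, "\n", sep = "")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' @export
summary.transx_scan <- function(object, fdr = 0.05, ...) {
  sig <- object[object$fdr_q < fdr, , drop = FALSE]
  out <- list(n_tested = nrow(object), fdr = fdr, n_significant = nrow(sig),
              n_activator = sum(sig$effect_direction == "activator"),
              n_repressor = sum(sig$effect_direction == "repressor"),
              masters = find_master_regulators(object, fdr_thresh = fdr))
  class(out) <- "summary.transx_scan"
  out
}

#' @export
print.summary.transx_scan <- function(x, ...) {
  cat("pairs tested:      ", x$n_tested, "\n")
  cat("FDR <", x$fdr, "significant:", x$n_significant,
      sprintf("(%d activator, %d repressor)\n", x$n_activator, x$n_repressor))
  if (nrow(x$masters) > 0) {
    cat("master regulators (>= 50 targets):\n")
    print.data.frame(x$masters)
  }
  invisible(x)
}

#' Run the single-tissue scan across several tissues
#'
#' @param grex_list list of `grex_matrix`.
#' @inheritParams scan_tissue
#' @return Combined `transx_scan` data.frame; FDR adjusted within each
#'   tissue separately.
#' @export
scan_all_tissues <- function(grex_list, expr, annot = NULL) {
  recs <- lapply(grex_list, scan_tissue, expr = expr, annot = annot)
  out <- do.call(rbind, lapply(recs, as.data.frame))
  class(out) <- c("transx_scan", "data.frame")
  rownames(out) <- NULL
  out
}

#' Identify master regulators
#'
#' Master regulators are trans-acting genes associated with `min_targets`
#' (default 50) or more distinct target genes at `fdr_q < fdr_thresh`.
#'
#' @param records scan records carrying `fdr_q`.
#' @param min_targets minimum number of distinct significant targets.
#' @param fdr_thresh significance threshold on `fdr_q`.
#' @return data.frame `trans_gene, n_targets`, sorted by descending target
#'   count (ties broken lexicographically by gene id).
#' @export
find_master_regulators <- function(records, min_targets = 50,
                                   fdr_thresh = 0.05) {
  sig <- records[records$fdr_q < fdr_thresh, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(trans_gene = character(0), n_targets = integer(0)))
  cnt <- tapply(sig$target_gene, sig$trans_gene,
                function(x) length(unique(x)))
  cnt <- cnt[cnt >= min_targets]
  if (length(cnt) == 0)
    return(data.frame(trans_gene = character(0), n_targets = integer(0)))
  ord <- order(-cnt, names(cnt))
  data.frame(trans_gene = names(cnt)[ord], n_targets = as.integer(cnt[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}
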