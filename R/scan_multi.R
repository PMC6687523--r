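## Multi-tissue trans scan: per-gene principal-component reduction of the
## cross-tissue predicted expression, then an F-test of the joint OLS fit
## against each cross-chromosome observed gene.

#' Reduce a gene's cross-tissue predicted expression to principal components
#'
#' Columns (tissues) are standardized, the eigen-decomposition of their
#' covariance (i.e. the correlation matrix) is taken, and components j with
#' `lambda_max / lambda_j < condition_max` are retained (strict inequality;
#' default 30). This drops near-collinear directions so the downstream
#' regression is well conditioned. Scores are the centered data projected on
#' the retained eigenvectors; eigenvector sign is fixed by making the
#' largest-magnitude loading positive.
#'
#' @param X numeric matrix, samples x tissues, for one predicted gene.
#'   Zero-variance columns are dropped first.
#' @param condition_max eigenvalue ratio bound (retain while
#'   `lambda_max/lambda_j < condition_max`).
#' @return An object of class `pc_reduction`: `eigenvalues` (all, after
#'   column drop), `k`, `scores` (samples x k), `tissues_used`, `n`.
#' @export
reduce_tissues <- function(X, condition_max = 30) {
  stopifnot(is.matrix(X) || is.data.frame(X))
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!any(keep)) stop("gene unpredictable in all tissues (all columns constant)")
  X <- X[, keep, drop = FALSE]
  Xs <- scale(X)
  n <- nrow(Xs)
  ev <- eigen(stats::cov(Xs), symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  ratio_ok <- lam > 0 & (lam[1] / lam) < condition_max
  k <- sum(ratio_ok)
  if (k < 1) stop("no retainable components")   # cannot occur: ratio 1 < bound
  V <- ev$vectors[, ratio_ok, drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xs %*% V
  structure(list(eigenvalues = lam, k = k, scores = scores,
                 loadings = V, tissues_used = colnames(X), n = n),
            class = "pc_reduction")
}

#' @export
print.pc_reduction <- function(x, ...) {
  cat("pc_reduction: ", length(x$tissues_used), " tissue(s) -> k = ", x$k,
      " components (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' F-test of the joint multi-tissue fit for one target gene
#'
#' OLS of the observed target expression on the retained principal-component
#' scores plus an intercept;
#' `F = (R^2 / k) / ((1 - R^2) / (n - k - 1))` with p from the upper tail of
#' `F(k, n - k - 1)`, and `r2_adj = 1 - (1 - R^2)(n - 1)/(n - k - 1)`.
#'
#' @param red a `pc_reduction`.
#' @param y observed expression vector for the target gene, aligned to the
#'   reduction's samples.
#' @return One-row data.frame: `k, n, F_stat, df1, df2, R2, r2_adj, p,
#'   p_underflow`.
#' @export
multixcan_test <- function(red, y) {
  stopifnot(inherits(red, "pc_reduction"))
  n <- red$n
  k <- red$k
  if (length(y) != n) stop("y length does not match samples")
  if (n <= k + 1) stop("insufficient df: n <= k + 1")
  if (stats::sd(y) == 0) stop("constant target vector")
  yc <- y - mean(y)
  # full OLS fit (no orthogonality assumption, so any basis of the
  # retained span gives the same R^2)
  fit <- stats::lm.fit(cbind(1, red$scores), y)
  R2 <- 1 - sum(fit$residuals^2) / sum(yc^2)
  R2 <- min(max(R2, 0), 1)
  df2 <- n - k - 1
  F_stat <- (R2 / k) / ((1 - R2) / df2)
  p <- stats::pf(F_stat, k, df2, lower.tail = FALSE)
  underflow <- !is.finite(F_stat) || p < P_FLOOR
  if (!is.finite(F_stat)) F_stat <- Inf
  p <- max(p, P_FLOOR)
  data.frame(k = k, n = n, F_stat = F_stat, df1 = k, df2 = df2, R2 = R2,
             r2_adj = 1 - (1 - R2) * (n - 1) / df2, p = p,
             p_underflow = underflow)
}

#' Multi-tissue trans scan
#'
#' For each gene predicted in at least one tissue, assembles its cross-tissue
#' GReX matrix, reduces it to principal components ([reduce_tissues()]), and
#' tests the joint fit against every cross-chromosome observed gene
#' ([multixcan_test()]). q-values are BH-adjusted over all tested pairs.
#'
#' @param grex_list list of `grex_matrix`, one per tissue.
#' @param expr an [expression_matrix()].
#' @param annot gene annotation covering predicted genes (`gene_id`,
#'   `chrom`); defaults to the expression matrix's gene_meta.
#' @param condition_max eigenvalue ratio bound for component retention.
#' @param min_samples minimum shared sample count.
#' @return data.frame of class `transx_multiscan` with columns `trans_gene,
#'   target_gene, model, k, n, F_stat, df1, df2, r2_adj, p, p_underflow,
#'   fdr_q`.
#' @export
multiscan <- function(grex_list, expr, annot = NULL, condition_max = 30,
                      min_samples = 10) {
  if (length(grex_list) == 0) stop("empty tissue list")
  stopifnot(inherits(expr, "expression_matrix"))
  if (is.null(annot)) annot <- expr$gene_meta
  genes <- gene_table(annot)
  chrom_of <- stats::setNames(as.character(genes$chrom), genes$gene_id)

  shared <- rownames(expr$values)
  for (g in grex_list) shared <- intersect(shared, rownames(g$values))
  if (length(shared) < min_samples)
    stop("fewer than ", min_samples, " shared samples")
  n <- length(shared)

  B <- expr$values[shared, , drop = FALSE]
  keep_b <- apply(B, 2, stats::sd) > 0 & !is.na(chrom_of[colnames(B)])
  B <- B[, keep_b, drop = FALSE]
  cb <- chrom_of[colnames(B)]
  Bc <- scale(B, center = TRUE, scale = FALSE)
  ssb <- colSums(Bc^2)

  pred_genes <- sort(unique(unlist(lapply(grex_list, function(g)
    colnames(g$values)))))
  pred_genes <- pred_genes[!is.na(chrom_of[pred_genes])]

  out <- vector("list", length(pred_genes))
  for (i in seq_along(pred_genes)) {
    gid <- pred_genes[i]
    cols <- lapply(grex_list, function(g)
      if (gid %in% colnames(g$values)) g$values[shared, gid] else NULL)
    X <- do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
    colnames(X) <- vapply(grex_list[!vapply(cols, is.null, logical(1))],
                          function(g) g$tissue, character(1))
    red <- tryCatch(reduce_tissues(X, condition_max), error = function(e) NULL)
    if (is.null(red)) next
    k <- red$k
    if (n <= k + 1) next
    targets <- which(cb != chrom_of[gid])
    if (length(targets) == 0) next
    ssc <- colSums(red$scores^2)
    proj <- crossprod(red$scores, Bc[, targets, drop = FALSE])  # k x T
    R2 <- colSums(proj^2 / ssc) / ssb[targets]
    R2 <- pmin(pmax(R2, 0), 1)
    df2 <- n - k - 1
    F_stat <- (R2 / k) / ((1 - R2) / df2)
    p <- stats::pf(F_stat, k, df2, lower.tail = FALSE)
    underflow <- !is.finite(F_stat) | p < P_FLOOR
    F_stat[!is.finite(F_stat)] <- Inf
    p <- pmax(p, P_FLOOR)
    out[[i]] <- data.frame(
      trans_gene = gid, target_gene = colnames(B)[targets], model = "multi",
      k = k, n = n, F_stat = F_stat, df1 = k, df2 = df2,
      r2_adj = 1 - (1 - R2) * (n - 1) / df2,
      p = p, p_underflow = underflow, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(rec) || nrow(rec) == 0) {
    rec <- data.frame(trans_gene = character(0), target_gene = character(0),
                      model = character(0), k = integer(0), n = integer(0),
                      F_stat = numeric(0), df1 = integer(0), df2 = integer(0),
                      r2_adj = numeric(0), p = numeric(0),
                      p_underflow = logical(0), fdr_q = numeric(0))
  } else {
    rec$fdr_q <- bh_fdr(rec$p)
    rec <- rec[order(rec$p, rec$trans_gene, rec$target_gene), , drop = FALSE]
  }
  rownames(rec) <- NULL
  class(rec) <- c("transx_multiscan", "data.frame")
  rec
}

#' @export
print.transx_multiscan <- function(x, fdr = 0.05, ...) {
  cat("multi-tissue trans scan: ", nrow(x), " pairs tested, ",
      sum(x$fdr_q < fdr), " at FDR < ", fdr, "\n", sep = "")
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}
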