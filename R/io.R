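## Readers/writers for the pipeline's input and output formats, plus basic
## variant QC.  All tabular formats are plain tab-separated text; genotypes
## may alternatively arrive as VCF with a DS (dosage) FORMAT field.

#' Construct a genotype dosage matrix
#'
#' Container for effect-allele dosages (samples x variants) plus per-variant
#' metadata. Dosages live in `[0, 2]`; missing dosages are `NA` and are
#' mean-imputed (with `2 * MAF`) at prediction time so sample sizes stay fixed.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#'   Rownames are sample ids, colnames variant ids.
#' @param variant_meta data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt` and optionally `maf`; one row per column of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variant_meta) {
  stopifnot(is.matrix(dosages), is.data.frame(variant_meta))
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variant_meta))
  if (length(miss) > 0)
    stop("variant_meta missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(variant_meta) != ncol(dosages))
    stop("variant_meta rows must match dosage columns")
  if (anyDuplicated(variant_meta$variant_id))
    stop("duplicate variant id: ",
         variant_meta$variant_id[duplicated(variant_meta$variant_id)][1])
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate sample id")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosage out of range [0, 2]: found ", format(if (rng[1] < 0) rng[1] else rng[2]))
  colnames(dosages) <- variant_meta$variant_id
  if (is.null(variant_meta$maf)) {
    m <- colMeans(dosages, na.rm = TRUE) / 2
    variant_meta$maf <- pmin(m, 1 - m)
  }
  structure(list(dosages = dosages, variant_meta = variant_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$dosages), " samples x ",
      ncol(x$dosages), " variants\n", sep = "")
  cat("  MAF range: ", paste(signif(range(x$variant_meta$maf), 3), collapse = " - "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Sample ids of a container
#'
#' @param x a `genotype_matrix`, `expression_matrix` or `grex_matrix`.
#' @return Character vector of sample ids, in storage order.
#' @export
sample_ids <- function(x) {
  rownames(if (!is.null(x$dosages)) x$dosages else x$values)
}

#' Read genotype dosages
#'
#' Reads either a VCF whose FORMAT includes the `DS` dosage field, or a
#' tab-separated dosage matrix with columns `variant_id, chrom, pos, ref, alt
#' [, maf]` followed by one column per sample. MAF is computed from the
#' dosages when absent from the file. Sample order is preserved.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"vcf"`, `"dosage"`. `"auto"` treats
#'   `.vcf`/`.vcf.gz` as VCF, anything else as a dosage matrix.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (is.null(ds) || all(is.na(ds)))
    stop("VCF has no DS dosage field")
  vid <- fix$ID
  vid[is.na(vid) | vid == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(vid) | vid == "."]
  meta <- data.frame(variant_id = vid, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  dos <- t(ds)  # samples x variants
  bad <- which(!is.na(dos) & (dos < 0 | dos > 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("dosage out of range at variant ", meta$variant_id[bad[1, 2]])
  genotype_matrix(dos, meta)
}

read_genotypes_dosage <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("dosage file missing column(s): ", paste(miss, collapse = ", "))
  meta_cols <- intersect(c(need, "maf"), names(d))
  samp_cols <- setdiff(names(d), meta_cols)
  if (length(samp_cols) == 0) stop("dosage file has no sample columns")
  dos <- as.matrix(d[, samp_cols, drop = FALSE])
  if (!is.numeric(dos)) {
    bad_row <- which(apply(d[, samp_cols, drop = FALSE], 1,
                           function(r) anyNA(suppressWarnings(as.numeric(r)) ) &&
                             !anyNA(r)))[1]
    stop("malformed dosage row at line ", bad_row + 1L)
  }
  bad <- which(!is.na(dos) & (dos < 0 | dos > 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("dosage out of range at line ", bad[1, 1] + 1L,
         " (variant ", d$variant_id[bad[1, 1]], ")")
  dos <- t(dos)  # samples x variants
  rownames(dos) <- samp_cols
  meta <- d[, meta_cols, drop = FALSE]
  genotype_matrix(dos, meta)
}

#' Write a genotype matrix as a dosage text file
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(G, path) {
  out <- cbind(G$variant_meta,
               as.data.frame(t(G$dosages), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter variants by minor allele frequency
#'
#' Retains variants with MAF strictly greater than `maf_min`, preserving
#' order. Strict inequality matches the usual "MAF > 0.05" convention for
#' imputed genotype panels.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min MAF threshold in `[0, 0.5]`.
#' @return A filtered [genotype_matrix()].
#' @export
filter_variants <- function(G, maf_min = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"), maf_min >= 0, maf_min <= 0.5)
  keep <- G$variant_meta$maf > maf_min
  structure(list(dosages = G$dosages[, keep, drop = FALSE],
                 variant_meta = G$variant_meta[keep, , drop = FALSE]),
            class = "genotype_matrix")
}

#' Construct an observed-expression matrix
#'
#' @param values numeric matrix, samples x genes; rownames sample ids,
#'   colnames gene ids.
#' @param gene_meta data.frame with at least `gene_id` and `chrom`; optional
#'   `start`, `end`, `strand`. One row per gene (superset allowed).
#' @param drop_constant drop all-constant gene columns (with a warning)
#'   rather than erroring.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_meta, drop_constant = TRUE) {
  stopifnot(is.matrix(values), is.data.frame(gene_meta))
  if (anyDuplicated(colnames(values))) stop("duplicate gene ids")
  if (!all(c("gene_id", "chrom") %in% names(gene_meta)))
    stop("gene_meta needs columns gene_id and chrom")
  if (anyDuplicated(gene_meta$gene_id))
    gene_meta <- gene_meta[!duplicated(gene_meta$gene_id), , drop = FALSE]
  missing_genes <- setdiff(colnames(values), gene_meta$gene_id)
  if (length(missing_genes) > 0)
    stop("genes without annotation: ", paste(utils::head(missing_genes, 5), collapse = ", "))
  gene_meta <- gene_meta[match(colnames(values), gene_meta$gene_id), , drop = FALSE]
  const <- apply(values, 2, function(v) stats::var(v, na.rm = TRUE)) == 0
  const[is.na(const)] <- TRUE
  if (any(const)) {
    if (!drop_constant) stop("constant expression column: ",
                             colnames(values)[which(const)[1]])
    warning(sum(const), " constant gene column(s) dropped")
    values <- values[, !const, drop = FALSE]
    gene_meta <- gene_meta[!const, , drop = FALSE]
  }
  structure(list(values = values, gene_meta = gene_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " samples x ",
      ncol(x$values), " genes on ",
      length(unique(x$gene_meta$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Read an observed-expression matrix
#'
#' Expects a tab-separated file with a `sample_id` first column and one
#' column per gene; expression is assumed pre-normalized (e.g. HCP residuals
#' for RNA-seq, RMA values for arrays).
#'
#' @param path file path.
#' @param gene_meta gene annotation data.frame (`gene_id`, `chrom`, ...).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, gene_meta) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "sample_id") stop("first column must be sample_id")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  expression_matrix(m, gene_meta)
}

#' Write an expression matrix
#' @param E an [expression_matrix()] (or `grex_matrix`, same layout).
#' @param path output path.
#' @export
write_expression <- function(E, path) {
  out <- data.frame(sample_id = rownames(E$values),
                    E$values, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-tissue prediction weight store
#'
#' Accepts either a PredictDB-style SQLite file with a `weights` table
#' (columns `rsid, gene, weight, ref_allele, eff_allele`) or a tab-separated
#' twin with the same columns. Zero-weight records are dropped on read; a
#' duplicated (gene, rsid) pair is an error.
#'
#' @param path file path.
#' @param tissue tissue label; defaults to the filename stem.
#' @return An object of class `weight_store` with elements `tissue` and
#'   `weights` (data.frame `gene, rsid, ref_allele, eff_allele, weight`).
#' @export
read_weights <- function(path, tissue = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(tissue))
    tissue <- sub("\\.(db|sqlite|txt|tsv)(\\.gz)?$", "", basename(path))
  magic <- readBin(path, "raw", n = 15L)
  if (identical(rawToChar(magic), "SQLite format 3")) {
    if (!requireNamespace("RSQLite", quietly = TRUE))
      stop("reading SQLite weight stores requires the RSQLite package; ",
           "use the tab-separated twin format instead")
    con <- RSQLite::dbConnect(RSQLite::SQLite(), path)
    on.exit(RSQLite::dbDisconnect(con))
    w <- RSQLite::dbReadTable(con, "weights")
  } else {
    w <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  need <- c("rsid", "gene", "weight", "ref_allele", "eff_allele")
  miss <- setdiff(need, names(w))
  if (length(miss) > 0)
    stop("weight store missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(w[, c("gene", "rsid")]))
    stop("duplicate weight record (gene, rsid): ",
         paste(w[duplicated(w[, c("gene", "rsid")]), c("gene", "rsid")][1, ],
               collapse = ", "))
  w <- w[is.finite(w$weight) & w$weight != 0, need, drop = FALSE]
  weight_store(w, tissue)
}

#' Construct a weight store from a data.frame
#' @param weights data.frame with columns `rsid, gene, weight, ref_allele,
#'   eff_allele` (zero weights dropped).
#' @param tissue tissue label.
#' @return A `weight_store`.
#' @export
weight_store <- function(weights, tissue) {
  need <- c("rsid", "gene", "weight", "ref_allele", "eff_allele")
  stopifnot(all(need %in% names(weights)))
  if (anyDuplicated(weights[, c("gene", "rsid")]))
    stop("duplicate weight record")
  weights <- weights[is.finite(weights$weight) & weights$weight != 0, ,
                     drop = FALSE]
  structure(list(tissue = tissue,
                 weights = weights[, need, drop = FALSE]),
            class = "weight_store")
}

#' @export
print.weight_store <- function(x, ...) {
  cat("weight_store '", x$tissue, "': ", nrow(x$weights), " weights for ",
      length(unique(x$weights$gene)), " genes\n", sep = "")
  invisible(x)
}

#' Write a weight store as tab-separated text
#' @param W a `weight_store`.
#' @param path output path.
#' @export
write_weights <- function(W, path) {
  utils::write.table(W$weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an association result table
#'
#' Tab-separated with header `trans_gene, target_gene, model, statistic,
#' effect_or_F, df, p, fdr_q, n_samples`. `statistic` is the test statistic
#' value (t for single-tissue rows, F for multi-tissue rows); `effect_or_F`
#' carries the correlation r for single-tissue rows and the F statistic for
#' multi-tissue rows; `df` is `n-2` for single-tissue rows and `"df1/df2"`
#' for multi-tissue rows. Numeric fields round-trip at 10 significant digits.
#'
#' @param records a data.frame of scan records (see [scan_tissue()] /
#'   [multiscan()]), or an empty data.frame for a header-only file.
#' @param path output path.
#' @export
write_associations <- function(records, path) {
  cols <- c("trans_gene", "target_gene", "model", "statistic", "effect_or_F",
            "df", "p", "fdr_q", "n_samples")
  if (nrow(records) == 0) {
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols),
                                dimnames = list(NULL, cols)))
  } else {
    if (!is.null(records$F_stat)) {       # multi-tissue schema
      out <- data.frame(trans_gene = records$trans_gene,
                        target_gene = records$target_gene,
                        model = records$model,
                        statistic = records$F_stat,
                        effect_or_F = records$F_stat,
                        df = paste0(records$df1, "/", records$df2),
                        p = records$p, fdr_q = records$fdr_q,
                        n_samples = records$n,
                        stringsAsFactors = FALSE)
    } else {
      out <- data.frame(trans_gene = records$trans_gene,
                        target_gene = records$target_gene,
                        model = records$model,
                        statistic = records$t_stat,
                        effect_or_F = records$r,
                        df = as.character(records$n - 2L),
                        p = records$p, fdr_q = records$fdr_q,
                        n_samples = records$n,
                        stringsAsFactors = FALSE)
    }
    for (nm in c("statistic", "effect_or_F", "p", "fdr_q"))
      out[[nm]] <- sprintf("%.10g", out[[nm]])
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association result table written by [write_associations()]
#'
#' @param path file path.
#' @return data.frame with the written columns; numerics parsed back.
#' @export
read_associations <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(df = "character"))
  for (nm in c("statistic", "effect_or_F", "p", "fdr_q"))
    if (!is.null(d[[nm]])) d[[nm]] <- as.numeric(d[[nm]])
  d
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, then member genes per line).
#' @param source_label label recorded on the collection.
#' @return A named list of unique member-gene character vectors, with
#'   attribute `source`; class `gene_set_collection`.
#' @export
read_gene_sets <- function(path, source_label = basename(path)) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  structure(sets, source = source_label, class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#' @param sets named list of gene id vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation (GTF, BED, or plain TSV)
#'
#' Returns interval-level annotation used by the scans (gene -> chromosome)
#' and by the mappability module (exon/UTR intervals). GTF and BED are parsed
#' with rtracklayer; coordinates are reported 1-based inclusive. A plain TSV
#' with columns `gene_id, chrom, start, end, strand, feature` (feature in
#' `exon`/`UTR`) is accepted as a lightweight twin.
#'
#' @param path file path.
#' @return data.frame `gene_id, chrom, start, end, strand, feature`.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.(gtf|gff|gff3|bed)(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr)
    gene <- if (!is.null(df$gene_id)) df$gene_id else df$name
    feature <- if (!is.null(df$type)) as.character(df$type) else "exon"
    feature[grepl("utr", feature, ignore.case = TRUE)] <- "UTR"
    out <- data.frame(gene_id = gene, chrom = as.character(df$seqnames),
                      start = df$start, end = df$end,
                      strand = as.character(df$strand), feature = feature,
                      stringsAsFactors = FALSE)
    out <- out[out$feature %in% c("exon", "UTR"), , drop = FALSE]
  } else {
    out <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand", "feature")
    miss <- setdiff(need, names(out))
    if (length(miss) > 0)
      stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  }
  out
}

#' Collapse interval annotation to one row per gene
#'
#' @param annot interval-level annotation from [read_annotation()] or any
#'   data.frame with `gene_id` and `chrom`.
#' @return data.frame `gene_id, chrom` (plus span when intervals present).
#' @export
gene_table <- function(annot) {
  g <- annot[!duplicated(annot$gene_id), , drop = FALSE]
  data.frame(gene_id = g$gene_id, chrom = g$chrom, stringsAsFactors = FALSE)
}
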