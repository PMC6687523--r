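## k-mer gene mappability and cross-mappability QC.
##
## A k-mer's mappability is 1 / (number of genomic positions it maps to),
## counting exact matches on both strands. Gene mappability is the
## length-weighted average of exon-mappability (k = 75) and UTR-mappability
## (k = 36). Cross-mappability from gene A to gene B counts A's exon 75-mers
## and UTR 36-mers whose exact alignment starts within B's exonic or UTR
## intervals. Matching is exact (no mismatches); the alignment start of a
## reverse-strand hit is its leftmost forward-strand coordinate.

#' Mappability configuration
#'
#' @param k_exon k-mer length for exonic regions (default 75, read length
#'   of typical RNA-seq).
#' @param k_utr k-mer length for UTRs (default 36).
#' @param gene_score_min genes with mappability below this are excluded
#'   (strict `<`; default 0.8).
#' @param crossmap_max pairs with cross-mappability count above this (in
#'   either direction) are excluded (default 0, i.e. any positive count).
#' @param blacklist_terms gene-summary substrings (case-insensitive) that
#'   exclude a gene.
#' @return A list of class `mappability_config`.
#' @export
mappability_config <- function(k_exon = 75, k_utr = 36, gene_score_min = 0.8,
                               crossmap_max = 0,
                               blacklist_terms = c("paralog", "pseudogene",
                                                   "retro")) {
  stopifnot(k_exon >= 1, k_utr >= 1,
            gene_score_min >= 0, gene_score_min <= 1)
  structure(list(k_exon = as.integer(k_exon), k_utr = as.integer(k_utr),
                 gene_score_min = gene_score_min, crossmap_max = crossmap_max,
                 blacklist_terms = blacklist_terms),
            class = "mappability_config")
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## All k-mers of a sequence with their start positions.
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

## Multiset counts of all forward-strand k-mers in the genome.
genome_kmer_counts <- function(genome, k) {
  all_k <- unlist(lapply(genome, seq_kmers, k = k), use.names = FALSE)
  if (length(all_k) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(all_k)
  stats::setNames(as.integer(tab), names(tab))
}

## Number of genomic positions each query k-mer maps to (both strands;
## a palindromic k-mer's forward and reverse hit at one locus counts once).
kmer_hit_counts <- function(queries, counts) {
  fwd <- counts[match(queries, names(counts))]
  fwd[is.na(fwd)] <- 0L
  rc <- revcomp(queries)
  rev <- counts[match(rc, names(counts))]
  rev[is.na(rev)] <- 0L
  rev[rc == queries] <- 0L  # palindrome: same positions, do not double count
  as.integer(fwd + rev)
}

#' Mappability of a single k-mer
#'
#' `1 / (number of positions the k-mer maps to in the genome)`, exact
#' matches on both strands. A k-mer absent from the genome has undefined
#' mappability and returns `NA` (cannot arise for k-mers extracted from the
#' genome itself).
#'
#' @param genome named character vector of sequences (see [read_genome()]).
#' @param kmer k-mer string.
#' @return `1 / hits`, or `NA` when the k-mer does not occur.
#' @export
kmer_mappability <- function(genome, kmer) {
  counts <- genome_kmer_counts(genome, nchar(kmer))
  hits <- kmer_hit_counts(toupper(kmer), counts)
  if (hits == 0) return(NA_real_)
  1 / hits
}

## Merge overlapping/adjacent 1-based inclusive intervals.
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df)
  out <- list()
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start[1]; e <- d$end[1]
    res <- NULL
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= e + 1L) e <- max(e, d$end[i])
      else { res <- rbind(res, c(s, e)); s <- d$start[i]; e <- d$end[i] }
    }
    res <- rbind(res, c(s, e))
    out[[ch]] <- data.frame(chrom = ch, start = res[, 1], end = res[, 2],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## Subtract intervals `b` from `a` (both merged, same chrom set).
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  out <- NULL
  for (i in seq_len(nrow(a))) {
    segs <- data.frame(start = a$start[i], end = a$end[i])
    bb <- b[b$chrom == a$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(bb))) {
      new <- NULL
      for (r in seq_len(nrow(segs))) {
        s <- segs$start[r]; e <- segs$end[r]
        bs <- bb$start[j]; be <- bb$end[j]
        if (be < s || bs > e) { new <- rbind(new, c(s, e)); next }
        if (bs > s) new <- rbind(new, c(s, bs - 1L))
        if (be < e) new <- rbind(new, c(be + 1L, e))
      }
      segs <- if (is.null(new))
        data.frame(start = integer(0), end = integer(0))
      else data.frame(start = new[, 1], end = new[, 2])
      if (nrow(segs) == 0) break
    }
    if (nrow(segs) > 0)
      out <- rbind(out, data.frame(chrom = a$chrom[i], start = segs$start,
                                   end = segs$end, stringsAsFactors = FALSE))
  }
  if (is.null(out)) data.frame(chrom = character(0), start = integer(0),
                               end = integer(0)) else out
}

## Merged exon (UTR-subtracted) and UTR intervals for one gene.
gene_regions <- function(gene_id, annot) {
  g <- annot[annot$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) stop("gene not in annotation: ", gene_id)
  exon <- merge_intervals(g[g$feature == "exon", c("chrom", "start", "end")])
  utr <- merge_intervals(g[g$feature == "UTR", c("chrom", "start", "end")])
  exon_only <- if (nrow(utr) > 0) subtract_intervals(exon, utr) else exon
  list(exon = exon_only, utr = utr, exon_with_utr = exon)
}

## k-mers fully contained in intervals; intervals shorter than k contribute
## no k-mers.
region_kmers <- function(regions, genome, k) {
  if (nrow(regions) == 0) return(character(0))
  unlist(lapply(seq_len(nrow(regions)), function(i) {
    seq <- genome[[regions$chrom[i]]]
    s <- regions$start[i]; e <- min(regions$end[i], nchar(seq))
    if (e - s + 1L < k) return(character(0))
    starts <- s:(e - k + 1L)
    substring(seq, starts, starts + k - 1L)
  }), use.names = FALSE)
}

region_length <- function(regions) {
  if (nrow(regions) == 0) return(0L)
  sum(regions$end - regions$start + 1L)
}

#' Gene mappability score
#'
#' Exon-mappability is the mean mappability over all `k_exon`-mers fully
#' inside the merged exonic intervals (UTR-overlapping exon bases are
#' assigned to the UTR component); UTR-mappability likewise with
#' `k_utr`-mers. The gene score is their average weighted by total merged
#' exon and UTR length. A gene with no UTR gets its exon-mappability; a
#' gene with zero extractable k-mers gets `NA`.
#'
#' @param gene_id gene identifier present in `annot`.
#' @param annot interval annotation (`gene_id, chrom, start, end, feature`,
#'   feature in `exon`/`UTR`), as from [read_annotation()].
#' @param genome named character vector of sequences.
#' @param cfg a [mappability_config()].
#' @param kmer_counts optional precomputed list with elements `exon` and
#'   `utr` from internal genome indexing (used by [mappability_table()]).
#' @return Numeric score in `[0, 1]`, or `NA`.
#' @export
gene_mappability <- function(gene_id, annot, genome,
                             cfg = mappability_config(),
                             kmer_counts = NULL) {
  row <- mappability_row(gene_id, annot, genome, cfg, kmer_counts)
  row$score
}

mappability_row <- function(gene_id, annot, genome, cfg, kmer_counts = NULL) {
  if (is.null(kmer_counts))
    kmer_counts <- list(exon = genome_kmer_counts(genome, cfg$k_exon),
                        utr = genome_kmer_counts(genome, cfg$k_utr))
  reg <- gene_regions(gene_id, annot)
  ek <- region_kmers(reg$exon, genome, cfg$k_exon)
  uk <- region_kmers(reg$utr, genome, cfg$k_utr)
  m_exon <- if (length(ek) > 0)
    mean(1 / kmer_hit_counts(ek, kmer_counts$exon)) else NA_real_
  m_utr <- if (length(uk) > 0)
    mean(1 / kmer_hit_counts(uk, kmer_counts$utr)) else NA_real_
  len_exon <- region_length(reg$exon)
  len_utr <- region_length(reg$utr)
  len_exon_overlap <- region_length(reg$exon_with_utr)
  wavg <- function(le, lu) {
    if (!is.na(m_exon) && !is.na(m_utr)) (le * m_exon + lu * m_utr) / (le + lu)
    else if (!is.na(m_exon)) m_exon
    else if (!is.na(m_utr)) m_utr
    else NA_real_
  }
  data.frame(gene_id = gene_id, m_exon = m_exon, m_utr = m_utr,
             len_exon = len_exon, len_utr = len_utr,
             score = wavg(len_exon, len_utr),
             score_overlap_weighted = wavg(len_exon_overlap, len_utr),
             stringsAsFactors = FALSE)
}

#' Mappability table for all annotated genes
#'
#' @inheritParams gene_mappability
#' @return data.frame with per-gene component mappabilities, lengths, the
#'   score (UTR bases subtracted from exons before weighting), and the
#'   alternate overlap-weighted score.
#' @export
mappability_table <- function(annot, genome, cfg = mappability_config()) {
  kc <- list(exon = genome_kmer_counts(genome, cfg$k_exon),
             utr = genome_kmer_counts(genome, cfg$k_utr))
  genes <- unique(annot$gene_id)
  out <- do.call(rbind, lapply(genes, mappability_row, annot = annot,
                               genome = genome, cfg = cfg, kmer_counts = kc))
  rownames(out) <- NULL
  out
}

## Forward-read k-mers starting within a gene's exon+UTR intervals
## (k-mers may extend past the interval end: only the start must lie
## inside).
start_region_kmers <- function(gene_id, annot, genome, k) {
  g <- annot[annot$gene_id == gene_id & annot$feature %in% c("exon", "UTR"), ,
             drop = FALSE]
  reg <- merge_intervals(g[, c("chrom", "start", "end")])
  if (nrow(reg) == 0) return(character(0))
  unlist(lapply(seq_len(nrow(reg)), function(i) {
    seq <- genome[[reg$chrom[i]]]
    last_start <- nchar(seq) - k + 1L
    s <- reg$start[i]; e <- min(reg$end[i], last_start)
    if (e < s) return(character(0))
    starts <- s:e
    substring(seq, starts, starts + k - 1L)
  }), use.names = FALSE)
}

#' Cross-mappability count from gene A to gene B
#'
#' The number of gene A k-mer instances (exon `k_exon`-mers, UTR
#' `k_utr`-mers, one per start position) that align exactly, on either
#' strand, with alignment start inside gene B's exonic or UTR intervals.
#' The count is directional; [filter_analysis_set()] excludes a pair when
#' either direction is positive.
#'
#' @param geneA,geneB gene ids in `annot`.
#' @inheritParams gene_mappability
#' @return Non-negative integer count.
#' @export
cross_mappability <- function(geneA, geneB, annot, genome,
                              cfg = mappability_config()) {
  regA <- gene_regions(geneA, annot)
  a75 <- region_kmers(regA$exon, genome, cfg$k_exon)
  a36 <- region_kmers(regA$utr, genome, cfg$k_utr)
  b75 <- start_region_kmers(geneB, annot, genome, cfg$k_exon)
  b36 <- start_region_kmers(geneB, annot, genome, cfg$k_utr)
  hit <- function(q, bset) {
    if (length(q) == 0 || length(bset) == 0) return(0L)
    bs <- unique(bset)
    sum(q %in% bs | revcomp(q) %in% bs)
  }
  hit(a75, b75) + hit(a36, b36)
}

#' Cross-mappability table for gene pairs
#'
#' @param pairs data.frame with columns `geneA, geneB` (ordered pairs), or
#'   NULL for all ordered pairs of distinct annotated genes.
#' @inheritParams gene_mappability
#' @return data.frame `geneA, geneB, count`.
#' @export
crossmap_table <- function(annot, genome, cfg = mappability_config(),
                           pairs = NULL) {
  if (is.null(pairs)) {
    genes <- unique(annot$gene_id)
    pairs <- expand.grid(geneA = genes, geneB = genes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$geneA != pairs$geneB, , drop = FALSE]
  }
  pairs$count <- vapply(seq_len(nrow(pairs)), function(i)
    cross_mappability(pairs$geneA[i], pairs$geneB[i], annot, genome, cfg),
    integer(1))
  rownames(pairs) <- NULL
  pairs
}

#' Apply mappability, cross-mappability, and summary-keyword filters
#'
#' Drops genes with mappability score below `cfg$gene_score_min` (strict) or
#' missing from the table; drops genes whose RefSeq-style summary text
#' contains any blacklist term (case-insensitive substring); drops pairs
#' involving a dropped gene or with a cross-mappability count above
#' `cfg$crossmap_max` in either direction. Idempotent.
#'
#' @param genes character vector of candidate gene ids.
#' @param pairs data.frame of candidate pairs with columns `trans_gene,
#'   target_gene` (extra columns carried through).
#' @param mtab mappability table ([mappability_table()] output, or any
#'   data.frame with `gene_id` and `score`).
#' @param xtab cross-mappability table (`geneA, geneB, count`); absent
#'   pairs count 0.
#' @param summaries named character vector of per-gene summary text
#'   (optional).
#' @param cfg a [mappability_config()].
#' @return List `kept_genes`, `kept_pairs`, `exclusion_log` (data.frame
#'   `item, reason`).
#' @export
filter_analysis_set <- function(genes, pairs, mtab, xtab = NULL,
                                summaries = NULL,
                                cfg = mappability_config()) {
  log <- list()
  score <- mtab$score[match(genes, mtab$gene_id)]
  bad_missing <- is.na(score)
  bad_low <- !bad_missing & score < cfg$gene_score_min
  for (g in genes[bad_missing])
    log[[length(log) + 1L]] <- c(g, "mappability score missing")
  for (g in genes[bad_low])
    log[[length(log) + 1L]] <- c(g, sprintf("mappability score < %g",
                                            cfg$gene_score_min))
  bad_term <- rep(FALSE, length(genes))
  if (!is.null(summaries)) {
    txt <- tolower(summaries[genes])
    for (term in cfg$blacklist_terms) {
      hit <- !is.na(txt) & grepl(term, txt, fixed = TRUE)
      for (g in genes[hit & !bad_term])
        log[[length(log) + 1L]] <- c(g, paste0("summary contains '", term, "'"))
      bad_term <- bad_term | hit
    }
  }
  kept_genes <- genes[!(bad_missing | bad_low | bad_term)]

  kept_pairs <- pairs
  if (!is.null(pairs) && nrow(pairs) > 0) {
    ok_gene <- pairs$trans_gene %in% kept_genes &
      pairs$target_gene %in% kept_genes
    xcount <- rep(0L, nrow(pairs))
    if (!is.null(xtab) && nrow(xtab) > 0) {
      k1 <- match(paste(pairs$trans_gene, pairs$target_gene, sep = "\r"),
                  paste(xtab$geneA, xtab$geneB, sep = "\r"))
      k2 <- match(paste(pairs$target_gene, pairs$trans_gene, sep = "\r"),
                  paste(xtab$geneA, xtab$geneB, sep = "\r"))
      c1 <- ifelse(is.na(k1), 0L, xtab$count[k1])
      c2 <- ifelse(is.na(k2), 0L, xtab$count[k2])
      xcount <- pmax(c1, c2)
    }
    ok_x <- xcount <= cfg$crossmap_max
    for (i in which(ok_gene & !ok_x))
      log[[length(log) + 1L]] <-
        c(paste0(pairs$trans_gene[i], "|", pairs$target_gene[i]),
          sprintf("cross-mappability count %d", xcount[i]))
    for (i in which(!ok_gene))
      log[[length(log) + 1L]] <-
        c(paste0(pairs$trans_gene[i], "|", pairs$target_gene[i]),
          "involves excluded gene")
    kept_pairs <- pairs[ok_gene & ok_x, , drop = FALSE]
    rownames(kept_pairs) <- NULL
  }
  exclusion_log <- if (length(log) > 0) {
    m <- do.call(rbind, log)
    data.frame(item = m[, 1], reason = m[, 2], stringsAsFactors = FALSE)
  } else data.frame(item = character(0), reason = character(0))
  list(kept_genes = kept_genes, kept_pairs = kept_pairs,
       exclusion_log = exclusion_log)
}
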