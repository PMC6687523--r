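# Interval annotation helper: one gene from explicit exon/UTR intervals.
ann_row <- function(gene, chrom, start, end, feature) {
  data.frame(gene_id = gene, chrom = chrom, start = start, end = end,
             strand = "+", feature = feature, stringsAsFactors = FALSE)
}

test_that("k-mer mappability is 1 / mapped positions, both strands", {
  genome <- c(chr1 = "AAACCCTTTGA")
  expect_equal(kmer_mappability(genome, "AAC"), 1)        # unique, rc absent
  genome2 <- c(chr1 = "AACGGAACGG")
  expect_equal(kmer_mappability(genome2, "AACGG"), 0.5)   # two positions
  # palindromic k-mer at one locus: forward and reverse hit coincide
  genome3 <- c(chr1 = "TTACGTTT")
  expect_equal(rc("ACGT"), "ACGT")
  expect_equal(kmer_mappability(genome3, "ACGT"), 1)
  # reverse-complement occurrences on another sequence count as positions
  genome4 <- c(chr1 = "AAACCCTT", chr2 = "AAGGGTTT")     # GGGTT = rc(AACCC)
  expect_equal(kmer_mappability(genome4, "AACCC"),
               1 / count_kmer_positions(genome4, "AACCC"))
  expect_equal(kmer_mappability(genome4, "AACCC"), 0.5)
  # absent k-mer: undefined
  expect_true(is.na(kmer_mappability(genome, "GGGGG")))
})

test_that("gene score is the length-weighted exon/UTR average", {
  set.seed(71)
  exon <- random_dna(100)
  utr <- random_dna(50)
  spacer <- random_dna(40)
  genome <- c(chr1 = paste0(exon, utr, spacer, utr))
  annot <- rbind(ann_row("g1", "chr1", 1, 100, "exon"),
                 ann_row("g1", "chr1", 101, 150, "UTR"))
  cfg <- mappability_config()
  tab <- mappability_table(annot, genome, cfg)
  # exon 75-mers unique (m = 1); every UTR 36-mer occurs exactly twice
  expect_equal(tab$m_exon, 1)
  expect_equal(tab$m_utr, 0.5)
  expect_equal(tab$score, (100 * 1 + 50 * 0.5) / 150)
  expect_equal(tab$score, 5 / 6)

  # no UTR annotation: score = exon mappability
  annot2 <- ann_row("g2", "chr1", 1, 100, "exon")
  expect_equal(gene_mappability("g2", annot2, genome, cfg), 1)
})

test_that("exon intervals shorter than k contribute no k-mers", {
  set.seed(72)
  genome <- c(chr1 = random_dna(300))
  annot <- rbind(ann_row("g1", "chr1", 1, 50, "exon"),     # < 75: skipped
                 ann_row("g1", "chr1", 101, 200, "exon"))
  s <- gene_mappability("g1", annot, genome, mappability_config())
  expect_equal(s, 1)
  # all intervals too short -> no extractable k-mers -> NA
  annot2 <- ann_row("g3", "chr1", 1, 50, "exon")
  expect_true(is.na(gene_mappability("g3", annot2, genome,
                                     mappability_config())))
})

test_that("on an all-unique genome every score is 1 and nothing is excluded", {
  set.seed(73)
  genome <- c(chr1 = random_dna(500), chr2 = random_dna(500))
  annot <- rbind(ann_row("gA", "chr1", 11, 160, "exon"),
                 ann_row("gA", "chr1", 161, 220, "UTR"),
                 ann_row("gB", "chr2", 51, 250, "exon"))
  cfg <- mappability_config()
  mtab <- mappability_table(annot, genome, cfg)
  expect_true(all(mtab$score == 1))
  xtab <- crossmap_table(annot, genome, cfg)
  expect_true(all(xtab$count == 0))
  pairs <- data.frame(trans_gene = "gA", target_gene = "gB")
  res <- filter_analysis_set(c("gA", "gB"), pairs, mtab, xtab, NULL, cfg)
  expect_equal(res$kept_genes, c("gA", "gB"))
  expect_equal(nrow(res$kept_pairs), 1L)
  expect_equal(nrow(res$exclusion_log), 0L)
})

test_that("whole-gene duplication halves exon mappability and is excluded", {
  set.seed(74)
  exon <- random_dna(100)
  utr <- random_dna(50)
  genome <- c(chr1 = paste0(random_dna(20), exon, utr, random_dna(20)),
              chr2 = paste0(random_dna(35), exon, utr, random_dna(35)))
  annot <- rbind(ann_row("gA", "chr1", 21, 120, "exon"),
                 ann_row("gA", "chr1", 121, 170, "UTR"),
                 ann_row("gB", "chr2", 36, 135, "exon"),
                 ann_row("gB", "chr2", 136, 185, "UTR"))
  cfg <- mappability_config()
  mtab <- mappability_table(annot, genome, cfg)
  expect_true(all(mtab$m_exon <= 0.5))
  expect_true(all(mtab$score <= 0.5))
  # duplicate limit: cross-map = all exon 75-mers + all UTR 36-mers
  n_expected <- (100 - 75 + 1) + (50 - 36 + 1)
  expect_equal(cross_mappability("gA", "gB", annot, genome, cfg), n_expected)
  expect_equal(cross_mappability("gB", "gA", annot, genome, cfg), n_expected)
  xtab <- crossmap_table(annot, genome, cfg)
  pairs <- data.frame(trans_gene = "gA", target_gene = "gB")
  res <- filter_analysis_set(c("gA", "gB"), pairs, mtab, xtab, NULL, cfg)
  expect_equal(nrow(res$kept_pairs), 0L)
  expect_true(any(grepl("mappability score", res$exclusion_log$reason)))
})

test_that("genes with no shared subsequence have zero cross-mappability", {
  set.seed(75)
  genome <- c(chr1 = random_dna(200), chr2 = random_dna(200))
  annot <- rbind(ann_row("gA", "chr1", 1, 150, "exon"),
                 ann_row("gB", "chr2", 1, 150, "exon"))
  expect_equal(cross_mappability("gA", "gB", annot, genome,
                                 mappability_config()), 0L)
})

test_that("a planted 75-mer in gene B is found from either strand", {
  set.seed(76)
  exonA <- random_dna(100)
  shared <- substring(exonA, 10, 84)                 # one 75-mer of gene A
  genome <- c(chr1 = exonA,
              chr2 = paste0(random_dna(30), shared, random_dna(30)),
              chr3 = paste0(random_dna(30), rc(shared), random_dna(30)))
  annot <- rbind(ann_row("gA", "chr1", 1, 100, "exon"),
                 ann_row("gB", "chr2", 1, 135, "exon"),
                 ann_row("gC", "chr3", 1, 135, "exon"))
  cfg <- mappability_config()
  expect_gte(cross_mappability("gA", "gB", annot, genome, cfg), 1L)
  expect_gte(cross_mappability("gA", "gC", annot, genome, cfg), 1L)
})

test_that("analysis-set filtering applies score, blacklist and pair rules", {
  mtab <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     score = c(0.79, 0.80, 0.95, 0.99))
  xtab <- data.frame(geneA = "g4", geneB = "g2", count = 1L)  # one direction
  summaries <- c(g3 = "retrotransposed locus derived from chr7")
  pairs <- data.frame(trans_gene = c("g2", "g2", "g3"),
                      target_gene = c("g4", "g1", "g2"))
  cfg <- mappability_config()
  res <- filter_analysis_set(c("g1", "g2", "g3", "g4"), pairs, mtab, xtab,
                             summaries, cfg)
  # g1: score 0.79 < 0.8 out; g2: 0.80 retained (strict <); g3: blacklist
  expect_equal(res$kept_genes, c("g2", "g4"))
  # pair (g2,g4): crossmap 1 in the reverse direction -> excluded;
  # (g2,g1) and (g3,g2) involve excluded genes
  expect_equal(nrow(res$kept_pairs), 0L)
  expect_true(any(grepl("cross-mappability", res$exclusion_log$reason)))
  expect_true(any(grepl("retro", res$exclusion_log$reason)))

  # a gene absent from the mappability table is excluded and logged
  res2 <- filter_analysis_set(c("g2", "g9"), pairs[0, ], mtab, xtab, NULL, cfg)
  expect_equal(res2$kept_genes, "g2")
  expect_true(any(grepl("missing", res2$exclusion_log$reason)))

  # idempotence on the kept set
  res3 <- filter_analysis_set(res$kept_genes, res$kept_pairs, mtab, xtab,
                              summaries, cfg)
  expect_equal(res3$kept_genes, res$kept_genes)
  expect_equal(nrow(res3$exclusion_log), 0L)
})
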