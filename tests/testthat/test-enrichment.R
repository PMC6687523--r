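# Exhaustive oracle: probability of observing >= x set members when drawing
# N genes from a background of M containing K members, by enumerating all
# C(M, N) draws.
enum_hyper_p <- function(M, K, N, x) {
  draws <- combn(M, N)
  mean(apply(draws, 2, function(d) sum(d <= K)) >= x)
}

test_that("hypergeometric p equals exhaustive enumeration for M <= 12", {
  for (case in list(c(10, 5, 4, 4), c(10, 5, 4, 2), c(12, 6, 5, 3),
                    c(8, 3, 4, 1), c(12, 4, 6, 4))) {
    M <- case[1]; K <- case[2]; N <- case[3]; x <- case[4]
    background <- paste0("g", seq_len(M))
    selected <- background[seq_len(N)]
    # place exactly x set members among the selected genes
    members <- c(selected[seq_len(x)],
                 if (K > x) background[(N + 1):(N + K - x)])
    res <- hypergeom_enrich(selected, list(s = members), background,
                            min_overlap = 1)
    expect_equal(res$x, x)
    expect_equal(res$K, K)
    expect_equal(res$p, enum_hyper_p(M, K, N, x), tolerance = 1e-12)
  }
  # the worked case M=10, K=5, N=4, x=4: p = C(5,4)/C(10,4) = 5/210
  background <- paste0("g", 1:10)
  res <- hypergeom_enrich(background[1:4], list(s = background[1:5]),
                          background, min_overlap = 1)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
})

test_that("sets below the minimum overlap are omitted from testing", {
  background <- paste0("g", 1:100)
  selected <- background[1:10]
  coll <- list(big = background[1:20],    # overlap 10
               small = background[7:60])  # overlap 4
  res <- hypergeom_enrich(selected, coll, background, min_overlap = 5)
  expect_equal(res$set_name, "big")
  res2 <- hypergeom_enrich(selected, coll, background, min_overlap = 4)
  expect_setequal(res2$set_name, c("big", "small"))
  # BH adjustment across tested sets only
  expect_equal(res2$adjusted_p, bh_fdr(res2$p))
})

test_that("selected genes outside the background are an error, named", {
  expect_error(hypergeom_enrich(c("g1", "zz"), list(s = "g1"),
                                paste0("g", 1:5)), "zz")
})

test_that("a fully selected disjoint set gets the minimal p with x = N", {
  background <- paste0("g", 1:60)
  coll <- list(hit = background[1:8], other = background[31:45])
  res <- hypergeom_enrich(background[1:8], coll, background, min_overlap = 5)
  expect_equal(res$set_name[1], "hit")
  expect_equal(res$x[1], 8L)
  expect_equal(res$x[1], res$N[1])
})

test_that("reference overlap matches pairs through model eSNPs", {
  stores <- list(toy_weights(c("A", "A", "C"), c("rs1", "rs2", "rs9"),
                             c(0.3, -0.2, 1)))
  ref <- data.frame(snp_id = c("rs1", "rs9"), gene_id = c("B", "D"),
                    fdr = c(0.01, 0.2))
  pairs <- data.frame(trans_gene = c("A", "A", "C"),
                      target_gene = c("B", "X", "D"))
  res <- overlap_with_reference(pairs, stores, ref)
  # (A,B): rs1 -> B at fdr 0.01 matches; (A,X): target mismatch;
  # (C,D): rs9 -> D fails the fdr < 0.05 filter
  expect_equal(res$n_matched, 1L)
  expect_equal(res$matched_pairs$trans_gene, "A")
  expect_equal(res$match_table$esnp, "rs1")

  # brute-force join oracle on a randomized fixture
  set.seed(61)
  genes <- paste0("G", 1:6)
  w <- data.frame(rsid = paste0("rs", 1:12),
                  gene = sample(genes, 12, TRUE), weight = rnorm(12),
                  ref_allele = "A", eff_allele = "G")
  store <- weight_store(w, "t")
  ref2 <- data.frame(snp_id = sample(paste0("rs", 1:15), 8),
                     gene_id = sample(genes, 8, TRUE), fdr = 0.01)
  pairs2 <- expand.grid(trans_gene = genes, target_gene = genes,
                        stringsAsFactors = FALSE)
  got <- overlap_with_reference(pairs2, store, ref2)$pairs$matched
  want <- vapply(seq_len(nrow(pairs2)), function(i) {
    snps <- w$rsid[w$gene == pairs2$trans_gene[i]]
    any(ref2$snp_id %in% snps & ref2$gene_id == pairs2$target_gene[i])
  }, logical(1))
  expect_equal(got, want)
})

test_that("fold enrichment reproduces the printed-percentage convention", {
  expect_equal(fold_enrichment(5, 55, 3547, 2.4e7, "printed"), 900)
  expect_equal(fold_enrichment(728, 2356, 168893, 2e8, "printed"), 387.5)
  expect_equal(fold_enrichment(1, 10, 10, 100, "exact"), 1)
  expect_error(fold_enrichment(1, 10, 1, 1e9, "printed"), "underflow")
})

test_that("permutation null preserves strata and is seed-reproducible", {
  set.seed(62)
  sim <- simulate_cohort(sim_config(n_samples = 50, n_genes = 12,
                                    n_tissues = 2, seed = 3))
  genes <- gene_table(sim$annot)
  pairs <- data.frame(trans_gene = c("gene_01", "gene_03", "gene_06"),
                      target_gene = c("gene_02", "gene_09", "gene_12"))
  ref <- simulate_reference(sim$truth, sim$stores, coverage = 1,
                            n_decoys = 5, seed = 4)
  r1 <- permutation_overlap_p(pairs, genes, genes, sim$stores, ref,
                              B = 50, seed = 9)
  r2 <- permutation_overlap_p(pairs, genes, genes, sim$stores, ref,
                              B = 50, seed = 9)
  expect_equal(r1$permuted_overlaps, r2$permuted_overlaps)
  expect_equal(r1$empirical_p, r1$exceed_count / 50)
  expect_length(r1$permuted_overlaps, 50)

  # degenerate floors: no reference rows -> all overlaps 0, strict-exceed p=0
  ref0 <- ref[0, ]
  r0 <- permutation_overlap_p(pairs, genes, genes, sim$stores, ref0,
                              B = 20, seed = 9)
  expect_equal(r0$observed_overlap, 0L)
  expect_equal(r0$empirical_p, 0)

  # a stratum larger than its pool errors, naming the stratum
  tiny <- genes[genes$chrom == "chr1", ][1, , drop = FALSE]
  many <- data.frame(trans_gene = rep("gene_01", 2),
                     target_gene = c("gene_02", "gene_07"))
  expect_error(permutation_overlap_p(many, tiny, genes, sim$stores, ref,
                                     B = 5, seed = 1), "chr")
})
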