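test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- sim_config(n_samples = 40, n_genes = 8, n_tissues = 3, seed = 42)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the dosages
  d3 <- simulate_cohort(sim_config(n_samples = 40, n_genes = 8,
                                   n_tissues = 3, seed = 43))
  expect_false(identical(d3$genotypes$dosages,
                         simulate_cohort(cfg)$genotypes$dosages))
})

test_that("empirical MAF sits within 3 binomial standard errors of target", {
  sim <- simulate_cohort(sim_config(n_samples = 2000, n_genes = 6,
                                    n_tissues = 1, seed = 5))
  maf_true <- sim$truth$maf
  counted <- colMeans(sim$genotypes$dosages) / 2
  se <- sqrt(maf_true * (1 - maf_true) / (2 * 2000))
  expect_true(all(abs(counted - maf_true) < 3.5 * se))
})

test_that("realized cis heritability matches the configured cis_h2", {
  sim <- simulate_cohort(sim_config(n_samples = 5000, n_genes = 6,
                                    n_tissues = 2, cis_h2 = 0.4, seed = 6))
  t1 <- 1  # regulator-level expression in tissue 1 = GReX + residual
  h2 <- vapply(seq_len(6), function(g) {
    var(sim$grex_true[[t1]][, g]) /
      var(sim$expression_by_tissue[[t1]][, g])
  }, numeric(1))
  expect_true(all(abs(h2 - 0.4) < 0.05))
})

test_that("cross-tissue GReX correlation tracks the sharing parameter", {
  sim <- simulate_cohort(sim_config(n_samples = 5000, n_genes = 20,
                                    n_tissues = 4, tissue_sharing = 0.5,
                                    seed = 7))
  cors <- unlist(lapply(seq_len(20), function(g) {
    gx <- sapply(sim$grex_true, function(m) m[, g])
    cc <- cor(gx)
    cc[upper.tri(cc)]
  }))
  # per-gene realized sharing is noisy at 5 cis SNPs; the mean over genes
  # and tissue pairs estimates rho
  expect_lt(abs(mean(cors) - 0.5), 0.1)
})

test_that("weight stores default to the true simulation weights", {
  sim <- simulate_cohort(sim_config(n_samples = 100, n_genes = 5,
                                    n_tissues = 2, seed = 8))
  grex <- predict_all(sim$genotypes, sim$stores)
  expect_equal(grex[[1]]$values, sim$grex_true[[1]], tolerance = 1e-12)
  expect_equal(grex[[2]]$values, sim$grex_true[[2]], tolerance = 1e-12)
  # opt-in estimation noise breaks the exact identity
  simn <- simulate_cohort(sim_config(n_samples = 100, n_genes = 5,
                                     n_tissues = 2, weight_noise_sd = 0.2,
                                     seed = 8))
  grexn <- predict_all(simn$genotypes, simn$stores)
  expect_gt(max(abs(grexn[[1]]$values - simn$grex_true[[1]])), 0)
})

test_that("trans edges are always cross-chromosome and infeasible ones error", {
  sim <- simulate_cohort(sim_config(seed = 9))
  chrom <- sim$truth$chrom
  expect_true(all(chrom[sim$truth$edges$regulator] !=
                    chrom[sim$truth$edges$target]))
  bad <- data.frame(regulator = 1, target = 6, beta = 0.5,
                    active_tissue = 1)  # genes 1 and 6 share chr1 of 5
  expect_error(simulate_cohort(sim_config(trans_edges = bad, seed = 9)),
               "infeasible")
})

test_that("a fresh draw from stored truth replays the same architecture", {
  cfg <- sim_config(n_samples = 60, n_genes = 6, n_tissues = 2, seed = 10)
  sim1 <- simulate_cohort(cfg)
  cfg2 <- sim_config(n_samples = 60, n_genes = 6, n_tissues = 2, seed = 11)
  sim2 <- simulate_cohort(cfg2, truth = sim1$truth)
  expect_equal(sim2$truth$edges, sim1$truth$edges)
  expect_equal(sim2$stores[[1]]$weights, sim1$stores[[1]]$weights)
  expect_false(identical(sim1$genotypes$dosages, sim2$genotypes$dosages))
})

test_that("synthetic references cover the requested fraction of true edges", {
  edges <- data.frame(regulator = seq(1, 79, by = 2),
                      target = seq(2, 80, by = 2),
                      beta = 0.5, active_tissue = 1)
  sim <- simulate_cohort(sim_config(n_samples = 30, n_genes = 80,
                                    n_tissues = 1, trans_edges = edges,
                                    seed = 12))
  pairs <- data.frame(trans_gene = sim$truth$edges$regulator,
                      target_gene = sim$truth$edges$target)
  # full coverage, decoys can never match fabricated SNP ids
  ref1 <- simulate_reference(sim$truth, sim$stores, coverage = 1, seed = 13)
  expect_equal(overlap_with_reference(pairs, sim$stores, ref1)$n_matched,
               40L)
  # zero coverage -> zero matches among true edges
  ref0 <- simulate_reference(sim$truth, sim$stores, coverage = 0, seed = 13)
  expect_equal(overlap_with_reference(pairs, sim$stores, ref0)$n_matched, 0L)
  # half coverage on 40 edges: exactly 20 planted, verified by brute join
  ref05 <- simulate_reference(sim$truth, sim$stores, coverage = 0.5,
                              seed = 13)
  got <- overlap_with_reference(pairs, sim$stores, ref05)
  expect_equal(got$n_matched, 20L)
  w <- do.call(rbind, lapply(sim$stores, function(s) s$weights))
  want <- sum(vapply(seq_len(nrow(pairs)), function(i) {
    snps <- w$rsid[w$gene == pairs$trans_gene[i]]
    any(ref05$snp_id %in% snps & ref05$gene_id == pairs$target_gene[i] &
          ref05$fdr < 0.05)
  }, logical(1)))
  expect_equal(got$n_matched, want)
})
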