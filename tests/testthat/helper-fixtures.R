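# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# A hand-sized genotype matrix with aligned A/G variants.
toy_genotypes <- function(dosages, sample_ids = NULL, maf = NULL) {
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(dosages)))
  rownames(dosages) <- sample_ids
  nv <- ncol(dosages)
  meta <- data.frame(variant_id = paste0("rs", seq_len(nv)),
                     chrom = "chr1", pos = seq_len(nv) * 100L,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  if (!is.null(maf)) meta$maf <- maf
  genotype_matrix(dosages, meta)
}

toy_weights <- function(gene, rsid, weight, ref = "A", eff = "G",
                        tissue = "toy") {
  weight_store(data.frame(rsid = rsid, gene = gene, weight = weight,
                          ref_allele = ref, eff_allele = eff,
                          stringsAsFactors = FALSE), tissue)
}

# Wrap a plain matrix as a grex_matrix (unit-test shim for scan inputs).
as_grex <- function(values, tissue = "toy") {
  structure(list(values = values, tissue = tissue,
                 coverage = data.frame(gene_id = colnames(values),
                                       n_used = 1L, n_model = 1L)),
            class = "grex_matrix")
}

# Gaussian GReX + expression blocks with predicted genes on chrA and
# observed genes on chrB, so every pair is cross-chromosome.
null_scan_fixture <- function(n, n_pred, n_obs, tissue = "toy") {
  samples <- paste0("s", seq_len(n))
  A <- matrix(rnorm(n * n_pred), n,
              dimnames = list(samples, paste0("pg", seq_len(n_pred))))
  B <- matrix(rnorm(n * n_obs), n,
              dimnames = list(samples, paste0("og", seq_len(n_obs))))
  annot <- data.frame(
    gene_id = c(colnames(A), colnames(B)),
    chrom = rep(c("chrA", "chrB"), c(n_pred, n_obs)),
    stringsAsFactors = FALSE)
  list(grex = as_grex(A, tissue),
       expr = expression_matrix(B, annot),
       annot = annot)
}

# Random DNA with (almost surely) no repeated k-mer at these lengths.
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# Brute-force oracle: positions (across all sequences, forward strand)
# where `kmer` or its reverse complement occurs; palindromes counted once.
count_kmer_positions <- function(genome, kmer) {
  k <- nchar(kmer)
  queries <- unique(c(kmer, rc(kmer)))
  total <- 0L
  for (seq in genome) {
    n <- nchar(seq)
    if (n < k) next
    subs <- substring(seq, 1:(n - k + 1), k:n)
    total <- total + sum(subs %in% queries)
  }
  total
}
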