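---
title: "Methods: mapping trans-acting genes from predicted expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping trans-acting genes from predicted expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transxcan)
```

## The model

Trans regulation is modeled as a two-step causal chain: cis variants set
the expression level of a regulator gene; the regulator's expression level
influences a target gene on another chromosome. `transxcan` instruments
the first step with the **genetically regulated expression** (GReX) of the
regulator,

$$\widehat{\mathrm{GReX}}_{s,g} \;=\; \sum_{v \in \mathrm{model}(g)} w_{gv}\, d_{sv},$$

where $d_{sv}$ is sample $s$'s dosage of the model's effect allele at
variant $v$ and $w_{gv}$ are elastic-net weights trained in an independent
cohort. Using externally trained weights matters: it prevents the leakage
that would occur if the cis model were fit in the same cohort whose
observed expression is then scanned.

The **single-tissue scan** correlates each predicted gene with each
observed gene on a different chromosome. With both vectors standardized to
mean 0 and sample sd 1 (denominator $n-1$),
$r = \langle \tilde a, \tilde b\rangle/(n-1)$,
$t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-sided p on $n-2$ df. The full grid is
one `crossprod()` of the standardized blocks; a brute-force per-pair test
gives identical numbers (tested to 1e-12). BH FDR is computed within each
tissue, because each tissue model is a separate instrument set.

The **multi-tissue scan** exploits the empirical fact that cis-eQTLs are
widely shared across tissues: the per-tissue GReX vectors of one gene are
correlated replicate measurements of the same latent cis signal. For each
gene the samples × tissues block is column-standardized and
eigen-decomposed; components $j$ with
$\lambda_{\max}/\lambda_j < 30$ (strict) are kept, and the target is
regressed on the retained scores plus an intercept:
$F = (R^2/k)\,/\,((1-R^2)/(n-k-1))$ on $(k,\, n-k-1)$ df. With a single
tissue this collapses exactly to the correlation scan through $F = t^2$
(tested to 1e-10). Note that a gene with $m$ cis model variants yields a
cross-tissue block of rank at most $m$, so $k \le m$ regardless of how
many tissues are modeled.

**Replication** joins discovery pairs (FDR < 0.05) to a second cohort's
scan and flags pairs with replication $p < 0.05$; direction consistency
compares t-statistic signs (undefined for sign-free F records). The
expected true-positive rate is summarized by $\pi_1 = 1 - \pi_0$, with
$\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on a 0.05–0.95 grid
and a cubic smoothing spline (df = 3) evaluated at the largest $\lambda$ —
the qvalue-style smoother. A fixed-$\lambda$ (0.5) variant is available
and is the automatic fallback when fewer than four grid points are usable.

## Mappability quality control

Multi-mapping reads create spurious cross-chromosome correlations:
expression attributed to gene B may partly be gene A's. Three filters
guard against this:

* **gene mappability** — mean over exon 75-mers and UTR 36-mers of
  $1/(\text{number of genomic positions the k-mer maps to})$, combined as
  a length-weighted average; genes below 0.8 (strict) are dropped;
* **cross-mappability** — the count of gene A k-mers whose exact alignment
  (either strand) starts inside gene B's exonic/UTR intervals; any
  positive count in either direction disqualifies the pair;
* a case-insensitive summary-keyword blacklist
  (`paralog`, `pseudogene`, `retro`).

Matching is exact, both strands, with a palindromic k-mer's coincident
forward/reverse hit counted once. The read lengths 75 (exons) and 36
(UTRs) are the conventional values for this QC. Where exon and UTR
annotations overlap, UTR bases are assigned to the UTR component before
length weighting; the table also reports the overlap-inclusive weighting
(`score_overlap_weighted`) so either convention can be inspected. The
alignment start of a reverse-strand hit is taken as its leftmost
forward-strand coordinate.

## Enrichment and reference overlap

Gene-set enrichment is the upper-tail hypergeometric probability of the
observed overlap, restricted to sets with at least 5 selected genes, and
BH-adjusted across tested sets (verified against exhaustive enumeration of
all draws for small backgrounds). Overlap with an external trans-eQTL
reference counts pairs (A → B) where some nonzero-weight model variant of
A is reported as a trans-eSNP of B. Its significance comes from a
chromosome-matched permutation null: B = 1000 random pair sets preserving
the per-chromosome composition of the trans-gene and target-gene lists
(marginally; pairing within an iteration is random subject to the
cross-chromosome rule), with the empirical p defined strictly as
$\#(\text{permuted} > \text{observed})/B$. The exceed count is reported so
$\ge$ or $(x+1)/(B+1)$ conventions can be recomputed. Fold enrichment of
the reference-match rate among top pairs versus all tested pairs is
reported both exactly and under printed-percentage rounding (numerator to
integer percent, denominator to two decimals), since quoted enrichment
figures are conventionally derived from rounded percentages.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| FDR threshold | 0.05 | per-tissue BH significance |
| replication p | 0.05 | replication call in second cohort |
| condition number bound | 30 | strict $\lambda_{\max}/\lambda_i$ cut for PC retention |
| mappability minimum | 0.8 | strict gene-score cut |
| cross-map maximum | 0 | any positive count excludes the pair |
| min gene-set overlap | 5 | hypergeometric testing floor |
| master-regulator floor | 50 | distinct significant targets |
| permutations B | 1000 | overlap null resolution (min p 1/B) |
| MAF filter | 0.05 | strict lower bound on minor allele frequency |

## The simulator

`simulate_cohort()` draws Hardy–Weinberg dosages at unlinked variants
(MAF uniform on [0.05, 0.5]), gives each gene a sparse set of cis
variants whose effect sizes share a common component across tissues
(correlation `tissue_sharing`), scales weights so the cis component
explains `cis_h2` of regulator expression variance, and adds trans edges:
the target's observed expression is `beta` times the regulator's
expression *in the edge's active tissue* plus Gaussian noise. Emitted
weight stores carry the true weights by default so prediction is exact
and tests isolate the downstream statistics; estimation noise and an
AR(1)-correlated dosage mode (to exercise LD-driven false positives) are
opt-in. Chromosomes are assigned round-robin so cross-chromosome pairing
is always defined; an intra-chromosomal trans edge is rejected.

Defaults — 500 samples, 20 genes, 10 tissues, 5 cis variants per gene,
cis h² = 0.4, cross-tissue sharing ρ = 0.5, β = 0.5 against unit noise —
were fixed by a design power calculation before any testing: with a trans
effect active in a tissue other than the modeled one, the single-tissue
correlation is attenuated to roughly
$\rho\sqrt{h^2}\,\beta/\sqrt{\beta^2+1} \approx 0.14$ (borderline at
n = 500 under BH across ~300 pairs), while the joint fit recovers
$R^2 \approx h^2\beta^2/(\beta^2+1) \approx 0.08$, comfortably
detectable — the regime in which multi-tissue integration should, and in
our tests does, out-power a mismatched single tissue.

What the simulator does **not** emulate: realistic LD panels, imputation
error, count-level RNA-seq noise (expression is generated directly on the
normalized Gaussian scale the scans assume), confounding shared between
genotype and expression batches, and cis weights estimated with error
(unless enabled). Passing calibration and power tests on these cohorts
therefore demonstrates correctness of the statistics under the model's
own assumptions, not robustness to the full messiness of real cohorts —
in particular the LD caveat that trans signals can be false positives
from linked cis effects still applies to real data.

## Numerical choices and degenerate inputs

* p-values below the smallest positive normal double are floored there
  and flagged (`p_underflow`) rather than reported as 0.
* The eigen-decomposition runs on the covariance of **standardized**
  columns (the correlation matrix): tissues are on a common scale only
  after standardization, and the retention rule is scale-free this way.
  Eigenvector sign is fixed by making the largest-magnitude loading
  positive, so scores are reproducible across platforms.
* `multixcan_test()` fits the OLS by QR (`lm.fit`), not by assuming
  orthogonal scores, so its $R^2$ is invariant to any basis rotation of
  the retained span; the bulk `multiscan()` path exploits the exact
  orthogonality of its own PCA scores for speed.
* Constant expression columns are dropped with a warning (a constant
  vector has no defined correlation); genes without a placed chromosome
  are excluded from pairing, since "different chromosome" cannot be
  certified for them.
* Missing dosages are mean-imputed with 2 × MAF at prediction time,
  keeping sample size fixed and the predictor unbiased in expectation.
  Strand-ambiguous (A/T, C/G) model variants are excluded by default at
  prediction time, as their orientation cannot be verified.
* Master-regulator ties are broken lexicographically by gene id.
  All thresholds quoted as strict above are implemented strictly
  (MAF > 0.05, score < 0.8 excluded, ratio < 30 retained, ≥ 50 targets).
* Weight stores are accepted as PredictDB-style SQLite (when `RSQLite`
  is installed) or as an equivalent tab-separated file; zero-weight rows
  are dropped on read and duplicate (gene, variant) records are an error.

## Problem sizes used by the test-suite

Calibration uses 200 replicates of a 200-sample, 50 × 50-gene null
cohort (2,500 cross-chromosome pairs) for both scans; the power
comparison uses 200 simulated cohorts at the simulator defaults with the
trans effect active in tissue 7 of 10; π1 recovery uses 10,000 p-values
per mixture; the permutation null uses B = 1000. These sizes give
Monte-Carlo standard errors small enough for the stated tolerances
(e.g. ±3 binomial SEs on rates over 200 replicates) while the whole
suite stays fast enough to run routinely.

## Known limitations

* Only cis-driven trans regulation is detectable: a regulator with no cis
  model (or no usable variants in the cohort) is invisible.
* PC truncation is conservative; weak tissue-specific components near the
  condition bound are discarded, trading power for stability.
* The scans assume pre-normalized expression (e.g. HCP residuals); no
  covariate interface is exposed.
* eQTLGen-style reference tables are consumed, not derived; the package
  does not run SNP-level trans-eQTL scans.
* Real-data discovery counts depend on controlled-access cohorts and are
  out of scope here; the package's empirical claims are those its tests
  and `scripts/acceptance.R` compute on synthetic cohorts, plus the
  arithmetic identities on published summary counts.
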