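## Replication bookkeeping between a discovery and a replication cohort:
## Storey-style pi1 estimation from the replication p-value distribution,
## p < 0.05 replication flags, and direction consistency.

#' Estimate pi1 (expected true positive rate) from a p-value vector
#'
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` is evaluated on a grid
#' of lambda values; the `smoother` method fits a cubic smoothing spline
#' (df = 3) to `pi0(lambda)` and takes its value at the largest lambda, the
#' `fixed_lambda` method returns `pi0(0.5)`. `pi1 = 1 - pi0`, with pi0
#' clipped to `[0, 1]`. This is the estimator popularized by the qvalue
#' package; only pi0/pi1 are needed here, not per-hypothesis q-values.
#'
#' @param p numeric vector of p-values in `(0, 1]`, length >= 30.
#' @param lambda_grid grid of lambda values (default `seq(0.05, 0.95, 0.05)`).
#' @param method `"smoother"` (default) or `"fixed_lambda"`. The smoother
#'   falls back to fixed-lambda when fewer than 4 usable grid points remain.
#' @return An object of class `pi1_estimate`: `pi0`, `pi1`, `lambda_grid`,
#'   `pi0_lambda` (raw grid estimates), `method`, `n_pvalues`.
#' @export
estimate_pi1 <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05),
                         method = c("smoother", "fixed_lambda")) {
  method <- match.arg(method)
  if (length(p) < 30) stop("unstable pi1: need at least 30 p-values")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  pi0_l <- vapply(lambda_grid, function(l) sum(p > l) / (m * (1 - l)),
                  numeric(1))
  if (method == "smoother") {
    ok <- is.finite(pi0_l)
    if (sum(ok) < 4) {
      method <- "fixed_lambda"
    } else {
      fit <- stats::smooth.spline(lambda_grid[ok], pi0_l[ok], df = 3)
      pi0 <- stats::predict(fit, x = max(lambda_grid[ok]))$y
    }
  }
  if (method == "fixed_lambda") {
    l0 <- lambda_grid[which.min(abs(lambda_grid - 0.5))]
    pi0 <- sum(p > l0) / (m * (1 - l0))
  }
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi0 = pi0, pi1 = 1 - pi0, lambda_grid = lambda_grid,
                 pi0_lambda = pi0_l, method = method, n_pvalues = m),
            class = "pi1_estimate")
}

#' @export
print.pi1_estimate <- function(x, ...) {
  cat(sprintf("pi1 = %.3f (pi0 = %.3f; %s, %d p-values)\n",
              x$pi1, x$pi0, x$method, x$n_pvalues))
  invisible(x)
}

#' Test discovered trans pairs for replication in a second cohort
#'
#' Discovery pairs at `fdr_q < q_thresh` are joined (on trans gene, target
#' gene, and model) to the replication scan; a pair replicates when its
#' replication p-value is below `p_thresh`. Direction consistency compares
#' the sign of the t-statistic between cohorts for single-tissue records;
#' it is undefined (NA) for sign-free multi-tissue F records. Pairs absent
#' from the replication scan are marked untestable. pi1 is estimated from
#' the replication p-values of the testable pairs when at least 30 are
#' available.
#'
#' @param discovery scan records with `fdr_q` (single- or multi-tissue).
#' @param replication scan records with `p` from the replication cohort.
#' @param q_thresh discovery FDR threshold.
#' @param p_thresh replication p-value threshold.
#' @param join_on columns identifying a pair (default
#'   `c("trans_gene", "target_gene", "model")`).
#' @return An object of class `replication_result`: `pairs` (joined table
#'   with `testable`, `replicated`, `direction_consistent`), `summary`
#'   (counts), and `pi1` (a [estimate_pi1()] result or NULL).
#' @export
replicate_pairs <- function(discovery, replication, q_thresh = 0.05,
                            p_thresh = 0.05,
                            join_on = c("trans_gene", "target_gene", "model")) {
  disc <- as.data.frame(discovery)
  repl <- as.data.frame(replication)
  disc <- disc[disc$fdr_q < q_thresh, , drop = FALSE]
  key <- function(d) do.call(paste, c(d[join_on], sep = "\r"))
  i <- match(key(disc), key(repl))
  testable <- !is.na(i)
  rep_p <- ifelse(testable, repl$p[i], NA_real_)
  replicated <- !is.na(rep_p) & rep_p < p_thresh

  has_t <- !is.null(disc$t_stat) && !is.null(repl$t_stat)
  direction_consistent <- if (has_t) {
    ifelse(testable, sign(disc$t_stat) == sign(repl$t_stat[i]), NA)
  } else rep(NA, nrow(disc))

  pairs <- cbind(disc,
                 data.frame(testable = testable, replication_p = rep_p,
                            replicated = replicated,
                            direction_consistent = direction_consistent))
  pi1 <- if (sum(testable) >= 30)
    estimate_pi1(rep_p[testable]) else NULL
  summary <- list(
    discovered = nrow(disc),
    testable = sum(testable),
    replicated = sum(replicated),
    frac_direction_consistent =
      if (has_t && any(testable))
        mean(direction_consistent[testable], na.rm = TRUE) else NA_real_,
    pi1 = if (!is.null(pi1)) pi1$pi1 else NA_real_)
  structure(list(pairs = pairs, summary = summary, pi1 = pi1),
            class = "replication_result")
}

#' @export
print.replication_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("discovered %d | testable %d | replicated %d",
              s$discovered, s$testable, s$replicated))
  if (!is.na(s$frac_direction_consistent))
    cat(sprintf(" | direction-consistent %.2f", s$frac_direction_consistent))
  if (!is.na(s$pi1)) cat(sprintf(" | pi1 %.2f", s$pi1))
  cat("\n")
  invisible(x)
}
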