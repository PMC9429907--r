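# Shared statistical primitives reused across the pipeline stages.

#' Welch two-sample t test
#'
#' Two-sided Welch test (unequal variances, Welch--Satterthwaite degrees of
#' freedom) used to compare virulence indices and spore yields between strains.
#' Thin, validated wrapper over [stats::t.test()] that adds the zero-variance
#' conventions the pipeline needs and a compact result record.
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @return An object of class `welch_test`: list with `t`, `df`, `p`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @details When both groups have zero variance and equal means the test is
#'   degenerate and `t = 0, p = 1` is returned by convention; zero variance
#'   with unequal means (or in only one group) is an error since the statistic
#'   is undefined or infinite.
#' @examples
#' welch_t_test(c(1, 2, 3), c(2, 3, 4, 5))
#' @export
welch_t_test <- function(sample_a, sample_b) {
  sample_a <- as.numeric(sample_a)
  sample_b <- as.numeric(sample_b)
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("welch_t_test: each sample needs n >= 2")
  if (anyNA(sample_a) || anyNA(sample_b))
    stop("welch_t_test: NA values not allowed")
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      res <- list(t = 0, df = length(sample_a) + length(sample_b) - 2, p = 1,
                  mean_a = mean(sample_a), mean_b = mean(sample_b),
                  n_a = length(sample_a), n_b = length(sample_b))
      class(res) <- "welch_test"
      return(res)
    }
    stop("welch_t_test: zero variance in both groups with unequal means")
  }
  if (va == 0 || vb == 0)
    stop("welch_t_test: zero variance in one group")
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
              p = ht$p.value,
              mean_a = mean(sample_a), mean_b = mean(sample_b),
              n_a = length(sample_a), n_b = length(sample_b))
  class(res) <- "welch_test"
  res
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sample t test: t_%.1f = %.3g, P = %.3g\n",
              x$df, x$t, x$p))
  cat(sprintf("  means: %.4g vs %.4g (n = %d, %d)\n",
              x$mean_a, x$mean_b, x$n_a, x$n_b))
  invisible(x)
}

#' One-sample t test on paired differences
#'
#' Used to ask whether total cell density differs between induced cultures and
#' their paired non-induced controls (mean difference != 0, two-sided).
#'
#' @param induced,control Equal-length paired numeric vectors, n >= 2.
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_density_test <- function(induced, control) {
  if (length(induced) != length(control))
    stop("paired_density_test: vectors must be paired (equal length)")
  n <- length(induced)
  if (n < 2) stop("paired_density_test: n >= 2 required")
  d <- as.numeric(induced) - as.numeric(control)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, n = n))
    stop("paired_density_test: zero variance of differences with nonzero mean")
  }
  ht <- stats::t.test(d, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_diff = mean(d), n = n)
}

#' Multiple-testing adjustment
#'
#' Holm step-down or Benjamini--Hochberg / Benjamini--Yekutieli step-up
#' adjustment, clipped to 1 with monotonicity enforced (all via
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @param method One of `"holm"`, `"bh"`, `"by"`.
#' @return Adjusted p values in input order.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh", "by")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("adjust_pvalues: p values must lie in [0, 1]")
  stats::p.adjust(p, method = switch(method, holm = "holm", bh = "BH", by = "BY"))
}

#' Spearman rank correlation with small-sample exact permutation p
#'
#' Computes rho on average ranks (ties allowed). The two-sided p value uses
#' the t approximation, except for small n (default n <= 8) where the exact
#' permutation distribution of |rho| is enumerated over all n! orderings.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param exact_n_max Largest n for which the exact permutation p is used.
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_correlation <- function(x, y, exact_n_max = 8L) {
  n <- length(x)
  if (length(y) != n) stop("spearman_correlation: unequal lengths")
  if (n < 3) stop("spearman_correlation: n >= 3 required")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("spearman_correlation: correlation undefined for constant input")
  rho <- stats::cor(rx, ry)
  if (n <= exact_n_max) {
    perms <- .permutations(n)
    rho_null <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1:n as a matrix (n! rows); n capped to keep memory sane
.permutations <- function(n) {
  if (n > 9L) stop("exact permutation enumeration capped at n = 9")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(rep.int(k, nrow(sub)), sub + (sub >= k))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

# Evaluate an expression under a temporary RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
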