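# Shared statistical primitives: Spearman correlation with exact/approximate
# p-values, hypergeometric overlap tests and Haldane-corrected odds ratios.

.perm_cache <- new.env(parent = emptyenv())

# All permutations of 1..n as an n! x n integer matrix (cached per n).
.permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  build <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    out <- vector("list", length(v))
    for (i in seq_along(v)) {
      sub <- build(v[-i])
      out[[i]] <- cbind(v[i], sub)
    }
    do.call(rbind, out)
  }
  m <- build(seq_len(n))
  .perm_cache[[key]] <- m
  m
}

#' Spearman correlation with a two-sided p-value
#'
#' Computes the Spearman rank correlation between two series using average
#' ranks for ties. For `n >= 10` samples the p-value comes from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`; below 10 samples
#' an exact permutation distribution over all `n!` rank assignments is used.
#'
#' @param x,y Numeric vectors of equal length (at least 3 values).
#' @return A list with elements `rho` and `p` (two-sided). If either series
#'   is constant, `rho` and `p` are `NA` and a warning is raised.
#' @examples
#' spearman_test(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant series: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    p <- .spearman_p_approx(rho, n)
  } else {
    # exact permutation null: correlation of rx against every permutation of ry
    rxs <- (rx - mean(rx))
    rxs <- rxs / sqrt(sum(rxs^2))
    rys <- (ry - mean(ry))
    rys <- rys / sqrt(sum(rys^2))
    perms <- .permutations(n)
    null_rho <- as.numeric(matrix(rys[perms], nrow(perms)) %*% rxs)
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = p)
}

# vectorised two-sided t-approximation p-value for Spearman rho
.spearman_p_approx <- function(rho, n) {
  r2 <- pmin(rho^2, 1 - 1e-12)
  tstat <- abs(rho) * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
}

#' One-sided hypergeometric overlap p-value
#'
#' Probability of observing an overlap at least as large as `a` between a set
#' of size `k1` and a set of size `k2` drawn from a universe of size `n`
#' (upper tail, `P(X >= a)`).
#'
#' @param a Observed overlap size.
#' @param k1,k2 Sizes of the two sets.
#' @param n Universe size.
#' @return A single p-value.
#' @export
hypergeom_p <- function(a, k1, k2, n) {
  stopifnot(n >= 1, a >= 0, k1 <= n, k2 <= n, a <= min(k1, k2))
  stats::phyper(a - 1, k1, n - k1, k2, lower.tail = FALSE)
}

#' Odds ratio of a 2x2 table with Haldane-Anscombe correction
#'
#' Returns `(a * d) / (b * c)`. When any cell is zero, 0.5 is added to every
#' cell (Haldane-Anscombe) so the ratio stays finite and non-degenerate.
#'
#' @param a,b,c,d Cell counts of the 2x2 table.
#' @return The (possibly corrected) odds ratio.
#' @export
odds_ratio <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  (a * d) / (b * c)
}

#' Overlap statistics for two gene sets over a universe
#'
#' Builds the 2x2 membership table of two sets over a common universe and
#' returns the cell counts together with the Haldane-corrected odds ratio and
#' the one-sided hypergeometric enrichment p-value (computed from the
#' uncorrected counts).
#'
#' @param set1,set2 Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible identifiers.
#' @return A list with `a`, `b`, `c`, `d`, `odds_ratio` and `p`.
#' @export
overlap_test <- function(set1, set2, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  set1 <- unique(set1)
  set2 <- unique(set2)
  if (!all(set1 %in% universe) || !all(set2 %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  a <- length(intersect(set1, set2))
  b <- length(set1) - a
  c <- length(set2) - a
  d <- length(universe) - a - b - c
  list(
    a = a, b = b, c = c, d = d,
    odds_ratio = odds_ratio(a, b, c, d),
    p = hypergeom_p(a, length(set1), length(set2), length(universe))
  )
}

# seed helper: all generators draw from a stream derived from one user seed,
# with a fixed per-stage offset so stages stay independent of each other.
.with_stage_seed <- function(seed, offset, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  derived <- (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
  withr::with_seed(derived, code)
}
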