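# Differential-expression calling and Spearman co-expression network
# construction, with expression-half stratification, distance stratification
# and the negative-bias signed-rank test.

#' Call differentially expressed transcripts per drug
#'
#' A transcript is up-regulated for a drug when its abundance ratio against
#' the matched solvent control exceeds `fc_threshold` at *both* time points
#' (3 h and 6 h), and down-regulated when the ratio falls below
#' `1 / fc_threshold` at both. Ratios are computed after adding a small
#' pseudocount to numerator and denominator so zero-abundance transcripts do
#' not produce infinite fold changes.
#'
#' @param expr Expression `SummarizedExperiment` (see
#'   [simulate_expression()]).
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @param pseudocount RPKM pseudocount added to both sides of the ratio.
#' @return A data.frame with columns `drug`, `transcript`, `direction`
#'   (`up`/`down`), `fc_3h`, `fc_6h`.
#' @export
call_de <- function(expr, fc_threshold = 1.5, pseudocount = 0.1) {
  vals <- expr_values(expr)
  meta <- expr_samples(expr)
  drugs <- unique(meta$drug[!meta$solvent_flag])
  out <- list()
  for (d in drugs) {
    rows_d <- meta[meta$drug == d & !meta$solvent_flag, , drop = FALSE]
    if (!all(c(3L, 6L) %in% rows_d$timepoint_h)) {
      warning(sprintf("drug %s lacks both time points; skipped", d))
      next
    }
    solv <- unique(rows_d$solvent)
    fc <- sapply(c(3L, 6L), function(tp) {
      trt <- rows_d$sample[rows_d$timepoint_h == tp][1L]
      ctl <- meta$sample[meta$solvent_flag & meta$solvent == solv &
                         meta$timepoint_h == tp]
      if (length(ctl) == 0L) {
        stop(sprintf("no %s solvent control at %d h for drug %s",
                     solv, tp, d))
      }
      (vals[, trt] + pseudocount) / (vals[, ctl[1L]] + pseudocount)
    })
    up <- fc[, 1L] > fc_threshold & fc[, 2L] > fc_threshold
    down <- fc[, 1L] < 1 / fc_threshold & fc[, 2L] < 1 / fc_threshold
    keep <- up | down
    if (!any(keep)) next
    out[[d]] <- data.frame(
      drug = d,
      transcript = rownames(vals)[keep],
      direction = ifelse(up[keep], "up", "down"),
      fc_3h = fc[keep, 1L],
      fc_6h = fc[keep, 2L],
      row.names = NULL,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(drug = character(), transcript = character(),
                      direction = character(), fc_3h = numeric(),
                      fc_6h = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Spearman correlation of every vlincRNA against every mRNA
#'
#' Computes, over all samples, the Spearman rank correlation (average ranks
#' for ties) and its two-sided p-value for every (vlincRNA, mRNA) pair. With
#' 10 or more samples the p-value uses the t-approximation; below 10, the
#' exact permutation distribution. Constant series are skipped with a
#' warning.
#'
#' @param expr Expression `SummarizedExperiment`.
#' @return A data.frame `vlinc`, `gene`, `rho`, `p` covering all pairs.
#' @export
coexpression_scores <- function(expr) {
  vals <- expr_values(expr)
  n <- ncol(vals)
  if (n < 5L) stop("at least 5 samples required")
  vlincs <- expr_ids(expr, "vlincRNA")
  genes <- expr_ids(expr, "mRNA")
  if (length(vlincs) == 0L || length(genes) == 0L) {
    stop("expression matrix must contain both vlincRNAs and mRNAs")
  }
  const <- apply(vals, 1L, function(r) stats::sd(r) == 0)
  if (any(const)) {
    warning(sprintf("%d constant series skipped (rho undefined)", sum(const)))
  }
  vl_use <- setdiff(vlincs, rownames(vals)[const])
  g_use <- setdiff(genes, rownames(vals)[const])
  ranks <- t(apply(vals[c(vl_use, g_use), , drop = FALSE], 1L, rank))
  rho <- stats::cor(t(ranks[vl_use, , drop = FALSE]),
                    t(ranks[g_use, , drop = FALSE]))
  res <- data.frame(
    vlinc = rep(vl_use, times = length(g_use)),
    gene = rep(g_use, each = length(vl_use)),
    rho = as.numeric(rho),
    stringsAsFactors = FALSE
  )
  if (n >= 10L) {
    res$p <- .spearman_p_approx(res$rho, n)
  } else {
    res$p <- mapply(function(v, g) {
      spearman_test(vals[v, ], vals[g, ])$p
    }, res$vlinc, res$gene)
  }
  res
}

#' Build the thresholded co-expression network
#'
#' Retains every (vlincRNA, mRNA) pair with `|rho| > rho_min` and
#' `p < p_max` (the study's thresholds: 0.35 and 0.01, with no multiplicity
#' correction across pairs). The edge sign is the sign of rho.
#'
#' @param expr Expression `SummarizedExperiment`.
#' @param rho_min Minimum correlation magnitude (exclusive).
#' @param p_max Maximum p-value (exclusive).
#' @param scores Optional precomputed output of [coexpression_scores()].
#' @return A data.frame `vlinc`, `gene`, `rho`, `p`, `sign` with attributes
#'   `rho_min`, `p_max` and `vlincs` (all vlincRNAs scored, including those
#'   with zero retained edges).
#' @export
spearman_network <- function(expr, rho_min = 0.35, p_max = 0.01,
                             scores = NULL) {
  if (is.null(scores)) scores <- coexpression_scores(expr)
  keep <- abs(scores$rho) > rho_min & scores$p < p_max
  net <- scores[keep, , drop = FALSE]
  net$sign <- ifelse(net$rho > 0, "positive", "negative")
  rownames(net) <- NULL
  attr(net, "rho_min") <- rho_min
  attr(net, "p_max") <- p_max
  attr(net, "vlincs") <- unique(scores$vlinc)
  class(net) <- c("coexpression_network", "data.frame")
  net
}

#' Split genes into expression halves
#'
#' Ranks mRNAs by their maximum abundance over all samples (descending),
#' keeping only genes with a maximum above zero, and labels the top 50% as
#' `top` and the rest as `bottom`. With an odd count the top half receives
#' the extra gene. Ties in the maximum are broken by gene id so the split is
#' deterministic.
#'
#' @param expr Expression `SummarizedExperiment`.
#' @return A data.frame `gene`, `max_abund`, `half` ordered by decreasing
#'   maximum abundance.
#' @export
stratify_by_expression <- function(expr) {
  vals <- expr_values(expr)[expr_ids(expr, "mRNA"), , drop = FALSE]
  mx <- apply(vals, 1L, max)
  keep <- mx > 0
  mx <- mx[keep]
  ord <- order(-mx, names(mx))
  mx <- mx[ord]
  n_top <- ceiling(length(mx) / 2)
  data.frame(
    gene = names(mx),
    max_abund = unname(mx),
    half = rep(c("top", "bottom"), c(n_top, length(mx) - n_top)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Median network correlation by genomic distance
#'
#' For network edges whose gene lies on the same chromosome as the vlincRNA,
#' computes the gap between the two intervals (0 when they overlap or are
#' adjacent) and reports the median rho per distance bin. Genes on other
#' chromosomes fall in no bin; empty bins are reported as `NA`.
#'
#' @param net A [spearman_network()] result.
#' @param annotation `GRanges` annotation covering all network features.
#' @param breaks Bin boundaries in bases (right-open; the last bin is
#'   unbounded). Defaults to the 0-5 kb / 5-10 kb / 10-100 kb / >100 kb
#'   stratification.
#' @return A named numeric vector of per-bin median rho values.
#' @export
distance_stratified_medians <- function(net, annotation,
                                        breaks = c(0, 5e3, 1e4, 1e5)) {
  if (!all(c(net$vlinc, net$gene) %in% names(annotation))) {
    stop("annotation does not cover all network features")
  }
  kb <- function(x) paste0(x / 1e3, "kb")
  labels <- c(paste0("[", kb(breaks[-length(breaks)]), ",",
                     kb(breaks[-1]), ")"),
              paste0(">=", kb(breaks[length(breaks)])))
  d <- suppressWarnings(
    GenomicRanges::distance(annotation[net$vlinc], annotation[net$gene]))
  med <- rep(NA_real_, length(breaks))
  names(med) <- labels
  bin <- findInterval(d, c(breaks, Inf), rightmost.closed = FALSE)
  for (b in seq_along(breaks)) {
    sel <- !is.na(d) & bin == b
    if (any(sel)) med[b] <- stats::median(net$rho[sel])
  }
  med
}

#' Test the genome-wide bias towards negative co-expression
#'
#' Counts negative and positive network edges per vlincRNA and applies a
#' one-sided Wilcoxon signed-rank test of the paired counts
#' (negative > positive), mirroring the study's global negative-correlation
#' bias test.
#'
#' @param net A [spearman_network()] result covering at least 2 vlincRNAs.
#' @return A list with `p`, `n_negative`, `n_positive` (per-vlincRNA counts).
#' @export
negative_bias_test <- function(net) {
  vlincs <- attr(net, "vlincs")
  if (is.null(vlincs)) vlincs <- unique(net$vlinc)
  if (length(vlincs) < 2L) stop("at least 2 vlincRNAs required")
  n_neg <- vapply(vlincs, function(v) sum(net$vlinc == v & net$sign == "negative"),
                  numeric(1))
  n_pos <- vapply(vlincs, function(v) sum(net$vlinc == v & net$sign == "positive"),
                  numeric(1))
  if (all(n_neg == n_pos)) {
    warning("all pairs tied; p = 1")
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(n_neg, n_pos, paired = TRUE,
                         alternative = "greater")$p.value)
  }
  list(p = p, n_negative = n_neg, n_positive = n_pos)
}
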