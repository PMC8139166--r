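# Cas13 knockdown effect quantification: bounded fold changes (FC), relative
# fold changes (RFC) and between-group effect-size summaries.

#' Filter knockdown tables for expressed genes
#'
#' Keeps genes whose FPKM exceeds `min_fpkm` in at least one of the six
#' arm x day columns.
#'
#' @param table A `knockdown_table` data.frame with columns `T0`, `T3`, `T6`,
#'   `NT0`, `NT3`, `NT6`.
#' @param min_fpkm Threshold (default 1).
#' @return The filtered table.
#' @export
filter_expressed <- function(table, min_fpkm = 1) {
  cols <- c("T0", "T3", "T6", "NT0", "NT3", "NT6")
  stopifnot(all(cols %in% names(table)))
  mx <- do.call(pmax, table[cols])
  table[mx > min_fpkm, , drop = FALSE]
}

#' Bounded fold changes and relative fold changes under knockdown
#'
#' For each gene computes the bounded fold change of day 3 or 6 against day 0
#' within each arm, `FC-Td = Td / (Td + T0)` (targeting) and
#' `FC-NTd = NTd / (NTd + NT0)` (mismatch control), then the relative fold
#' change `RFC-Td = FC-Td / (FC-Td + FC-NTd)` and the day-averaged
#' `RFC-T3/6 = (RFC-T3 + RFC-T6) / 2`. Both quantities equal exactly 0.5
#' under no change and are bounded in (0, 1). A pseudocount is added to every
#' FPKM value before the ratios so zero-expression genes do not produce 0/0.
#'
#' @param table A (filtered) `knockdown_table`.
#' @param pseudocount FPKM pseudocount (default 0.01).
#' @return A data.frame with `gene`, the four FC columns, `RFC_T3`, `RFC_T6`
#'   and `RFC_T36`.
#' @export
relative_fold_change <- function(table, pseudocount = 0.01) {
  cols <- c("T0", "T3", "T6", "NT0", "NT3", "NT6")
  stopifnot(all(cols %in% names(table)), pseudocount > 0)
  v <- lapply(table[cols], function(x) x + pseudocount)
  fc <- function(num, den) num / (num + den)
  FC_T3 <- fc(v$T3, v$T0)
  FC_T6 <- fc(v$T6, v$T0)
  FC_NT3 <- fc(v$NT3, v$NT0)
  FC_NT6 <- fc(v$NT6, v$NT0)
  RFC_T3 <- FC_T3 / (FC_T3 + FC_NT3)
  RFC_T6 <- FC_T6 / (FC_T6 + FC_NT6)
  data.frame(
    gene = table$gene,
    FC_T3 = FC_T3, FC_T6 = FC_T6, FC_NT3 = FC_NT3, FC_NT6 = FC_NT6,
    RFC_T3 = RFC_T3, RFC_T6 = RFC_T6, RFC_T36 = (RFC_T3 + RFC_T6) / 2,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Group genes by co-expression with the targeted vlincRNA
#'
#' Splits genes into the four groups used in the knockdown analysis:
#' significant positive network (`rho > rho_min`, `p < p_max`), significant
#' negative network (`rho < -rho_min`, `p < p_max`), and the background
#' controls (genes with positive / negative rho that did not reach both
#' thresholds). Also extracts the top-n most strongly correlated network
#' genes per sign (ranked by |rho|).
#'
#' @param scores [coexpression_scores()] rows for the targeted vlincRNA
#'   (columns `gene`, `rho`, `p`), covering all expressed genes.
#' @param rho_min,p_max Network thresholds (defaults 0.35 and 0.01).
#' @param top_n Integer vector of top-n subset sizes (default `c(50, 100)`).
#' @return A named list of gene-id vectors: `positive`, `negative`,
#'   `background_positive`, `background_negative` and `top<k>_positive` /
#'   `top<k>_negative` for each requested `k`.
#' @export
group_genes <- function(scores, rho_min = 0.35, p_max = 0.01,
                        top_n = c(50L, 100L)) {
  stopifnot(all(c("gene", "rho", "p") %in% names(scores)))
  sig <- abs(scores$rho) > rho_min & scores$p < p_max
  groups <- list(
    positive = scores$gene[sig & scores$rho > 0],
    negative = scores$gene[sig & scores$rho < 0],
    background_positive = scores$gene[!sig & scores$rho > 0],
    background_negative = scores$gene[!sig & scores$rho < 0]
  )
  for (k in top_n) {
    for (sgn in c("positive", "negative")) {
      g <- groups[[sgn]]
      if (length(g) < k) {
        warning(sprintf("%s network smaller than top %d; using all %d genes",
                        sgn, k, length(g)))
        sel <- g
      } else {
        r <- abs(scores$rho[match(g, scores$gene)])
        sel <- g[order(-r)][seq_len(k)]
      }
      groups[[sprintf("top%d_%s", k, sgn)]] <- sel
    }
  }
  groups
}

# Cohen's d with pooled SD ((n1 + n2 - 2) denominator); NA when the pooled
# SD is zero.
cohens_d <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Effect-size summary of knockdown responses between gene groups
#'
#' For each comparison (all / top-100 / top-50 negative vs positive network
#' genes, and background-negative vs background-positive), reports the
#' difference of median RFCs (negative minus positive), Cohen's d, and a
#' one-sided Wilcoxon rank-sum p-value of negative > positive. In `by_day`
#' mode days 3 and 6 are analysed separately (columns `RFC_T3`, `RFC_T6`);
#' `combined` pools the two days' RFC values. Groups with fewer than 3 genes
#' give missing statistics.
#'
#' @param rfc Output of [relative_fold_change()].
#' @param groups Output of [group_genes()].
#' @param mode `"combined"` or `"by_day"`.
#' @return A data.frame with one row per comparison (x day in `by_day`
#'   mode): `comparison`, `day`, `n_neg`, `n_pos`, `median_diff`,
#'   `cohens_d`, `p`.
#' @export
effect_summary <- function(rfc, groups, mode = c("combined", "by_day")) {
  mode <- match.arg(mode)
  pairs <- list(all = c("negative", "positive"),
                background = c("background_negative", "background_positive"))
  top_ks <- sort(unique(as.integer(
    sub("^top(\\d+)_.*$", "\\1", grep("^top\\d+_", names(groups), value = TRUE)))))
  for (k in top_ks) {
    pairs[[sprintf("top%d", k)]] <-
      c(sprintf("top%d_negative", k), sprintf("top%d_positive", k))
  }
  days <- if (mode == "combined") "combined" else c("day3", "day6")
  rows <- list()
  for (cmp in names(pairs)) {
    gneg <- intersect(groups[[pairs[[cmp]][1L]]], rfc$gene)
    gpos <- intersect(groups[[pairs[[cmp]][2L]]], rfc$gene)
    for (d in days) {
      vals <- function(g) {
        idx <- match(g, rfc$gene)
        switch(d,
               combined = c(rfc$RFC_T3[idx], rfc$RFC_T6[idx]),
               day3 = rfc$RFC_T3[idx],
               day6 = rfc$RFC_T6[idx])
      }
      xn <- vals(gneg)
      xp <- vals(gpos)
      if (length(gneg) < 3L || length(gpos) < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = cmp, day = d, n_neg = length(gneg),
          n_pos = length(gpos), median_diff = NA_real_,
          cohens_d = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = cmp, day = d, n_neg = length(gneg), n_pos = length(gpos),
        median_diff = stats::median(xn) - stats::median(xp),
        cohens_d = cohens_d(xn, xp),
        p = suppressWarnings(
          stats::wilcox.test(xn, xp, alternative = "greater")$p.value),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
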