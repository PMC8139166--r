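# Overlap of co-expression networks with RAT gene sets, final threshold
# selection, network stability across treatments and cis/trans structure.

#' Expression-stratified overlap of a network with RAT gene sets
#'
#' Splits the network edges of one vlincRNA into four groups (sign x
#' expression half) and, for each group, computes the 2x2 overlap against the
#' RAT-called gene set within the expressed-gene universe, with
#' Haldane-corrected odds ratio and one-sided hypergeometric p-value. Empty
#' groups are flagged with `p = 1`.
#'
#' @param net A [spearman_network()] result (one or more vlincRNAs; rows for
#'   other vlincRNAs are ignored if `vlinc` is given).
#' @param rat_genes Character vector of genes called by the RAT analysis.
#' @param halves Output of [stratify_by_expression()] computed from the same
#'   expression matrix as the network.
#' @param universe Character vector of expressed genes (max abundance > 0).
#' @param vlinc Optional vlincRNA id to restrict to.
#' @param percentile,level Provenance labels copied into the result.
#' @return A data.frame with one row per sign x half group: `vlinc`, `sign`,
#'   `half`, `n_group`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`, `percentile`,
#'   `level`, `empty`.
#' @export
stratified_overlap <- function(net, rat_genes, halves, universe,
                               vlinc = NULL, percentile = NA, level = NA) {
  if (!is.null(vlinc)) net <- net[net$vlinc == vlinc, , drop = FALSE]
  vl <- if (is.null(vlinc)) unique(net$vlinc) else vlinc
  if (length(vl) != 1L) stop("stratified_overlap works on one vlincRNA at a time")
  rat_genes <- intersect(rat_genes, universe)
  half_of <- stats::setNames(halves$half, halves$gene)
  rows <- list()
  for (sgn in c("negative", "positive")) {
    for (h in c("top", "bottom")) {
      grp <- net$gene[net$sign == sgn]
      grp <- grp[grp %in% universe & half_of[grp] == h]
      grp <- grp[!is.na(grp)]
      if (length(grp) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          vlinc = vl, sign = sgn, half = h, n_group = 0L,
          a = 0L, b = 0L, c = length(rat_genes),
          d = length(universe) - length(rat_genes),
          odds_ratio = NA_real_, p = 1, percentile = percentile,
          level = level, empty = TRUE, stringsAsFactors = FALSE)
        next
      }
      ov <- overlap_test(grp, rat_genes, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        vlinc = vl, sign = sgn, half = h, n_group = length(grp),
        a = ov$a, b = ov$b, c = ov$c, d = ov$d,
        odds_ratio = ov$odds_ratio, p = ov$p, percentile = percentile,
        level = level, empty = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Select the final RAT percentile threshold per sign
#'
#' From gene-level stratified overlaps across all percentiles, picks for each
#' sign the percentile with the lowest p-value in the designated group:
#' negatively co-expressed genes in the top expression half and positively
#' co-expressed genes in the bottom half. Ties go to the stricter (smaller)
#' percentile. The validated sets are the intersections of the sign's network
#' genes with the RAT gene set at the chosen percentile.
#'
#' @param overlaps Row-bound [stratified_overlap()] results at gene level,
#'   covering all percentiles (column `percentile` filled in).
#' @param net The [spearman_network()] rows for this vlincRNA.
#' @param rat_gene_sets Named list of RAT gene-id vectors, one per percentile
#'   (names `"1"`, `"5"`, ...), gene level.
#' @return An object of class `final_network`: list with `vlinc`,
#'   `percentile` (named per sign), `validated` (named list of gene vectors
#'   per sign) and `fallback` flag (all p = 1 for a sign).
#' @export
select_final_threshold <- function(overlaps, net, rat_gene_sets) {
  overlaps <- overlaps[overlaps$level %in% c("gene", NA), , drop = FALSE]
  vl <- unique(overlaps$vlinc)
  stopifnot(length(vl) == 1L)
  designated <- c(negative = "top", positive = "bottom")
  chosen <- c(negative = NA_real_, positive = NA_real_)
  fallback <- c(negative = FALSE, positive = FALSE)
  validated <- list(negative = character(0), positive = character(0))
  for (sgn in names(designated)) {
    sub <- overlaps[overlaps$sign == sgn & overlaps$half == designated[sgn], ,
                    drop = FALSE]
    if (nrow(sub) == 0L) stop("no gene-level overlaps for sign ", sgn)
    sub <- sub[order(sub$percentile), , drop = FALSE]
    if (all(sub$p >= 1)) {
      fallback[sgn] <- TRUE
      chosen[sgn] <- min(sub$percentile)
    } else {
      best <- which(sub$p == min(sub$p))
      chosen[sgn] <- sub$percentile[best[1L]]  # stricter wins on ties
    }
    rat <- rat_gene_sets[[as.character(chosen[sgn])]]
    validated[[sgn]] <- intersect(net$gene[net$sign == sgn &
                                           net$vlinc == vl], rat)
  }
  structure(list(vlinc = vl, percentile = chosen, validated = validated,
                 fallback = fallback),
            class = "final_network")
}

#' @export
print.final_network <- function(x, ...) {
  cat(sprintf("final_network %s: negative %d genes @ %g%%, positive %d genes @ %g%%\n",
              x$vlinc, length(x$validated$negative), x$percentile["negative"],
              length(x$validated$positive), x$percentile["positive"]))
  invisible(x)
}

#' Network stability across treatments
#'
#' For each vlincRNA and edge sign, compares the validated gene sets obtained
#' under different treatments pairwise: shared fraction
#' `|intersection| / |smaller set|`, odds ratio and one-sided hypergeometric
#' p against the expressed universe. VlincRNAs with fewer than two treatments
#' are skipped.
#'
#' @param finals Named list (by treatment) of `final_network` objects for the
#'   same vlincRNA.
#' @param universe Character vector of expressed genes.
#' @return A data.frame with one row per (sign, treatment pair).
#' @export
network_stability <- function(finals, universe) {
  if (length(finals) < 2L) stop("at least two treatments required")
  treatments <- names(finals)
  rows <- list()
  for (sgn in c("negative", "positive")) {
    for (i in seq_len(length(treatments) - 1L)) {
      for (j in seq((i + 1L), length(treatments))) {
        s1 <- intersect(finals[[i]]$validated[[sgn]], universe)
        s2 <- intersect(finals[[j]]$validated[[sgn]], universe)
        smaller <- min(length(s1), length(s2))
        frac <- if (smaller == 0L) NA_real_ else
          length(intersect(s1, s2)) / smaller
        ov <- overlap_test(s1, s2, universe)
        rows[[length(rows) + 1L]] <- data.frame(
          vlinc = finals[[i]]$vlinc, sign = sgn,
          treatment_a = treatments[i], treatment_b = treatments[j],
          shared_fraction = frac, odds_ratio = ov$odds_ratio, p = ov$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cis versus genome-wide overlap odds ratios
#'
#' For every sample (a vlincRNA-treatment-sign combination), recomputes the
#' network/RAT overlap odds ratio restricted to genes on the vlincRNA's own
#' chromosome and compares the cis odds ratios against the genome-wide ones
#' across samples with a two-sided Wilcoxon rank-sum test; the direction
#' (median cis OR minus median genome-wide OR) is reported alongside.
#'
#' @param samples A list; each element is a list with fields `vlinc`,
#'   `coexpr_genes`, `rat_genes`, `universe`.
#' @param annotation `GRanges` annotation giving the chromosome of every
#'   feature.
#' @return A list with `per_sample` (data.frame of cis and genome-wide ORs),
#'   `p` (two-sided rank-sum) and `direction`.
#' @export
cis_trans_comparison <- function(samples, annotation) {
  chrom_of <- stats::setNames(as.character(GenomeInfoDb::seqnames(annotation)),
                              names(annotation))
  rows <- list()
  for (s in samples) {
    ov_all <- overlap_test(intersect(s$coexpr_genes, s$universe),
                           intersect(s$rat_genes, s$universe), s$universe)
    cis_universe <- s$universe[chrom_of[s$universe] == chrom_of[s$vlinc]]
    cis_coexpr <- intersect(s$coexpr_genes, cis_universe)
    if (length(cis_coexpr) == 0L || length(cis_universe) == 0L) {
      message(sprintf("sample %s: no cis genes; excluded", s$vlinc))
      next
    }
    ov_cis <- overlap_test(cis_coexpr, intersect(s$rat_genes, cis_universe),
                           cis_universe)
    rows[[length(rows) + 1L]] <- data.frame(
      vlinc = s$vlinc, or_all = ov_all$odds_ratio, or_cis = ov_cis$odds_ratio,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(list(per_sample = NULL, p = NA_real_, direction = NA_real_))
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  p <- suppressWarnings(
    stats::wilcox.test(tab$or_cis, tab$or_all)$p.value)
  list(per_sample = tab, p = p,
       direction = stats::median(tab$or_cis) - stats::median(tab$or_all))
}
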