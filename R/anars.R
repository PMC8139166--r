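# ANARS: average normalised aggregated RAT score over scaled gene bodies and
# unscaled 5-kb flanks, plus the top-30% and cis-vs-all rank-sum tests.

#' Scale a gene-body score vector to 5000 positions
#'
#' Relative position `j` (1..5000) takes the mean of the base scores in the
#' half-open slice `[floor((j-1) * L / 5000), floor(j * L / 5000))` of the
#' gene. For genes shorter than 5000 bases some slices are empty; those
#' positions take the score of the base containing them. The input vector is
#' assumed already oriented 5' to 3'.
#'
#' @param scores Numeric vector of per-base scores over the gene body.
#' @param positions Number of relative positions (default 5000).
#' @return A numeric vector of length `positions`.
#' @export
scale_gene <- function(scores, positions = 5000L) {
  L <- length(scores)
  stopifnot(L >= 1L)
  if (L == positions) return(as.numeric(scores))
  j <- seq_len(positions)
  lo <- floor((j - 1) * L / positions)
  hi <- floor(j * L / positions)
  cs <- c(0, cumsum(scores))
  out <- numeric(positions)
  nonempty <- hi > lo
  out[nonempty] <- (cs[hi[nonempty] + 1L] - cs[lo[nonempty] + 1L]) /
    (hi[nonempty] - lo[nonempty])
  out[!nonempty] <- scores[lo[!nonempty] + 1L]
  out
}

# per-base scores of an interval from an averaged track, oriented by strand
.track_window <- function(track, chrom, start, end, minus_strand = FALSE) {
  rle <- track$score[[chrom]]
  len <- length(rle)
  lo <- max(1L, start)
  hi <- min(len, end)
  v <- numeric(end - start + 1L)
  if (hi >= lo) {
    v[(lo - start + 1L):(hi - start + 1L)] <- as.numeric(S4Vectors::window(rle, lo, hi))
  }
  if (minus_strand) rev(v) else v
}

#' Compute the ANARS metagene profile of a gene group
#'
#' For every gene of the group, extracts the replica-averaged normalised RAT
#' score over the gene body (scaled to 5000 relative positions, oriented 5'
#' to 3') and over the unscaled 5-kb flanking windows immediately upstream
#' and downstream (strand-oriented, positions running towards / away from
#' the gene in transcription direction). The profile is the per-position mean
#' over genes.
#'
#' @param track An averaged `rat_track` (see [average_replicas()]).
#' @param genes Character vector of gene ids (non-empty).
#' @param annotation `GRanges` annotation covering the genes.
#' @param group Label stored in the profile (`positive`, `negative`,
#'   `background`, `cis`, `all`, ...).
#' @param flank Flank width in bases (default 5000).
#' @param positions Number of scaled body positions (default 5000).
#' @return An object of class `anars_profile`: list with numeric vectors
#'   `body`, `upstream`, `downstream` (length `positions`), plus `group` and
#'   `n_genes`.
#' @export
compute_anars <- function(track, genes, annotation, group = "all",
                          flank = 5000L, positions = 5000L) {
  stopifnot(inherits(track, "rat_track"))
  if (length(genes) == 0L) stop("empty gene group")
  if (!all(genes %in% names(annotation))) {
    stop("annotation does not cover all genes in the group")
  }
  gr <- annotation[genes]
  body <- matrix(0, positions, length(genes))
  up <- matrix(0, positions, length(genes))
  down <- matrix(0, positions, length(genes))
  ch <- as.character(GenomeInfoDb::seqnames(gr))
  st <- BiocGenerics::start(gr)
  en <- BiocGenerics::end(gr)
  minus <- as.character(BiocGenerics::strand(gr)) == "-"
  for (i in seq_along(genes)) {
    body[, i] <- scale_gene(
      .track_window(track, ch[i], st[i], en[i], minus[i]), positions)
    before <- .track_window(track, ch[i], st[i] - flank, st[i] - 1L, minus[i])
    after <- .track_window(track, ch[i], en[i] + 1L, en[i] + flank, minus[i])
    if (minus[i]) {
      up[, i] <- after
      down[, i] <- before
    } else {
      up[, i] <- before
      down[, i] <- after
    }
  }
  structure(
    list(body = rowMeans(body), upstream = rowMeans(up),
         downstream = rowMeans(down), group = group,
         n_genes = length(genes)),
    class = "anars_profile")
}

#' @export
print.anars_profile <- function(x, ...) {
  cat(sprintf("anars_profile [%s]: %d genes, mean body score %.4g\n",
              x$group, x$n_genes, mean(x$body)))
  invisible(x)
}

.profile_region <- function(profile, region) {
  if (is.numeric(profile)) return(profile)
  stopifnot(inherits(profile, "anars_profile"))
  profile[[region]]
}

#' Top-30% enrichment test between two ANARS profiles
#'
#' Ranks each profile's positional values independently, extracts the top
#' 30% of each, and applies a one-sided Wilcoxon rank-sum test of
#' `a > b` on the two subsets. This is the formal comparison of co-expressed
#' versus background metagene signal.
#'
#' @param a,b `anars_profile` objects (or plain numeric vectors).
#' @param region `"body"`, `"upstream"` or `"downstream"` (ignored for
#'   numeric input).
#' @param top Fraction of top positions used (default 0.3).
#' @return One-sided p-value.
#' @export
top30_test <- function(a, b, region = "body", top = 0.3) {
  va <- .profile_region(a, region)
  vb <- .profile_region(b, region)
  ka <- ceiling(length(va) * top)
  kb <- ceiling(length(vb) * top)
  ta <- sort(va, decreasing = TRUE)[seq_len(ka)]
  tb <- sort(vb, decreasing = TRUE)[seq_len(kb)]
  suppressWarnings(
    stats::wilcox.test(ta, tb, alternative = "greater")$p.value)
}

#' Cis versus all co-expressed ANARS comparison
#'
#' Drops zero-valued positions from both profiles, then applies a one-sided
#' Wilcoxon rank-sum test of cis > all. Skipped with a warning when either
#' vector is all-zero.
#'
#' @param profile_cis,profile_all `anars_profile` objects (or numeric
#'   vectors); the cis genes are a subset of all co-expressed genes.
#' @param region `"body"`, `"upstream"` or `"downstream"`.
#' @return One-sided p-value, or `NA` when a side has no non-zero values.
#' @export
cis_vs_all_test <- function(profile_cis, profile_all, region = "body") {
  vc <- .profile_region(profile_cis, region)
  va <- .profile_region(profile_all, region)
  vc <- vc[vc != 0]
  va <- va[va != 0]
  if (length(vc) == 0L || length(va) == 0L) {
    warning("all-zero profile; cis-vs-all test skipped")
    return(NA_real_)
  }
  suppressWarnings(
    stats::wilcox.test(vc, va, alternative = "greater")$p.value)
}
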