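# RAT signal processing: read-depth normalisation, no-oligo control
# subtraction, replica averaging, percentile-threshold region calling and
# replica-concordance statistics.

#' Normalise a raw RAT coverage track by total read count
#'
#' Divides the per-base coverage by the track's total read count, mirroring
#' the density-format conversion used upstream of all RAT analyses.
#'
#' @param track A raw `rat_track`.
#' @param total_reads Total read count; defaults to the count recorded in the
#'   track. Must be positive.
#' @return A `rat_track` at stage `"normalized"`.
#' @export
normalize_track <- function(track, total_reads = track$total_reads) {
  stopifnot(inherits(track, "rat_track"))
  if (is.null(total_reads) || total_reads <= 0) {
    stop("total_reads must be positive")
  }
  track$score <- track$score / total_reads
  track$stage <- "normalized"
  track
}

#' Subtract the no-oligo control signal
#'
#' Per-base difference between a normalised oligo-set track and the
#' normalised no-oligo control of the same vlincRNA, treatment and replica.
#' Negative values are retained; the downstream `> 0` threshold removes them
#' at region calling.
#'
#' @param track Normalised oligo-set `rat_track`.
#' @param control Normalised `rat_track` with source `"no_oligo"`.
#' @return A `rat_track` at stage `"subtracted"` (provenance of `track`).
#' @export
subtract_control <- function(track, control) {
  stopifnot(inherits(track, "rat_track"), inherits(control, "rat_track"))
  if (control$source != "no_oligo") stop("control must be a no_oligo track")
  if (track$treatment != control$treatment || track$vlinc != control$vlinc) {
    stop("track and control provenance mismatch (treatment/vlincRNA)")
  }
  if (track$stage != "normalized" || control$stage != "normalized") {
    stop("both tracks must be normalized before subtraction")
  }
  track$score <- track$score - control$score
  track$stage <- "subtracted"
  track
}

#' Average the two biological replicas
#'
#' Per-base arithmetic mean of two control-subtracted tracks of the same
#' vlincRNA and treatment. The result is the average normalised RAT score
#' consumed by the ANARS metagene statistic.
#'
#' @param r1,r2 Control-subtracted `rat_track` objects.
#' @return A `rat_track` at stage `"averaged"` with replica `NA`.
#' @export
average_replicas <- function(r1, r2) {
  stopifnot(inherits(r1, "rat_track"), inherits(r2, "rat_track"))
  if (r1$vlinc != r2$vlinc || r1$treatment != r2$treatment) {
    stop("replica mismatch (vlincRNA/treatment)")
  }
  if (r1$stage != "subtracted" || r2$stage != "subtracted") {
    stop("tracks must be control-subtracted before averaging")
  }
  r1$score <- (r1$score + r2$score) / 2
  r1$replica <- NA_integer_
  r1$source <- paste(unique(c(r1$source, r2$source)), collapse = "+")
  r1$stage <- "averaged"
  r1$total_reads <- NA_real_
  r1
}

# mean of an arbitrary set of subtracted tracks (used to pool oligo sets)
rat_mean <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  out <- tracks[[1L]]
  if (length(tracks) > 1L) {
    for (t in tracks[-1L]) out$score <- out$score + t$score
    out$score <- out$score / length(tracks)
  }
  out$source <- paste(vapply(tracks, `[[`, "", "source"), collapse = "+")
  out
}

#' Call RAT regions at a percentile threshold
#'
#' Implements the per-replica region pathway: (1) keep bases with score > 0
#' in `track`; (2) intersect base-wise with the > 0 bases of the other
#' oligo-set track (exact coordinates); (3) rank the surviving base scores of
#' `track` and keep the top `percentile` per cent (the threshold is the
#' k-th largest surviving score with `k = ceiling(n * percentile / 100)`;
#' ties at the threshold are all kept); (4) merge adjacent surviving bases
#' into regions.
#'
#' @param track Control-subtracted `rat_track` whose scores are ranked.
#' @param other_oligo_track Control-subtracted track of the second oligo set;
#'   only its `> 0` mask is used.
#' @param percentile One of 1, 5, 10, 20, 30.
#' @return A `GRanges` of merged regions with a `score` column (mean score)
#'   and metadata `percentile`. Empty when no base survives.
#' @export
call_regions <- function(track, other_oligo_track, percentile) {
  stopifnot(inherits(track, "rat_track"),
            inherits(other_oligo_track, "rat_track"))
  if (!percentile %in% c(1, 5, 10, 20, 30)) {
    stop("percentile must be one of 1, 5, 10, 20, 30")
  }
  mask <- (track$score > 0) & (other_oligo_track$score > 0)
  surv <- unlist(lapply(names(track$score), function(ch) {
    as.numeric(track$score[[ch]][mask[[ch]]])
  }))
  if (length(surv) == 0L) {
    message("no base survives the >0 / shared-oligo filters; empty region set")
    return(.empty_regions(track, percentile))
  }
  k <- ceiling(length(surv) * percentile / 100)
  thr <- sort(surv, decreasing = TRUE)[k]
  keep <- mask & (track$score >= thr)
  grl <- lapply(names(keep), function(ch) {
    ir <- methods::as(keep[[ch]], "IRanges")  # TRUE runs
    if (length(ir) == 0L) return(GenomicRanges::GRanges())
    sc <- IRanges::viewMeans(IRanges::Views(track$score[[ch]], ir))
    gr <- GenomicRanges::GRanges(ch, ir, score = as.numeric(sc))
    gr
  })
  out <- suppressWarnings(do.call(c, grl))
  S4Vectors::metadata(out)$percentile <- percentile
  S4Vectors::metadata(out)$track <- paste(track$vlinc, track$treatment,
                                          track$replica, sep = "|")
  out
}

.empty_regions <- function(track, percentile) {
  out <- GenomicRanges::GRanges()
  out$score <- numeric(0)
  S4Vectors::metadata(out)$percentile <- percentile
  out
}

#' Genes containing RAT regions in both replicas
#'
#' Gene-level: a gene is kept when at least one called region from *each*
#' replica falls within its boundaries (the two replicas' regions may have
#' different coordinates). Region-level: a gene is kept only when the
#' base-wise intersection of the two replicas' regions is non-empty within
#' its boundaries (exact coordinate matching). Only mRNA genes are
#' considered.
#'
#' @param regions_r1,regions_r2 `GRanges` of called regions per replica.
#' @param annotation `GRanges` annotation (see [make_annotation()]).
#' @param level `"gene"` or `"region"`.
#' @return A character vector of gene ids.
#' @export
genes_with_regions <- function(regions_r1, regions_r2, annotation,
                               level = c("gene", "region")) {
  level <- match.arg(level)
  genes <- annotation[annotation$class == "mRNA"]
  if (level == "gene") {
    keep <- IRanges::overlapsAny(genes, regions_r1) &
      IRanges::overlapsAny(genes, regions_r2)
  } else {
    shared <- GenomicRanges::intersect(
      GenomicRanges::reduce(GenomicRanges::granges(regions_r1)),
      GenomicRanges::reduce(GenomicRanges::granges(regions_r2)))
    keep <- IRanges::overlapsAny(genes, shared)
  }
  names(genes)[keep]
}

#' Replica concordance of RAT gene sets
#'
#' Overlap of the gene sets called in the two biological replicas over a
#' common universe: 2x2 table, Haldane-corrected odds ratio and one-sided
#' hypergeometric enrichment p-value.
#'
#' @param genes_r1,genes_r2 Character vectors of gene ids (subsets of
#'   `universe`).
#' @param universe Character vector of all eligible gene ids.
#' @return See [overlap_test()].
#' @export
replica_concordance <- function(genes_r1, genes_r2, universe) {
  overlap_test(genes_r1, genes_r2, universe)
}
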