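# RAT coverage track generator: per-base Poisson counts over a
# piecewise-constant rate with planted enrichment over network gene bodies
# and track-specific large-scale background heterogeneity.

#' Construct a RAT track object
#'
#' A `rat_track` holds a per-base score for every chromosome (as a compressed
#' `RleList`) together with its provenance: target vlincRNA, treatment,
#' biological replica and source (`oligo_set_1`, `oligo_set_2` or the
#' `no_oligo` specificity control), the total read count used for
#' normalisation, and the processing stage reached so far.
#'
#' @param score An `RleList` (one `Rle` per chromosome) of per-base scores.
#' @param vlinc,treatment,replica,source Provenance labels.
#' @param total_reads Total read count of the sample.
#' @param stage One of `"raw"`, `"normalized"`, `"subtracted"`, `"averaged"`.
#' @return An object of class `rat_track`.
#' @export
rat_track <- function(score, vlinc, treatment, replica, source, total_reads,
                      stage = "raw") {
  stopifnot(methods::is(score, "RleList"))
  structure(
    list(score = score, vlinc = vlinc, treatment = treatment,
         replica = as.integer(replica), source = source,
         total_reads = total_reads, stage = stage),
    class = "rat_track")
}

#' @export
print.rat_track <- function(x, ...) {
  cat(sprintf("rat_track %s | %s | replica %d | %s | stage %s | %d reads\n",
              x$vlinc, x$treatment, x$replica, x$source,
              x$stage, round(x$total_reads)))
  invisible(x)
}

#' Simulate raw RAT coverage tracks
#'
#' For every (vlincRNA, treatment) combination, generates two biological
#' replicas of three raw coverage tracks: two targeting oligo sets and one
#' no-oligo control. Coverage is Poisson per base over a piecewise-constant
#' rate with two components:
#'
#' * non-specific background: `background_rate` genome-wide, modulated per
#'   track by independent mean-one log-normal factors over `domain_size`
#'   blocks (`domain_sd` on the log scale). This mimics the large-scale
#'   pull-down variability that the oligo-set and replica intersection
#'   filters are designed to remove; independent per-base noise alone has no
#'   spatial structure, so lenient percentile thresholds would scatter
#'   called bases uniformly across all genes instead of concentrating
#'   replica-specific false regions the way real assays do;
#' * planted proximity signal, added on top of the modulated background in
#'   targeting tracks only: `background_rate * (chromatin_enrichment - 1)`
#'   over the gene bodies of the vlincRNA's planted network genes (times
#'   `cis_boost` for planted targets on the vlincRNA's own chromosome), with
#'   a linear taper back to zero over `rat_flank_decay` bases on each side
#'   of the body (chromatin proximity is regional). The no-oligo control
#'   carries background only.
#'
#' The expected coverage over planted gene bodies remains
#' `chromatin_enrichment x background` because the domain factors have mean
#' one. Total read counts are the realised coverage sums.
#'
#' @param spec A [simulation_spec()].
#' @param annotation Output of [make_annotation()].
#' @param truth Output of [make_ground_truth()].
#' @param treatments Treatment labels; defaults to `spec$treatments`.
#' @return A list of `rat_track` objects named
#'   `"<vlinc>|<treatment>|r<replica>|<source>"`.
#' @export
simulate_rat_tracks <- function(spec, annotation, truth,
                                treatments = spec$treatments) {
  validate_spec(spec)
  lens <- GenomeInfoDb::seqlengths(annotation)
  sources <- c("oligo_set_1", "oligo_set_2", "no_oligo")
  out <- list()
  .with_stage_seed(spec$seed, 31L, {
    for (v in truth$vlincs) {
      signal <- .signal_vectors(spec, annotation, truth, v)
      none <- lapply(lens, function(L) numeric(L))
      for (tr in treatments) {
        for (rep_i in 1:2) {
          for (src in sources) {
            s <- if (src == "no_oligo") none else signal
            cov <- .pois_tracks(s, lens, spec)
            key <- paste(v, tr, paste0("r", rep_i), src, sep = "|")
            out[[key]] <- rat_track(cov, v, tr, rep_i, src,
                                    total_reads = sum(vapply(cov, sum, 0)))
          }
        }
      }
    }
  })
  out
}

# per-chromosome additive planted signal (expected extra coverage) as plain
# numeric vectors; enrichment over the vlincRNA's network gene bodies with a
# linear flank taper
.signal_vectors <- function(spec, annotation, truth, vlinc) {
  lens <- GenomeInfoDb::seqlengths(annotation)
  sig <- lapply(lens, function(L) numeric(L))
  extra <- spec$background_rate * (spec$chromatin_enrichment - 1)
  tdf <- truth$targets[truth$targets$vlinc == vlinc, , drop = FALSE]
  if (nrow(tdf) == 0L) return(sig)
  tg <- annotation[tdf$gene]
  amp <- extra + spec$background_rate *
    spec$chromatin_enrichment * (ifelse(tdf$cis, spec$cis_boost, 1) - 1)
  ch <- as.character(GenomeInfoDb::seqnames(tg))
  st <- BiocGenerics::start(tg)
  en <- BiocGenerics::end(tg)
  fw <- spec$rat_flank_decay
  for (i in seq_along(tg)) {
    if (amp[i] == 0) next
    L <- length(sig[[ch[i]]])
    sig[[ch[i]]][st[i]:en[i]] <- amp[i]
    if (fw > 0) {
      taper <- amp[i] * (1 - seq_len(fw) / fw)
      lo <- max(1L, st[i] - fw)
      if (lo < st[i]) {
        sig[[ch[i]]][lo:(st[i] - 1L)] <- rev(taper)[seq_len(st[i] - lo)]
      }
      hi <- min(L, en[i] + fw)
      if (hi > en[i]) {
        sig[[ch[i]]][(en[i] + 1L):hi] <- taper[seq_len(hi - en[i])]
      }
    }
  }
  sig
}

# Poisson draw per base: domain-modulated background plus additive signal
.pois_tracks <- function(signal, lens, spec) {
  out <- lapply(names(signal), function(ch) {
    r <- rep(spec$background_rate, lens[[ch]])
    if (spec$domain_sd > 0) {
      nb <- ceiling(lens[[ch]] / spec$domain_size)
      f <- exp(stats::rnorm(nb, 0, spec$domain_sd) - spec$domain_sd^2 / 2)
      r <- r * rep(f, each = spec$domain_size)[seq_len(lens[[ch]])]
    }
    S4Vectors::Rle(stats::rpois(lens[[ch]], r + signal[[ch]]))
  })
  names(out) <- names(signal)
  methods::as(out, "RleList")
}
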