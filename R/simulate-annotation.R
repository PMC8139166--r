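# Synthetic genome annotation and planted ground truth.

#' Generate a synthetic gene/vlincRNA annotation
#'
#' Lays out non-overlapping mRNA gene intervals and vlincRNA loci on
#' `n_chromosomes` chromosomes. Each chromosome carries its share of vlincRNA
#' loci (assigned round-robin) followed by `genes_per_chromosome` gene bodies,
#' each separated by a fixed spacer so that the 5-kb flanking windows used in
#' metagene analysis never overlap a neighbouring gene. Coordinates are
#' 0-based half-open at I/O boundaries and 1-based closed inside the returned
#' `GRanges`. Strands alternate so both orientations are exercised
#' downstream.
#'
#' @param spec A [simulation_spec()].
#' @return A `GRanges` with `names` set to the feature id and a metadata
#'   column `class` (`"mRNA"` or `"vlincRNA"`). The chromosome lengths are
#'   recorded in `seqlengths`.
#' @export
make_annotation <- function(spec) {
  validate_spec(spec)
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  vlinc_host <- chroms[((seq_len(spec$n_vlinc) - 1L) %% spec$n_chromosomes) + 1L]

  seqn <- character(0)
  start0 <- integer(0)  # 0-based starts
  end0 <- integer(0)    # half-open ends
  id <- character(0)
  cls <- character(0)
  chrom_len <- stats::setNames(numeric(length(chroms)), chroms)
  gene_counter <- 0L
  for (ci in seq_along(chroms)) {
    pos <- spec$gene_spacer
    for (v in which(vlinc_host == chroms[ci])) {
      seqn <- c(seqn, chroms[ci])
      start0 <- c(start0, pos)
      end0 <- c(end0, pos + spec$vlinc_length)
      id <- c(id, sprintf("vlinc_%03d", v))
      cls <- c(cls, "vlincRNA")
      pos <- pos + spec$vlinc_length + spec$gene_spacer
    }
    for (g in seq_len(spec$genes_per_chromosome)) {
      gene_counter <- gene_counter + 1L
      seqn <- c(seqn, chroms[ci])
      start0 <- c(start0, pos)
      end0 <- c(end0, pos + spec$gene_length)
      id <- c(id, sprintf("gene_%05d", gene_counter))
      cls <- c(cls, "mRNA")
      pos <- pos + spec$gene_length + spec$gene_spacer
    }
    chrom_len[ci] <- pos + spec$gene_spacer
  }
  si <- GenomeInfoDb::Seqinfo(seqnames = chroms,
                               seqlengths = unname(chrom_len))
  ann <- GenomicRanges::GRanges(
    seqnames = factor(seqn, levels = chroms),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = rep_len(c("+", "-"), length(start0)),
    seqinfo = si
  )
  names(ann) <- id
  ann$class <- cls
  if (any(BiocGenerics::width(ann) < 1L)) stop("invalid interval widths")
  .check_disjoint(ann)
  ann
}

.check_disjoint <- function(ann) {
  hits <- GenomicRanges::findOverlaps(ann, drop.self = TRUE)
  if (length(hits) > 0L) stop("annotation intervals overlap: layout failed")
  invisible(ann)
}

#' Plant the ground-truth regulatory structure
#'
#' Samples disjoint positive and negative target gene sets for every
#' vlincRNA, labels each planted target as cis (same chromosome as its
#' vlincRNA) or trans, and records the expected direction of expression
#' change under knockdown (negative targets up, positive targets down).
#'
#' @param spec A [simulation_spec()].
#' @param annotation Output of [make_annotation()] for the same spec.
#' @return An object of class `ground_truth`: a list with a `targets`
#'   data.frame (`vlinc`, `gene`, `sign`, `cis`, `kd_direction`) and the
#'   per-vlincRNA sets in `positive` and `negative` named lists.
#' @export
make_ground_truth <- function(spec, annotation) {
  validate_spec(spec)
  genes <- names(annotation)[annotation$class == "mRNA"]
  vlincs <- names(annotation)[annotation$class == "vlincRNA"]
  per <- spec$network_size_pos + spec$network_size_neg
  targets <- .with_stage_seed(spec$seed, 11L, {
    pool <- sample(genes)
    tgt <- vector("list", length(vlincs))
    for (i in seq_along(vlincs)) {
      take <- pool[seq_len(per) + (i - 1L) * per]
      tgt[[i]] <- data.frame(
        vlinc = vlincs[i],
        gene = take,
        sign = rep(c("positive", "negative"),
                   c(spec$network_size_pos, spec$network_size_neg)),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, tgt)
  })
  chrom_of <- as.character(GenomeInfoDb::seqnames(annotation))
  names(chrom_of) <- names(annotation)
  targets$cis <- chrom_of[targets$gene] == chrom_of[targets$vlinc]
  targets$kd_direction <- ifelse(targets$sign == "negative", "up", "down")
  rownames(targets) <- NULL
  truth <- list(
    targets = targets,
    positive = split(targets$gene[targets$sign == "positive"],
                     targets$vlinc[targets$sign == "positive"]),
    negative = split(targets$gene[targets$sign == "negative"],
                     targets$vlinc[targets$sign == "negative"]),
    vlincs = vlincs
  )
  class(truth) <- "ground_truth"
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$vlincs), "vlincRNAs,",
      nrow(x$targets), "planted targets\n")
  invisible(x)
}

# planted targets (both signs) of one vlincRNA
truth_targets <- function(truth, vlinc) {
  truth$targets$gene[truth$targets$vlinc == vlinc]
}
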