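# Readers and writers for the plain-text interchange formats: 6-column BED
# annotation, bedGraph coverage tracks with a manifest, and TSV tables.
# Coordinates are 0-based half-open on disk and 1-based closed in GRanges.

#' Write an annotation as 6-column BED
#'
#' Columns: chrom, start (0-based), end (half-open), name, score (0),
#' strand. The feature class is recoverable from the name prefix
#' (`vlinc_` versus `gene_`).
#'
#' @param annotation A `GRanges` with names and a `class` column.
#' @param path Output file.
#' @export
write_bed <- function(annotation, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(annotation)),
    start = BiocGenerics::start(annotation) - 1L,
    end = BiocGenerics::end(annotation),
    name = names(annotation),
    score = 0L,
    strand = as.character(BiocGenerics::strand(annotation)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED annotation
#'
#' @param path BED file (0-based half-open coordinates).
#' @param seqlengths Optional named vector of chromosome lengths.
#' @return A `GRanges` with names and a `class` column inferred from the
#'   name prefix (`vlinc*` is `vlincRNA`, everything else `mRNA`).
#' @export
read_bed <- function(path, seqlengths = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed BED line %d in %s: expected 6 columns, got %d",
                 bad[1L], path, nf[bad[1L]]))
  }
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start0) | is.na(end0) | end0 <= start0 |
               !m[, 6L] %in% c("+", "-", "."))
  if (length(bad) > 0L) {
    stop(sprintf("malformed BED line %d in %s: invalid coordinates or strand",
                 bad[1L], path))
  }
  args <- list(
    seqnames = m[, 1L],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = m[, 6L]
  )
  if (!is.null(seqlengths)) {
    args$seqinfo <- GenomeInfoDb::Seqinfo(names(seqlengths),
                                           unname(seqlengths))
  }
  gr <- do.call(GenomicRanges::GRanges, args)
  names(gr) <- m[, 4L]
  gr$class <- ifelse(startsWith(m[, 4L], "vlinc"), "vlincRNA", "mRNA")
  gr
}

#' Write a score track as bedGraph
#'
#' Zero-score runs are omitted, keeping the files sparse. Coordinates are
#' 0-based half-open.
#'
#' @param score An `RleList` of per-base scores.
#' @param path Output file.
#' @export
write_bedgraph <- function(score, path) {
  gr <- methods::as(score, "GRanges")
  gr <- gr[gr$score != 0]
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    score = gr$score,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph track into an `RleList`
#'
#' Intervals must not overlap; bases not covered by any interval score zero.
#'
#' @param path bedGraph file (0-based half-open).
#' @param seqlengths Named vector of chromosome lengths (defines the genome).
#' @return An `RleList` of per-base scores.
#' @export
read_bedgraph <- function(path, seqlengths) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(methods::as(lapply(seqlengths, function(L) S4Vectors::Rle(0, L)),
                       "RleList"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 4L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed bedGraph line %d in %s: expected 4 columns",
                 bad[1L], path))
  }
  m <- do.call(rbind, fields)
  start0 <- suppressWarnings(as.integer(m[, 2L]))
  end0 <- suppressWarnings(as.integer(m[, 3L]))
  val <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(start0) | is.na(end0) | is.na(val) | end0 <= start0)
  if (length(bad) > 0L) {
    stop(sprintf("malformed bedGraph line %d in %s", bad[1L], path))
  }
  gr <- GenomicRanges::GRanges(
    m[, 1L], IRanges::IRanges(start0 + 1L, end0),
    seqinfo = GenomeInfoDb::Seqinfo(names(seqlengths), unname(seqlengths)))
  if (any(GenomicRanges::countOverlaps(gr, gr) > 1L)) {
    stop("bedGraph with overlapping intervals: ", path)
  }
  cov <- GenomicRanges::coverage(gr, weight = val)
  cov[names(seqlengths)]
}

#' Write a data.frame as TSV
#' @param df A data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input file.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression matrix and its sample metadata as TSV
#' @param expr Expression `SummarizedExperiment`.
#' @param matrix_path,meta_path Output files.
#' @export
write_expression <- function(expr, matrix_path, meta_path) {
  vals <- expr_values(expr)
  df <- data.frame(transcript = rownames(vals),
                   class = SummarizedExperiment::rowData(expr)$class,
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  write_tsv(expr_samples(expr), meta_path)
  invisible(matrix_path)
}

#' Read an expression matrix written by [write_expression()]
#' @param matrix_path,meta_path Input files.
#' @return An expression `SummarizedExperiment`.
#' @export
read_expression <- function(matrix_path, meta_path) {
  df <- read_tsv(matrix_path)
  meta <- read_tsv(meta_path)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$transcript
  storage.mode(vals) <- "double"
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = vals),
    rowData = S4Vectors::DataFrame(class = df$class, row.names = df$transcript),
    colData = S4Vectors::DataFrame(meta[, -1L, drop = FALSE],
                                   row.names = meta$sample)
  )
}

#' Write RAT tracks as bedGraph files plus a manifest
#'
#' @param tracks List of `rat_track` objects (see [simulate_rat_tracks()]).
#' @param dir Output directory (created if needed).
#' @return Path of the manifest TSV (columns: `path`, `vlinc`, `treatment`,
#'   `replica`, `source`, `total_reads`).
#' @export
write_rat_tracks <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(tracks, function(t) {
    fn <- paste0(gsub("[^A-Za-z0-9]+", "_",
                      paste(t$vlinc, t$treatment, t$replica, t$source,
                            sep = "_")), ".bedgraph")
    write_bedgraph(t$score, file.path(dir, fn))
    data.frame(path = fn, vlinc = t$vlinc, treatment = t$treatment,
               replica = t$replica, source = t$source,
               total_reads = t$total_reads, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  file.path(dir, "manifest.tsv")
}

#' Read RAT tracks from a manifest
#'
#' @param manifest_path Manifest TSV written by [write_rat_tracks()].
#' @param seqlengths Named chromosome lengths.
#' @return A named list of raw `rat_track` objects.
#' @export
read_rat_tracks <- function(manifest_path, seqlengths) {
  manifest <- read_tsv(manifest_path)
  dir <- dirname(manifest_path)
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    score <- read_bedgraph(file.path(dir, manifest$path[i]), seqlengths)
    key <- paste(manifest$vlinc[i], manifest$treatment[i],
                 paste0("r", manifest$replica[i]), manifest$source[i],
                 sep = "|")
    out[[key]] <- rat_track(score, manifest$vlinc[i], manifest$treatment[i],
                            manifest$replica[i], manifest$source[i],
                            manifest$total_reads[i])
  }
  out
}
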