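# Small simulation specs shared across tests. Sizes are kept modest so the
# whole suite runs quickly; the acceptance tests use their own larger specs.

tiny_spec <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_chromosomes = 2L, genes_per_chromosome = 20L,
               n_vlinc = 2L, network_size_pos = 3L, network_size_neg = 6L,
               n_samples = 64L, treatments = "DMSO")
  args[names(list(...))] <- list(...)
  do.call(simulation_spec, args)
}

sim_world <- function(spec) {
  ann <- make_annotation(spec)
  truth <- make_ground_truth(spec, ann)
  list(spec = spec, ann = ann, truth = truth)
}

# a hand-buildable expression container
make_expr <- function(values, classes, meta) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = values),
    rowData = S4Vectors::DataFrame(class = classes,
                                   row.names = rownames(values)),
    colData = S4Vectors::DataFrame(meta[, setdiff(names(meta), "sample"),
                                        drop = FALSE],
                                   row.names = meta$sample))
}

# a rat_track over one small chromosome from a plain numeric vector
vec_track <- function(x, chrom = "chrA", stage = "subtracted",
                      vlinc = "vlinc_001", treatment = "DMSO", replica = 1L,
                      source = "oligo_set_1", total_reads = 1000) {
  score <- methods::as(stats::setNames(list(S4Vectors::Rle(as.numeric(x))),
                                       chrom), "RleList")
  rat_track(score, vlinc, treatment, replica, source, total_reads,
            stage = stage)
}

# brute-force region caller used as the independent oracle: enumerate bases,
# sort, threshold at the k-th largest surviving score (ties kept), merge
# adjacent positions by hand
oracle_regions <- function(x1, x2, percentile) {
  stopifnot(length(x1) == length(x2))
  surv <- which(x1 > 0 & x2 > 0)
  if (length(surv) == 0L) return(data.frame(start = integer(), end = integer()))
  vals <- x1[surv]
  k <- ceiling(length(vals) * percentile / 100)
  thr <- sort(vals, decreasing = TRUE)[k]
  kept <- surv[vals >= thr]
  starts <- kept[c(TRUE, diff(kept) != 1L)]
  ends <- kept[c(diff(kept) != 1L, TRUE)]
  data.frame(start = starts, end = ends)
}
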