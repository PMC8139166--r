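# Expression series generator: a shared Gaussian latent treatment-response
# factor per vlincRNA induces the planted rank correlations; abundances are
# exponentiated so Spearman correlations survive the transform.

#' Simulate the drug-perturbation expression series
#'
#' Generates an RPKM-scale transcripts x samples matrix. Every vlincRNA is a
#' monotone transform of its own latent standard-normal treatment-response
#' factor; each planted target mixes that factor with independent noise so
#' the population Spearman correlation has magnitude `rho_target` with the
#' planted sign (the Gaussian Pearson coefficient is set to
#' `2 * sin(pi * rho_target / 6)`, the value whose rank correlation equals
#' `rho_target`). Non-network genes are independent of all vlincRNAs. The
#' log-abundances are exponentiated, so all values are positive and the rank
#' structure is preserved exactly.
#'
#' Sample metadata follows the study design: each drug is profiled at 3 h and
#' 6 h, and four solvent control samples (DMSO and water at both time points)
#' close the series.
#'
#' @param spec A [simulation_spec()].
#' @param annotation Output of [make_annotation()].
#' @param truth Output of [make_ground_truth()]; pass a truth with zero
#'   planted targets for a null series.
#' @return A `SummarizedExperiment` with assay `rpkm`, `rowData$class`
#'   (`mRNA`/`vlincRNA`) and `colData` columns `drug`, `timepoint_h`,
#'   `solvent_flag` and `solvent`.
#' @export
simulate_expression <- function(spec, annotation, truth) {
  validate_spec(spec)
  stopifnot(inherits(truth, "ground_truth"))
  if (!all(truth$targets$gene %in% names(annotation))) {
    stop("ground truth refers to genes absent from the annotation")
  }
  ids <- names(annotation)
  classes <- annotation$class
  vlincs <- ids[classes == "vlincRNA"]
  n <- spec$n_samples
  r <- 2 * sin(pi * spec$rho_target / 6)  # Pearson giving Spearman rho_target

  mat <- .with_stage_seed(spec$seed, 21L, {
    mu <- stats::rnorm(length(ids), mean = log(10), sd = 1)
    z <- matrix(stats::rnorm(length(vlincs) * n), length(vlincs), n,
                dimnames = list(vlincs, NULL))
    x <- matrix(stats::rnorm(length(ids) * n), length(ids), n,
                dimnames = list(ids, NULL))
    x[vlincs, ] <- z
    for (v in vlincs) {
      for (sgn in c("positive", "negative")) {
        tg <- truth$targets$gene[truth$targets$vlinc == v &
                                 truth$targets$sign == sgn]
        if (length(tg) == 0L) next
        eps <- x[tg, , drop = FALSE]
        mixed <- r * rep(z[v, ], each = length(tg)) + sqrt(1 - r^2) * eps
        x[tg, ] <- if (sgn == "positive") mixed else -mixed
      }
    }
    exp(mu + spec$noise_sd * x)
  })

  meta <- .sample_metadata(spec)
  colnames(mat) <- meta$sample
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = mat),
    rowData = S4Vectors::DataFrame(class = classes, row.names = ids),
    colData = S4Vectors::DataFrame(meta[, -1L], row.names = meta$sample)
  )
}

.sample_metadata <- function(spec) {
  n_drugs <- (spec$n_samples - 4L) %/% 2L
  drugs <- sprintf("drug_%02d", seq_len(n_drugs))
  # a couple of water-dissolved drugs, the rest in DMSO (as in the study)
  solvent_of <- stats::setNames(
    rep(c("water", "DMSO"), c(min(2L, n_drugs), max(0L, n_drugs - 2L))),
    drugs)
  rows <- expand.grid(timepoint_h = c(3L, 6L), drug = drugs,
                      stringsAsFactors = FALSE)[, c("drug", "timepoint_h")]
  rows$solvent_flag <- FALSE
  rows$solvent <- solvent_of[rows$drug]
  ctrl <- data.frame(drug = rep(c("DMSO", "water"), each = 2L),
                     timepoint_h = rep(c(3L, 6L), 2L),
                     solvent_flag = TRUE,
                     solvent = rep(c("DMSO", "water"), each = 2L),
                     stringsAsFactors = FALSE)
  meta <- rbind(rows, ctrl)
  meta$sample <- sprintf("s%02d_%s_%dh", seq_len(nrow(meta)), meta$drug,
                         meta$timepoint_h)
  meta[, c("sample", "drug", "timepoint_h", "solvent_flag", "solvent")]
}

# accessors used throughout the analysis modules -----------------------------

expr_values <- function(expr) {
  SummarizedExperiment::assay(expr, "rpkm")
}

expr_ids <- function(expr, class = NULL) {
  cls <- SummarizedExperiment::rowData(expr)$class
  if (is.null(class)) rownames(expr) else rownames(expr)[cls == class]
}

expr_samples <- function(expr) {
  cd <- SummarizedExperiment::colData(expr)
  data.frame(sample = rownames(cd), as.data.frame(cd),
             row.names = NULL, stringsAsFactors = FALSE)
}
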