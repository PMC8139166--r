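# The synthetic-data generators: determinism, planted structure, calibration.

test_that("annotation conserves counts, validity and determinism", {
  spec <- tiny_spec(n_chromosomes = 2L, genes_per_chromosome = 3L,
                    network_size_pos = 1L, network_size_neg = 1L)
  ann <- make_annotation(spec)
  expect_equal(sum(ann$class == "mRNA"), 6L)
  expect_equal(length(unique(as.character(GenomeInfoDb::seqnames(ann)))), 2L)
  expect_true(all(BiocGenerics::width(ann) >= 1L))
  expect_equal(length(GenomicRanges::findOverlaps(ann, drop.self = TRUE)), 0L)
  # byte-identical under the same seed
  ann2 <- make_annotation(tiny_spec(n_chromosomes = 2L,
                                    genes_per_chromosome = 3L,
                                    network_size_pos = 1L,
                                    network_size_neg = 1L))
  expect_identical(ann, ann2)
})

test_that("ground truth plants disjoint signed sets present in the annotation", {
  w <- sim_world(tiny_spec())
  tg <- w$truth$targets
  expect_true(all(tg$gene %in% names(w$ann)))
  expect_equal(anyDuplicated(tg$gene), 0L)  # disjoint across signs and vlincs
  expect_setequal(unique(tg$sign), c("positive", "negative"))
  chrom_of <- stats::setNames(as.character(GenomeInfoDb::seqnames(w$ann)),
                              names(w$ann))
  expect_equal(tg$cis, unname(chrom_of[tg$gene] == chrom_of[tg$vlinc]))
})

test_that("planted pairs reach the target rank correlation", {
  # Monte-Carlo over generator replicates: median |rho| of planted pairs
  # must be high at rho_target = 0.9 with 64 samples
  rhos <- unlist(lapply(1:20, function(s) {
    w <- sim_world(tiny_spec(seed = s))
    expr <- simulate_expression(w$spec, w$ann, w$truth)
    vals <- SummarizedExperiment::assay(expr)
    mapply(function(v, g) cor(vals[v, ], vals[g, ], method = "spearman"),
           w$truth$targets$vlinc, w$truth$targets$gene) *
      ifelse(w$truth$targets$sign == "positive", 1, -1)
  }))
  expect_gt(median(rhos), 0.7)
  expect_gt(min(rhos), 0.35)
})

test_that("expression is non-negative, deterministic and carries the study design", {
  w <- sim_world(tiny_spec())
  expr <- simulate_expression(w$spec, w$ann, w$truth)
  vals <- SummarizedExperiment::assay(expr)
  expect_true(all(vals >= 0))
  expect_equal(ncol(vals), 64L)
  meta <- SummarizedExperiment::colData(expr)
  expect_equal(sum(meta$solvent_flag), 4L)
  expect_setequal(unique(meta$timepoint_h), c(3L, 6L))
  # both solvents have controls at both time points
  ctl <- meta[meta$solvent_flag, ]
  expect_equal(nrow(unique(as.data.frame(ctl[, c("solvent", "timepoint_h")]))),
               4L)
  expr2 <- simulate_expression(w$spec, w$ann, w$truth)
  expect_identical(SummarizedExperiment::assay(expr2), vals)
})

test_that("expression generator ignores chromatin and knockdown parameters", {
  w1 <- sim_world(tiny_spec(chromatin_enrichment = 1, knockdown_effect = 0))
  w2 <- sim_world(tiny_spec(chromatin_enrichment = 5, knockdown_effect = 0.8))
  e1 <- simulate_expression(w1$spec, w1$ann, w1$truth)
  e2 <- simulate_expression(w2$spec, w2$ann, w2$truth)
  expect_identical(SummarizedExperiment::assay(e1),
                   SummarizedExperiment::assay(e2))
})

test_that("null truth yields a calibrated pair discovery rate", {
  spec <- tiny_spec(seed = 5L, genes_per_chromosome = 50L,
                    network_size_pos = 1L, network_size_neg = 1L)
  w <- sim_world(spec)
  # strip the planted pairs to get a pure null
  w$truth$targets <- w$truth$targets[0, ]
  expr <- simulate_expression(spec, w$ann, w$truth)
  net <- spearman_network(expr)
  scores <- coexpression_scores(expr)
  expect_lte(nrow(net) / nrow(scores), 0.02)
})

test_that("RAT coverage is a non-negative count with the planted mean enrichment", {
  ratio_at <- function(enr, seed) {
    spec <- tiny_spec(seed = seed, chromatin_enrichment = enr,
                      genes_per_chromosome = 60L, network_size_pos = 10L,
                      network_size_neg = 20L, domain_sd = 0)
    w <- sim_world(spec)
    tracks <- simulate_rat_tracks(spec, w$ann, w$truth)
    t1 <- tracks[["vlinc_001|DMSO|r1|oligo_set_1"]]
    vals <- unlist(lapply(t1$score, as.numeric))
    expect_true(all(vals >= 0) && all(vals == floor(vals)))
    tg <- w$ann[w$truth$targets$gene[w$truth$targets$vlinc == "vlinc_001"]]
    bg <- w$ann[setdiff(names(w$ann)[w$ann$class == "mRNA"],
                        w$truth$targets$gene)]
    mean_over <- function(gr) {
      mean(unlist(lapply(seq_along(gr), function(i) {
        ch <- as.character(GenomeInfoDb::seqnames(gr)[i])
        as.numeric(S4Vectors::window(t1$score[[ch]],
                                     BiocGenerics::start(gr)[i],
                                     BiocGenerics::end(gr)[i]))
      })))
    }
    mean_over(tg) / mean_over(bg)
  }
  r1 <- sapply(1:3, function(s) ratio_at(1, s))
  r3 <- sapply(1:3, function(s) ratio_at(3, s))
  expect_true(all(r1 > 0.9 & r1 < 1.1))
  expect_true(all(abs(r3 - 3) < 0.35))
})

test_that("no-oligo control is background-level and tracks are deterministic", {
  spec <- tiny_spec(seed = 2L, chromatin_enrichment = 4, domain_sd = 0)
  w <- sim_world(spec)
  tracks <- simulate_rat_tracks(spec, w$ann, w$truth)
  expect_length(tracks, spec$n_vlinc * length(spec$treatments) * 2 * 3)
  ctrl <- tracks[["vlinc_001|DMSO|r1|no_oligo"]]
  tg <- w$ann[w$truth$targets$gene[w$truth$targets$vlinc == "vlinc_001"]]
  ch <- as.character(GenomeInfoDb::seqnames(tg)[1])
  sl <- as.numeric(S4Vectors::window(ctrl$score[[ch]],
                                     BiocGenerics::start(tg)[1],
                                     BiocGenerics::end(tg)[1]))
  # background Poisson mean, not enriched
  expect_lt(mean(sl), spec$background_rate * 2)
  tracks2 <- simulate_rat_tracks(spec, w$ann, w$truth)
  expect_identical(tracks[[1]]$score, tracks2[[1]]$score)
})

test_that("knockdown tables carry planted shifts of the right direction", {
  spec <- tiny_spec(seed = 3L, knockdown_effect = 0.4)
  w <- sim_world(spec)
  kd <- simulate_knockdown(spec, w$truth, w$ann)
  expect_length(kd, spec$n_vlinc * 2L)
  tab <- kd[[1]]
  v <- attr(tab, "vlinc")
  rfc <- relative_fold_change(filter_expressed(tab))
  tg <- w$truth$targets[w$truth$targets$vlinc == v, ]
  m_neg <- median(rfc$RFC_T36[rfc$gene %in% tg$gene[tg$sign == "negative"]])
  m_pos <- median(rfc$RFC_T36[rfc$gene %in% tg$gene[tg$sign == "positive"]])
  expect_gt(m_neg, m_pos)
  # vlincRNA itself depleted in the targeting arm
  vrow <- tab[tab$gene == v, ]
  expect_lt(vrow$T3 / vrow$T0, 1)
})

test_that("zero knockdown effect gives median RFC about 0.5 in all groups", {
  spec <- tiny_spec(seed = 4L, knockdown_effect = 0, vlinc_depletion = 0)
  w <- sim_world(spec)
  kd <- simulate_knockdown(spec, w$truth, w$ann)
  rfc <- relative_fold_change(filter_expressed(kd[[1]]))
  expect_lt(abs(median(rfc$RFC_T36) - 0.5), 0.02)
})

test_that("survival counts recover the planted depletion ratios", {
  dep <- c(baseline = 1.0, challenge = 0.75)
  spec <- tiny_spec(seed = 6L, survival_depletion = dep, n_grna_pairs = 100L,
                    survival_depth = 2e6)
  w <- sim_world(spec)
  sv <- simulate_survival_counts(spec, w$truth)
  expect_true(all(sv$counts$count >= 0))
  expect_true(all(sv$counts$count == floor(sv$counts$count)))
  rt <- targeting_ratios(normalize_abundance(sv$counts), sv$pairing)
  m <- rt$summary
  expect_lt(abs(m$mean_ratio[m$condition == "baseline"] - 1.0), 0.03)
  expect_lt(abs(m$mean_ratio[m$condition == "challenge"] - 0.75), 0.03)
})

test_that("generators are mutually independent given the ground truth", {
  # changing survival parameters must not perturb the RAT draws, etc.
  s1 <- tiny_spec(seed = 9L)
  s2 <- tiny_spec(seed = 9L, survival_depth = 12345, kd_noise_sd = 0.9)
  w1 <- sim_world(s1)
  w2 <- sim_world(s2)
  expect_identical(w1$truth, w2$truth)
  expect_identical(
    SummarizedExperiment::assay(simulate_expression(s1, w1$ann, w1$truth)),
    SummarizedExperiment::assay(simulate_expression(s2, w2$ann, w2$truth)))
  t1 <- simulate_rat_tracks(s1, w1$ann, w1$truth)
  t2 <- simulate_rat_tracks(s2, w2$ann, w2$truth)
  expect_identical(t1[[3]]$score, t2[[3]]$score)
})

test_that("invalid specs are rejected", {
  expect_error(tiny_spec(rho_target = 1.2), "rho_target")
  expect_error(tiny_spec(chromatin_enrichment = 0.5), "chromatin_enrichment")
  expect_error(tiny_spec(knockdown_effect = 1), "knockdown_effect")
  expect_error(tiny_spec(n_samples = 7L), "n_samples")
  expect_error(tiny_spec(genes_per_chromosome = 2L), "exceed")
})
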