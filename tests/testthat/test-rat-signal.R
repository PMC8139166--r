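# RAT track processing and region calling, checked against a brute-force
# per-base oracle.

test_that("normalisation divides by total reads and rejects bad totals", {
  t <- vec_track(c(10, 0, 5), stage = "raw")
  n <- normalize_track(t, total_reads = 1000)
  expect_equal(as.numeric(n$score[[1]]), c(0.01, 0, 0.005))
  expect_equal(sum(sum(n$score)), sum(c(10, 0, 5)) / 1000)
  expect_error(normalize_track(t, total_reads = 0), "positive")
  z <- normalize_track(vec_track(c(0, 0, 0), stage = "raw", total_reads = 10))
  expect_true(all(as.numeric(z$score[[1]]) == 0))
})

test_that("control subtraction keeps negatives and checks provenance", {
  a <- vec_track(c(0.02, 0.02, 0.001), stage = "normalized")
  ctrl <- vec_track(c(0.005, 0.02, 0.004), stage = "normalized",
                    source = "no_oligo")
  s <- subtract_control(a, ctrl)
  expect_equal(as.numeric(s$score[[1]]), c(0.015, 0, -0.003))
  expect_equal(s$stage, "subtracted")
  # subtracting a track from itself gives zero everywhere
  self <- subtract_control(a, vec_track(c(0.02, 0.02, 0.001),
                                        stage = "normalized",
                                        source = "no_oligo"))
  expect_true(all(as.numeric(self$score[[1]]) == 0))
  bad <- vec_track(1:3, stage = "normalized", source = "no_oligo",
                   treatment = "etoposide")
  expect_error(subtract_control(a, bad), "mismatch")
  expect_error(subtract_control(a, a), "no_oligo")
})

test_that("replica averaging is the symmetric per-base mean", {
  r1 <- vec_track(c(0.02, 0, -0.01), replica = 1L)
  r2 <- vec_track(c(0.04, 0, 0.03), replica = 2L)
  m <- average_replicas(r1, r2)
  expect_equal(as.numeric(m$score[[1]]), c(0.03, 0, 0.01))
  m2 <- average_replicas(r2, r1)
  expect_identical(m$score, m2$score)
  same <- average_replicas(r1, vec_track(c(0.02, 0, -0.01), replica = 2L))
  expect_equal(as.numeric(same$score[[1]]), c(0.02, 0, -0.01))
  expect_error(average_replicas(r1, vec_track(1:3, vlinc = "vlinc_009")),
               "mismatch")
})

test_that("region calling matches hand-worked examples", {
  # 10 surviving bases scoring 1..10 at 30% -> scores 8, 9, 10 kept
  x <- c(1:10, rep(0, 5))
  other <- c(rep(1, 10), rep(0, 5))
  reg <- call_regions(vec_track(x), vec_track(other), 30)
  # the three kept bases are adjacent, so they merge into one region [8, 10]
  expect_equal(BiocGenerics::start(reg), 8)
  expect_equal(BiocGenerics::end(reg), 10)
  # adjacency merge: kept bases 100-102 and 200 give two regions
  y <- numeric(300)
  y[c(100, 101, 102, 200)] <- 5
  reg2 <- call_regions(vec_track(y), vec_track(y), 30)
  expect_equal(BiocGenerics::start(reg2), c(100, 200))
  expect_equal(BiocGenerics::end(reg2), c(102, 200))
  # all-nonpositive track gives an empty set
  expect_message(
    reg3 <- call_regions(vec_track(rep(-1, 10)), vec_track(rep(1, 10)), 10),
    "no base survives")
  expect_length(reg3, 0L)
  expect_error(call_regions(vec_track(1:5), vec_track(1:5), 7), "percentile")
})

test_that("region calling equals the brute-force oracle on random tracks", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(200:2000, 1)
    # lumpy signed scores with ties, as after control subtraction
    x1 <- round(rnorm(n, 0, 1), 1) + rep(round(rnorm(ceiling(n / 50)), 1),
                                         each = 50)[1:n]
    x2 <- round(rnorm(n, 0.2, 1), 1)
    for (pct in c(1, 5, 10, 20, 30)) {
      got <- suppressMessages(call_regions(vec_track(x1), vec_track(x2), pct))
      want <- oracle_regions(x1, x2, pct)
      expect_equal(BiocGenerics::start(got), want$start)
      expect_equal(BiocGenerics::end(got), want$end)
    }
  }
})

test_that("gene- and region-level calls differ exactly on coordinate matching", {
  ann <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1000, 20000), width = 10000),
                                strand = "+")
  names(ann) <- c("geneA", "geneB")
  ann$class <- "mRNA"
  r1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 2999))
  r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9000, 9999))
  # replicas hit geneA at different coordinates: kept at gene level only
  expect_equal(genes_with_regions(r1, r2, ann, "gene"), "geneA")
  expect_equal(genes_with_regions(r1, r2, ann, "region"), character(0))
  # identical region sets: both levels agree
  expect_equal(genes_with_regions(r1, r1, ann, "gene"),
               genes_with_regions(r1, r1, ann, "region"))
  # an empty replica empties both levels
  empty <- GenomicRanges::GRanges()
  expect_length(genes_with_regions(r1, empty, ann, "gene"), 0L)
  expect_length(genes_with_regions(r1, empty, ann, "region"), 0L)
})

test_that("replica concordance reduces to the shared overlap machinery", {
  universe <- sprintf("g%03d", 1:100)
  res <- replica_concordance(universe[1:50], universe[11:60], universe)
  expect_equal(res$odds_ratio, 16)
  expect_equal(res$p, hypergeom_p(40, 50, 50, 100))
  # independent random sets have median OR about 1
  set.seed(5)
  ors <- replicate(200, {
    replica_concordance(sample(universe, 50), sample(universe, 50),
                        universe)$odds_ratio
  })
  expect_lt(abs(log(median(ors))), log(1.5))
})

test_that("percentile thresholds give nested base sets on random tracks", {
  set.seed(33)
  for (i in 1:10) {
    n <- 3000
    x1 <- round(rnorm(n), 1) + rep(round(rnorm(60), 1), each = 50)
    x2 <- round(rnorm(n, 0.3), 1)
    prev <- NULL
    for (pct in c(1, 5, 10, 20, 30)) {
      got <- suppressMessages(call_regions(vec_track(x1), vec_track(x2), pct))
      bases <- unlist(mapply(seq, BiocGenerics::start(got),
                             BiocGenerics::end(got), SIMPLIFY = FALSE))
      if (!is.null(prev)) expect_true(all(prev %in% bases))
      prev <- bases
    }
  }
})

test_that("strong planted proximity signal is recovered at every percentile", {
  spec <- simulation_spec(seed = 55L, n_chromosomes = 2L,
                          genes_per_chromosome = 50L, n_vlinc = 1L,
                          network_size_pos = 5L, network_size_neg = 10L,
                          chromatin_enrichment = 8, treatments = "DMSO")
  ann <- make_annotation(spec)
  truth <- make_ground_truth(spec, ann)
  tracks <- simulate_rat_tracks(spec, ann, truth)
  gT <- function(r, s) tracks[[paste0("vlinc_001|DMSO|r", r, "|", s)]]
  sub <- lapply(1:2, function(r) {
    ctrl <- normalize_track(gT(r, "no_oligo"))
    list(o1 = subtract_control(normalize_track(gT(r, "oligo_set_1")), ctrl),
         o2 = subtract_control(normalize_track(gT(r, "oligo_set_2")), ctrl))
  })
  planted <- truth$targets$gene
  universe <- names(ann)[ann$class == "mRNA"]
  for (pct in c(1, 5, 10, 20, 30)) {
    r1 <- suppressMessages(call_regions(sub[[1]]$o1, sub[[1]]$o2, pct))
    r2 <- suppressMessages(call_regions(sub[[2]]$o1, sub[[2]]$o2, pct))
    gs <- genes_with_regions(r1, r2, ann, "gene")
    ov <- overlap_test(intersect(gs, universe), planted, universe)
    expect_gt(ov$odds_ratio, 1)
    expect_lt(ov$p, 0.01)
  }
})
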