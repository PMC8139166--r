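# Stratified overlap, final threshold selection, stability and cis/trans.

fake_net <- function(vlinc, genes_pos, genes_neg) {
  net <- data.frame(
    vlinc = vlinc,
    gene = c(genes_pos, genes_neg),
    rho = rep(c(0.6, -0.6), c(length(genes_pos), length(genes_neg))),
    p = 1e-5,
    sign = rep(c("positive", "negative"),
               c(length(genes_pos), length(genes_neg))),
    stringsAsFactors = FALSE)
  attr(net, "vlincs") <- vlinc
  net
}

fake_halves <- function(universe) {
  data.frame(gene = universe,
             max_abund = rev(seq_along(universe)),
             half = rep(c("top", "bottom"),
                        c(ceiling(length(universe) / 2),
                          floor(length(universe) / 2))),
             stringsAsFactors = FALSE)
}

test_that("stratified overlap builds the four sign x half groups", {
  universe <- sprintf("g%03d", 1:100)
  halves <- fake_halves(universe)
  net <- fake_net("v1", universe[1:10], universe[51:60])
  rat <- universe[c(1:5, 51:55, 90:95)]
  ov <- stratified_overlap(net, rat, halves, universe, percentile = 5,
                           level = "gene")
  expect_equal(nrow(ov), 4L)
  # positive edges all lie in the top half here
  row <- ov[ov$sign == "positive" & ov$half == "top", ]
  expect_equal(row$n_group, 10L)
  expect_equal(row$a, 5L)
  expect_equal(row$a + row$b + row$c + row$d, 100L)
  # empty group flagged with p = 1
  row2 <- ov[ov$sign == "positive" & ov$half == "bottom", ]
  expect_true(row2$empty)
  expect_equal(row2$p, 1)
  # worked enumeration case appears through the same machinery
  u10 <- sprintf("u%02d", 1:10)
  net10 <- fake_net("v1", character(0), u10[1:5])
  h10 <- data.frame(gene = u10, max_abund = 10:1,
                    half = rep(c("top", "bottom"), each = 5),
                    stringsAsFactors = FALSE)
  ov10 <- stratified_overlap(net10, u10[1:5], h10, u10)
  expect_equal(ov10$p[ov10$sign == "negative" & ov10$half == "top"],
               1 / choose(10, 5))
})

test_that("random RAT sets give median overlap OR near 1", {
  set.seed(31)
  universe <- sprintf("g%03d", 1:200)
  halves <- fake_halves(universe)
  net <- fake_net("v1", universe[1:30], universe[101:130])
  ors <- replicate(200, {
    ov <- stratified_overlap(net, sample(universe, 100), halves, universe)
    ov$odds_ratio[ov$sign == "positive" & ov$half == "top"]
  })
  expect_lt(abs(log(median(ors))), log(1.5))
})

test_that("final threshold selection follows lowest p with strict tie-break", {
  universe <- sprintf("g%03d", 1:100)
  net <- fake_net("v1", universe[1:10], universe[51:60])
  base <- data.frame(vlinc = "v1", level = "gene", stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(c(1, 5, 10, 20, 30), function(pct) {
    rbind(
      cbind(base, sign = "negative", half = "top",
            p = c(`1` = 0.5, `5` = 0.01, `10` = 0.2, `20` = 0.3,
                  `30` = 0.4)[as.character(pct)], percentile = pct),
      cbind(base, sign = "positive", half = "bottom",
            p = c(`1` = 0.05, `5` = 0.05, `10` = 0.2, `20` = 0.3,
                  `30` = 0.4)[as.character(pct)], percentile = pct))
  }))
  rat_sets <- stats::setNames(
    lapply(c(1, 5, 10, 20, 30), function(p) universe[c(1:4, 51:55)]),
    as.character(c(1, 5, 10, 20, 30)))
  fin <- select_final_threshold(rows, net, rat_sets)
  expect_equal(unname(fin$percentile["negative"]), 5)   # argmin p
  expect_equal(unname(fin$percentile["positive"]), 1)   # tie -> stricter
  expect_setequal(fin$validated$negative, universe[51:55])
  expect_setequal(fin$validated$positive, universe[1:4])
  # all-p-at-1 fallback flags and picks the strictest percentile
  rows2 <- rows
  rows2$p <- 1
  fin2 <- select_final_threshold(rows2, net, rat_sets)
  expect_true(all(fin2$fallback))
  expect_equal(unname(fin2$percentile["negative"]), 1)
})

test_that("network stability: identical, disjoint and planted-noise cases", {
  universe <- sprintf("g%03d", 1:100)
  fn <- function(neg, pos) {
    structure(list(vlinc = "v1", percentile = c(negative = 5, positive = 5),
                   validated = list(negative = neg, positive = pos),
                   fallback = c(negative = FALSE, positive = FALSE)),
              class = "final_network")
  }
  same <- network_stability(list(DMSO = fn(universe[1:20], universe[30:40]),
                                 drug = fn(universe[1:20], universe[30:40])),
                            universe)
  expect_true(all(same$shared_fraction == 1))
  expect_true(all(same$p < 1e-6))
  disj <- network_stability(list(DMSO = fn(universe[1:20], universe[30:40]),
                                 drug = fn(universe[41:60], universe[61:71])),
                            universe)
  expect_true(all(disj$shared_fraction == 0))
  expect_true(all(disj$odds_ratio < 1))
  expect_error(network_stability(list(DMSO = fn("a", "b")), universe),
               "two treatments")
})

test_that("cis/trans comparison: identity case and planted cis enrichment", {
  spec <- tiny_spec(genes_per_chromosome = 30L)
  w <- sim_world(spec)
  universe <- names(w$ann)[w$ann$class == "mRNA"]
  chrom_of <- stats::setNames(as.character(GenomeInfoDb::seqnames(w$ann)),
                              names(w$ann))
  v <- w$truth$vlincs[1]
  cis_universe <- universe[chrom_of[universe] == chrom_of[v]]
  # cis = all genes: the two odds ratios coincide
  s_id <- list(list(vlinc = v, coexpr_genes = cis_universe[1:10],
                    rat_genes = cis_universe[5:20],
                    universe = cis_universe))
  res_id <- cis_trans_comparison(s_id, w$ann)
  expect_equal(res_id$per_sample$or_cis, res_id$per_sample$or_all)
  # all-trans network: the sample is excluded
  trans_genes <- universe[chrom_of[universe] != chrom_of[v]]
  s_tr <- list(list(vlinc = v, coexpr_genes = trans_genes[1:5],
                    rat_genes = universe[1:20], universe = trans_genes))
  expect_message(res_tr <- cis_trans_comparison(s_tr, w$ann), "no cis")
  expect_true(is.na(res_tr$p))
  # planted 2x cis concentration lifts cis OR above genome-wide OR
  set.seed(41)
  wins <- replicate(40, {
    # cis: network and RAT sets drawn from a shared cis core (strong
    # association); trans: independent draws (no association)
    core <- sample(cis_universe, 14)
    coexpr <- c(core[1:10], sample(trans_genes, 10))
    rat <- c(core[5:14], sample(setdiff(universe, cis_universe), 10))
    s <- list(list(vlinc = v, coexpr_genes = unique(coexpr),
                   rat_genes = unique(rat), universe = universe))
    r <- cis_trans_comparison(s, w$ann)$per_sample
    r$or_cis > r$or_all
  })
  expect_gt(mean(wins), 0.8)
})
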