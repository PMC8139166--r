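# End-to-end orchestration: simulate inputs, build and validate the networks,
# quantify knockdown and survival effects, and write every stage's outputs.

#' Assemble a pipeline configuration
#'
#' @param seed Integer seed driving every generator.
#' @param outdir Output directory.
#' @param spec A [simulation_spec()]; its seed is overridden by `seed`.
#' @param rho_min,p_max Co-expression network thresholds.
#' @param fc_threshold Differential-expression fold-change threshold.
#' @param min_fpkm Knockdown expression filter.
#' @param percentiles RAT signal percentile thresholds.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = "vlincnet_out",
                            spec = simulation_spec(seed = seed),
                            rho_min = 0.35, p_max = 0.01,
                            fc_threshold = 1.5, min_fpkm = 1,
                            percentiles = c(1, 5, 10, 20, 30)) {
  spec$seed <- as.integer(seed)
  validate_spec(spec)
  structure(list(seed = as.integer(seed), outdir = outdir, spec = spec,
                 rho_min = rho_min, p_max = p_max,
                 fc_threshold = fc_threshold, min_fpkm = min_fpkm,
                 percentiles = percentiles),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML map onto [pipeline_config()] arguments; entries
#' under `spec:` override [simulation_spec()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec_args <- y$spec
  if (!is.null(y$seed) && is.null(spec_args$seed)) spec_args$seed <- y$seed
  spec <- do.call(simulation_spec, spec_args %||% list())
  args <- y[setdiff(names(y), "spec")]
  args$spec <- spec
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-study pipeline
#'
#' Generates all inputs with planted ground truth, then runs every analysis
#' stage: differential expression and the Spearman co-expression network with
#' the negative-bias and distance-stratified summaries; RAT track processing,
#' region calling and replica concordance at every percentile; ANARS metagene
#' profiles with the top-30% and cis-vs-all tests; expression-stratified
#' network/RAT overlap, final threshold selection, network stability and the
#' cis/trans comparison; knockdown RFC effect summaries; and survival ratio
#' contrasts. All outputs are written as TSV under `config$outdir` together
#' with a machine-readable `run_manifest.json`. Identical configuration and
#' seed produce byte-identical output trees.
#'
#' @param config A [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  spec <- config$spec

  # --- synthetic inputs -----------------------------------------------------
  ann <- make_annotation(spec)
  truth <- make_ground_truth(spec, ann)
  expr <- simulate_expression(spec, ann, truth)
  tracks <- simulate_rat_tracks(spec, ann, truth)
  kd <- simulate_knockdown(spec, truth, ann)
  surv <- simulate_survival_counts(spec, truth)

  write_bed(ann, file.path(out, "annotation.bed"))
  write_expression(expr, file.path(out, "expression.tsv"),
                   file.path(out, "samples.tsv"))
  write_rat_tracks(tracks, file.path(out, "rat"))
  write_tsv(truth$targets, file.path(out, "ground_truth.tsv"))
  for (p in names(kd)) {
    write_tsv(kd[[p]], file.path(out, paste0("knockdown_", p, ".tsv")))
  }
  write_tsv(surv$counts, file.path(out, "survival_counts.tsv"))
  write_tsv(surv$pairing, file.path(out, "survival_pairs.tsv"))

  # --- expression stage -----------------------------------------------------
  de <- call_de(expr, fc_threshold = config$fc_threshold)
  scores <- coexpression_scores(expr)
  net <- spearman_network(expr, config$rho_min, config$p_max, scores = scores)
  halves <- stratify_by_expression(expr)
  universe <- halves$gene
  bias <- negative_bias_test(net)
  dist_med <- distance_stratified_medians(net, ann)
  write_tsv(de, file.path(out, "de_sets.tsv"))
  write_tsv(as.data.frame(net), file.path(out, "network.tsv"))
  write_tsv(halves, file.path(out, "expression_halves.tsv"))
  write_tsv(data.frame(bin = names(dist_med), median_rho = unname(dist_med)),
            file.path(out, "distance_medians.tsv"))

  # --- RAT stage ------------------------------------------------------------
  combos <- expand.grid(vlinc = truth$vlincs, treatment = spec$treatments,
                        stringsAsFactors = FALSE)
  rat_rows <- list()
  anars_rows <- list()
  overlap_rows <- list()
  stability_in <- list()
  cis_samples <- list()
  finals <- list()
  for (i in seq_len(nrow(combos))) {
    v <- combos$vlinc[i]
    tr <- combos$treatment[i]
    gene_sets <- list()
    sub <- lapply(1:2, function(rep_i) {
      getT <- function(src) {
        tracks[[paste(v, tr, paste0("r", rep_i), src, sep = "|")]]
      }
      ctrl <- normalize_track(getT("no_oligo"))
      list(o1 = subtract_control(normalize_track(getT("oligo_set_1")), ctrl),
           o2 = subtract_control(normalize_track(getT("oligo_set_2")), ctrl))
    })
    avg <- average_replicas(rat_mean(list(sub[[1]]$o1, sub[[1]]$o2)),
                            rat_mean(list(sub[[2]]$o1, sub[[2]]$o2)))
    for (pct in config$percentiles) {
      regions <- lapply(sub, function(s) call_regions(s$o1, s$o2, pct))
      for (lvl in c("gene", "region")) {
        gs <- genes_with_regions(regions[[1]], regions[[2]], ann, lvl)
        gene_sets[[paste(lvl, pct, sep = "_")]] <- gs
      }
      g1 <- names(ann)[ann$class == "mRNA" &
                       IRanges::overlapsAny(ann, regions[[1]])]
      g2 <- names(ann)[ann$class == "mRNA" &
                       IRanges::overlapsAny(ann, regions[[2]])]
      conc <- replica_concordance(intersect(g1, universe),
                                  intersect(g2, universe), universe)
      rat_rows[[length(rat_rows) + 1L]] <- data.frame(
        vlinc = v, treatment = tr, percentile = pct,
        genes_r1 = length(g1), genes_r2 = length(g2),
        gene_level = length(gene_sets[[paste0("gene_", pct)]]),
        region_level = length(gene_sets[[paste0("region_", pct)]]),
        concordance_or = conc$odds_ratio, concordance_p = conc$p,
        stringsAsFactors = FALSE)
      # expression-stratified overlap at this percentile, both levels
      for (lvl in c("gene", "region")) {
        gs <- intersect(gene_sets[[paste(lvl, pct, sep = "_")]], universe)
        overlap_rows[[length(overlap_rows) + 1L]] <- stratified_overlap(
          net, gs, halves, universe, vlinc = v, percentile = pct, level = lvl)
        overlap_rows[[length(overlap_rows)]]$treatment <- tr
      }
    }
    # ANARS on the replica-averaged score
    netv <- net[net$vlinc == v, , drop = FALSE]
    groups <- list(positive = netv$gene[netv$sign == "positive"],
                   negative = netv$gene[netv$sign == "negative"])
    groups$background <- setdiff(universe,
                                 c(groups$positive, groups$negative))
    chrom_of <- stats::setNames(as.character(GenomeInfoDb::seqnames(ann)),
                                names(ann))
    coexpr <- c(groups$positive, groups$negative)
    cis_genes <- coexpr[chrom_of[coexpr] == chrom_of[v]]
    profs <- lapply(groups, function(g) {
      if (length(g) == 0L) NULL else compute_anars(avg, g, ann)
    })
    for (sgn in c("positive", "negative")) {
      if (is.null(profs[[sgn]]) || is.null(profs$background)) next
      for (reg in c("body", "upstream", "downstream")) {
        anars_rows[[length(anars_rows) + 1L]] <- data.frame(
          vlinc = v, treatment = tr, comparison = paste0(sgn, "_vs_background"),
          region = reg, p = top30_test(profs[[sgn]], profs$background, reg),
          stringsAsFactors = FALSE)
      }
    }
    if (length(cis_genes) > 0L && length(coexpr) > 0L) {
      p_cis <- compute_anars(avg, cis_genes, ann, group = "cis")
      p_all <- compute_anars(avg, coexpr, ann, group = "all")
      for (reg in c("body", "upstream", "downstream")) {
        anars_rows[[length(anars_rows) + 1L]] <- data.frame(
          vlinc = v, treatment = tr, comparison = "cis_vs_all", region = reg,
          p = suppressWarnings(cis_vs_all_test(p_cis, p_all, reg)),
          stringsAsFactors = FALSE)
      }
    }
    # final threshold per sign from the gene-level overlaps
    ovl <- do.call(rbind, overlap_rows)
    ovl_v <- ovl[ovl$vlinc == v & ovl$treatment == tr & ovl$level == "gene", ,
                 drop = FALSE]
    rat_sets <- stats::setNames(
      lapply(config$percentiles,
             function(p) intersect(gene_sets[[paste0("gene_", p)]], universe)),
      as.character(config$percentiles))
    fin <- select_final_threshold(ovl_v, netv, rat_sets)
    finals[[paste(v, tr, sep = "|")]] <- fin
    stability_in[[v]] <- c(stability_in[[v]] %||% list(),
                           stats::setNames(list(fin), tr))
    for (sgn in c("negative", "positive")) {
      cis_samples[[length(cis_samples) + 1L]] <- list(
        vlinc = v,
        coexpr_genes = intersect(netv$gene[netv$sign == sgn], universe),
        rat_genes = rat_sets[[as.character(fin$percentile[sgn])]],
        universe = universe)
    }
  }
  rat_summary <- do.call(rbind, c(rat_rows, list(make.row.names = FALSE)))
  anars_summary <- do.call(rbind, c(anars_rows, list(make.row.names = FALSE)))
  overlaps <- do.call(rbind, c(overlap_rows, list(make.row.names = FALSE)))
  write_tsv(rat_summary, file.path(out, "rat_summary.tsv"))
  write_tsv(anars_summary, file.path(out, "anars_tests.tsv"))
  write_tsv(overlaps, file.path(out, "overlaps.tsv"))
  final_df <- do.call(rbind, lapply(names(finals), function(k) {
    f <- finals[[k]]
    data.frame(combo = k, sign = names(f$percentile),
               percentile = unname(f$percentile),
               n_validated = lengths(f$validated)[names(f$percentile)],
               stringsAsFactors = FALSE)
  }))
  write_tsv(final_df, file.path(out, "final_networks.tsv"))

  stability <- do.call(rbind, c(
    lapply(stability_in[lengths(stability_in) >= 2L],
           network_stability, universe = universe),
    list(make.row.names = FALSE)))
  if (!is.null(stability)) {
    write_tsv(stability, file.path(out, "network_stability.tsv"))
  }
  cis_trans <- cis_trans_comparison(cis_samples, ann)
  if (!is.null(cis_trans$per_sample)) {
    write_tsv(cis_trans$per_sample, file.path(out, "cis_trans_or.tsv"))
  }

  # --- knockdown stage ------------------------------------------------------
  kd_rows <- list()
  for (p in names(kd)) {
    v <- attr(kd[[p]], "vlinc")
    tab <- filter_expressed(kd[[p]], config$min_fpkm)
    rfc <- relative_fold_change(tab)
    sc_v <- scores[scores$vlinc == v, c("gene", "rho", "p")]
    grp <- suppressWarnings(group_genes(sc_v, config$rho_min, config$p_max))
    for (mode in c("combined", "by_day")) {
      es <- effect_summary(rfc, grp, mode)
      es$pair <- p
      es$vlinc <- v
      kd_rows[[length(kd_rows) + 1L]] <- es
    }
    write_tsv(rfc, file.path(out, paste0("rfc_", p, ".tsv")))
  }
  kd_effects <- do.call(rbind, c(kd_rows, list(make.row.names = FALSE)))
  write_tsv(kd_effects, file.path(out, "knockdown_effects.tsv"))

  # --- survival stage -------------------------------------------------------
  norm <- normalize_abundance(surv$counts)
  ratios <- targeting_ratios(norm, surv$pairing)
  conds <- names(spec$survival_depletion)
  contrasts <- list()
  if (length(conds) >= 2L) {
    for (i in seq_len(length(conds) - 1L)) {
      ct <- condition_comparison(ratios$ratios, conds[i], conds[length(conds)])
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        condition_a = conds[i], condition_b = conds[length(conds)],
        p = ct$p, mean_drop = ct$mean_drop, stringsAsFactors = FALSE)
    }
  }
  surv_tests <- do.call(rbind, c(contrasts, list(make.row.names = FALSE)))
  write_tsv(ratios$ratios, file.path(out, "survival_ratios.tsv"))
  write_tsv(ratios$summary, file.path(out, "survival_summary.tsv"))
  if (!is.null(surv_tests)) {
    write_tsv(surv_tests, file.path(out, "survival_tests.tsv"))
  }

  # --- run manifest (no timestamps: identical runs are byte-identical) ------
  manifest <- list(
    seed = config$seed,
    thresholds = list(rho_min = config$rho_min, p_max = config$p_max,
                      fc_threshold = config$fc_threshold,
                      min_fpkm = config$min_fpkm,
                      percentiles = config$percentiles),
    spec = unclass(spec),
    stages = c("synthetic_data", "expression", "rat_signal", "anars",
               "network_validation", "knockdown", "survival")
  )
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(annotation = ann, truth = truth, expr = expr, net = net,
                 halves = halves, de = de, rat_summary = rat_summary,
                 anars = anars_summary, overlaps = overlaps, finals = finals,
                 stability = stability, cis_trans = cis_trans,
                 knockdown_effects = kd_effects, survival = ratios,
                 survival_tests = surv_tests))
}
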