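# Simulation design: one spec object holds every knob of the synthetic study.

#' Simulation specification for the synthetic study
#'
#' Bundles all parameters of the synthetic data generators. The defaults
#' emulate the design of the drug-perturbation study the pipeline targets:
#' a 64-sample expression series (drug treatments at 3 h and 6 h plus DMSO and
#' water solvent controls), vlincRNA target networks that are biased towards
#' negative co-expression, RAT chromatin-proximity tracks with two oligo sets,
#' a no-oligo control and two biological replicas per vlincRNA-treatment
#' combination, Cas13 knockdown tables at days 0/3/6 and pooled-gRNA survival
#' counts.
#'
#' @param seed Integer seed; all generators derive their random streams from
#'   it (with fixed per-stage offsets, so the stages are mutually independent).
#' @param n_chromosomes,genes_per_chromosome Genome layout; mRNA gene
#'   intervals are placed without overlap on each chromosome.
#' @param n_vlinc Number of vlincRNA loci, assigned round-robin to
#'   chromosomes.
#' @param n_samples Length of the expression series. Must be `2 * n_drugs + 4`
#'   for an integer number of drugs: each drug contributes a 3 h and a 6 h
#'   sample and there are four solvent controls (DMSO/water at 3 h and 6 h).
#' @param network_size_pos,network_size_neg Planted positive/negative targets
#'   per vlincRNA. Defaults scale the study's median network composition
#'   (roughly 1 positive : 2.4 negative, ~11% of expressed mRNAs in total).
#' @param rho_target Magnitude of the planted Spearman correlation between a
#'   vlincRNA and its targets, in (0, 1).
#' @param chromatin_enrichment Fold enrichment of RAT coverage over planted
#'   network gene bodies relative to background (>= 1).
#' @param cis_boost Extra multiplicative RAT enrichment applied to planted
#'   targets on the vlincRNA's own chromosome (1 = none).
#' @param knockdown_effect Fractional expression shift of planted targets
#'   under vlincRNA depletion, in [0, 1): negative targets go up by
#'   `1 + effect`, positive targets down by `1 - effect`.
#' @param noise_sd Standard deviation of log-abundance noise in the
#'   expression generator.
#' @param gene_length,gene_spacer,vlinc_length Interval sizes (bases) used to
#'   lay out the synthetic genome. The spacer leaves room for the 5-kb flanks
#'   used by the metagene statistic and keeps the genic fraction of the
#'   genome realistic (about 10%), so percentile thresholds on RAT signal
#'   retain discriminating power.
#' @param treatments Treatment labels for the RAT arm (first one is the
#'   vehicle control).
#' @param background_rate Expected background RAT coverage per base (reads).
#' @param rat_flank_decay Width (bases) of the linear taper of planted RAT
#'   enrichment on each side of a target gene body (proximity signal is
#'   regional, not sharply bounded by the gene).
#' @param domain_size,domain_sd Size (bases) and log-scale standard deviation
#'   of the mean-one log-normal background domain factors drawn independently
#'   per track (see [simulate_rat_tracks()]); `domain_sd = 0` disables the
#'   heterogeneity.
#' @param kd_noise_sd Log-normal measurement noise of knockdown FPKM values.
#' @param vlinc_depletion Fractional depletion of the vlincRNA itself in
#'   targeting arms at days 3/6 (the study reports ~20% average depletion).
#' @param survival_depletion Named vector of planted targeting/control
#'   abundance ratios per survival condition. Defaults follow the study's
#'   printed averages: 0.90 at pooling, 0.91 before the drug, 0.91 for
#'   etoposide without induction and 0.78 for etoposide with Dox induction.
#' @param n_grna_pairs Number of targeting/mismatch gRNA pairs in the
#'   survival pool.
#' @param survival_depth Expected sequencing depth per survival sample.
#' @param survival_noise_sd Log-normal biological noise on gRNA abundances.
#' @param survival_replicates Biological replicates per survival condition.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_chromosomes = 2L,
                            genes_per_chromosome = 100L,
                            n_vlinc = 2L,
                            n_samples = 64L,
                            network_size_pos = 7L,
                            network_size_neg = 16L,
                            rho_target = 0.9,
                            chromatin_enrichment = 3,
                            cis_boost = 1,
                            knockdown_effect = 0.4,
                            noise_sd = 1,
                            gene_length = 2000L,
                            gene_spacer = 18000L,
                            vlinc_length = 50000L,
                            treatments = c("DMSO", "etoposide"),
                            background_rate = 0.02,
                            rat_flank_decay = 5000L,
                            domain_size = 10000L,
                            domain_sd = 0,
                            kd_noise_sd = 0.1,
                            vlinc_depletion = 0.2,
                            survival_depletion = c(baseline = 0.90,
                                                   pre_drug = 0.91,
                                                   drug_noDox = 0.91,
                                                   drug_Dox = 0.78),
                            n_grna_pairs = 4L,
                            survival_depth = 1e5,
                            survival_noise_sd = 0.05,
                            survival_replicates = 3L) {
  spec <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    n_vlinc = as.integer(n_vlinc),
    n_samples = as.integer(n_samples),
    network_size_pos = as.integer(network_size_pos),
    network_size_neg = as.integer(network_size_neg),
    rho_target = rho_target,
    chromatin_enrichment = chromatin_enrichment,
    cis_boost = cis_boost,
    knockdown_effect = knockdown_effect,
    noise_sd = noise_sd,
    gene_length = as.integer(gene_length),
    gene_spacer = as.integer(gene_spacer),
    vlinc_length = as.integer(vlinc_length),
    treatments = treatments,
    background_rate = background_rate,
    rat_flank_decay = as.integer(rat_flank_decay),
    domain_size = as.integer(domain_size),
    domain_sd = domain_sd,
    kd_noise_sd = kd_noise_sd,
    vlinc_depletion = vlinc_depletion,
    survival_depletion = survival_depletion,
    n_grna_pairs = as.integer(n_grna_pairs),
    survival_depth = survival_depth,
    survival_noise_sd = survival_noise_sd,
    survival_replicates = as.integer(survival_replicates)
  )
  class(spec) <- "simulation_spec"
  validate_spec(spec)
  spec
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("simulation_spec:",
      x$n_chromosomes, "chromosomes x", x$genes_per_chromosome, "genes,",
      x$n_vlinc, "vlincRNAs,", x$n_samples, "samples\n")
  cat("  planted network:", x$network_size_pos, "positive /",
      x$network_size_neg, "negative targets per vlincRNA, |rho| =",
      x$rho_target, "\n")
  cat("  chromatin enrichment:", x$chromatin_enrichment,
      " knockdown effect:", x$knockdown_effect, "\n")
  invisible(x)
}

validate_spec <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  counts <- c(spec$n_chromosomes, spec$genes_per_chromosome, spec$n_vlinc,
              spec$n_samples, spec$gene_length, spec$gene_spacer,
              spec$vlinc_length, spec$n_grna_pairs, spec$survival_replicates)
  if (any(counts <= 0)) stop("all counts and sizes must be positive")
  if (spec$rho_target <= 0 || spec$rho_target >= 1) {
    stop("rho_target must lie in (0, 1)")
  }
  if (spec$chromatin_enrichment < 1) stop("chromatin_enrichment must be >= 1")
  if (spec$cis_boost < 1) stop("cis_boost must be >= 1")
  if (spec$domain_sd < 0 || spec$domain_size <= 0) {
    stop("domain_size must be positive and domain_sd non-negative")
  }
  if (spec$knockdown_effect < 0 || spec$knockdown_effect >= 1) {
    stop("knockdown_effect must lie in [0, 1)")
  }
  n_genes <- spec$n_chromosomes * spec$genes_per_chromosome
  per_vlinc <- spec$network_size_pos + spec$network_size_neg
  if (per_vlinc * spec$n_vlinc >= n_genes) {
    stop("planted networks exceed the number of available genes")
  }
  if (spec$n_samples < 6L || (spec$n_samples - 4L) %% 2L != 0L) {
    stop("n_samples must be 2 * n_drugs + 4 (two time points per drug plus ",
         "four solvent controls)")
  }
  if (is.null(names(spec$survival_depletion)) ||
      any(spec$survival_depletion <= 0)) {
    stop("survival_depletion must be a named vector of positive ratios")
  }
  invisible(spec)
}
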