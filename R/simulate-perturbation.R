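# Generators for the Cas13 knockdown FPKM tables and the pooled-gRNA
# survival counts.

#' Simulate Cas13 knockdown FPKM tables
#'
#' For every vlincRNA, produces FPKM tables for `pairs_per_vlinc` pairs of
#' cell lines expressing a targeting gRNA (arm `T`) or its cognate mismatch
#' control (arm `NT`), each sampled at days 0, 3 and 6 of Cas13 induction.
#' Day-0 samples are identically distributed across arms. In targeting arms
#' at days 3 and 6, planted negative targets are shifted up by
#' `1 + knockdown_effect`, planted positive targets down by
#' `1 - knockdown_effect`, and the vlincRNA itself is depleted by
#' `vlinc_depletion`; mismatch arms carry no systematic shift. All values get
#' independent log-normal measurement noise (`kd_noise_sd`).
#'
#' @param spec A [simulation_spec()].
#' @param truth Output of [make_ground_truth()].
#' @param annotation Output of [make_annotation()].
#' @param pairs_per_vlinc Number of gRNA pairs per vlincRNA (study design: 2).
#' @return A named list of `knockdown_table` data.frames (one per gRNA pair)
#'   with columns `gene`, `T0`, `T3`, `T6`, `NT0`, `NT3`, `NT6` and
#'   attributes `vlinc` and `pair`.
#' @export
simulate_knockdown <- function(spec, truth, annotation, pairs_per_vlinc = 2L) {
  validate_spec(spec)
  ids <- names(annotation)
  out <- list()
  .with_stage_seed(spec$seed, 41L, {
    baseline <- exp(stats::rnorm(length(ids), mean = log(20), sd = 1))
    names(baseline) <- ids
    for (v in truth$vlincs) {
      shift <- rep(1, length(ids))
      names(shift) <- ids
      tdf <- truth$targets[truth$targets$vlinc == v, , drop = FALSE]
      shift[tdf$gene[tdf$sign == "negative"]] <- 1 + spec$knockdown_effect
      shift[tdf$gene[tdf$sign == "positive"]] <- 1 - spec$knockdown_effect
      shift[v] <- 1 - spec$vlinc_depletion
      for (p in seq_len(pairs_per_vlinc)) {
        noise <- function() exp(stats::rnorm(length(ids), 0, spec$kd_noise_sd))
        tab <- data.frame(
          gene = ids,
          T0 = baseline * noise(),
          T3 = baseline * shift * noise(),
          T6 = baseline * shift * noise(),
          NT0 = baseline * noise(),
          NT3 = baseline * noise(),
          NT6 = baseline * noise(),
          stringsAsFactors = FALSE
        )
        attr(tab, "vlinc") <- v
        attr(tab, "pair") <- sprintf("%s_gRNA%d", v, p)
        class(tab) <- c("knockdown_table", "data.frame")
        out[[attr(tab, "pair")]] <- tab
      }
    }
  })
  out
}

#' Simulate pooled-gRNA survival counts
#'
#' Emulates the survival challenge: cell lines carrying targeting gRNAs or
#' their cognate mismatch controls are pooled, treated, and the gRNA cassette
#' abundances are profiled by sequencing. Targeting gRNAs are depleted
#' multiplicatively by the planted per-condition ratio in
#' `spec$survival_depletion`; control gRNAs keep weight 1. Counts are Poisson
#' at the configured depth with log-normal biological noise per
#' (gRNA, condition, replicate).
#'
#' @param spec A [simulation_spec()].
#' @param truth Output of [make_ground_truth()] (gRNA pairs are allocated
#'   round-robin to the vlincRNAs).
#' @return A list with `counts` (data.frame: `grna`, `pair`, `type`,
#'   `condition`, `replicate`, `count`) and `pairing` (data.frame:
#'   `targeting`, `control`, `pair`).
#' @export
simulate_survival_counts <- function(spec, truth) {
  validate_spec(spec)
  pairs <- sprintf("pair%d", seq_len(spec$n_grna_pairs))
  targeting <- paste0(pairs, "_T")
  control <- paste0(pairs, "_NT")
  conditions <- names(spec$survival_depletion)
  rows <- list()
  .with_stage_seed(spec$seed, 51L, {
    for (cond in conditions) {
      dep <- spec$survival_depletion[[cond]]
      for (rep_i in seq_len(spec$survival_replicates)) {
        w <- c(rep(dep, length(targeting)), rep(1, length(control))) *
          exp(stats::rnorm(2L * length(pairs), 0, spec$survival_noise_sd))
        lambda <- spec$survival_depth * w / sum(w)
        cnt <- stats::rpois(length(lambda), lambda)
        rows[[length(rows) + 1L]] <- data.frame(
          grna = c(targeting, control),
          pair = rep(pairs, 2L),
          type = rep(c("targeting", "control"), each = length(pairs)),
          condition = cond,
          replicate = rep_i,
          count = cnt,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  list(
    counts = do.call(rbind, rows),
    pairing = data.frame(targeting = targeting, control = control,
                         pair = pairs, stringsAsFactors = FALSE)
  )
}
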