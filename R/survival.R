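# Pooled-gRNA survival analysis: library-fraction normalisation,
# targeting/control abundance ratios and condition contrasts.

#' Normalise gRNA counts to library fractions
#'
#' Converts raw counts to the fraction of the library within each
#' (condition, replicate) sample, so fractions sum to 1 per sample. The ratio
#' statistics downstream are invariant to this choice of scale.
#'
#' @param counts Data.frame with columns `grna`, `condition`, `replicate`,
#'   `count` (see [simulate_survival_counts()]).
#' @return The same data.frame with an added `fraction` column.
#' @export
normalize_abundance <- function(counts) {
  stopifnot(all(c("grna", "condition", "replicate", "count") %in%
                names(counts)),
            all(counts$count >= 0))
  key <- interaction(counts$condition, counts$replicate, drop = TRUE)
  totals <- tapply(counts$count, key, sum)
  if (any(totals <= 0)) stop("zero-total sample")
  counts$fraction <- counts$count / as.numeric(totals[key])
  counts
}

#' Targeting / control abundance ratios per gRNA pair
#'
#' Estimates relative survival of cells carrying a targeting gRNA versus its
#' cognate mismatch control: the ratio of their library fractions, with
#' replicate fractions averaged within each condition before the ratio is
#' taken. Pairs whose control fraction is zero give a missing ratio with a
#' warning.
#'
#' @param norm Output of [normalize_abundance()].
#' @param pairing Data.frame with columns `targeting`, `control`, `pair`.
#' @return A list with `ratios` (data.frame `pair`, `condition`, `ratio`) and
#'   `summary` (per-condition mean and median ratio).
#' @export
targeting_ratios <- function(norm, pairing) {
  stopifnot(all(c("targeting", "control", "pair") %in% names(pairing)))
  miss <- setdiff(c(pairing$targeting, pairing$control), norm$grna)
  if (length(miss) > 0L) {
    stop("pairing refers to unknown gRNAs: ", paste(miss, collapse = ", "))
  }
  conditions <- unique(norm$condition)
  rows <- list()
  for (cond in conditions) {
    sub <- norm[norm$condition == cond, , drop = FALSE]
    mean_frac <- tapply(sub$fraction, sub$grna, mean)
    for (i in seq_len(nrow(pairing))) {
      ft <- mean_frac[[pairing$targeting[i]]]
      fc <- mean_frac[[pairing$control[i]]]
      ratio <- if (fc == 0) {
        warning(sprintf("pair %s in %s: control fraction is zero",
                        pairing$pair[i], cond))
        NA_real_
      } else ft / fc
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pairing$pair[i], condition = cond, ratio = ratio,
        stringsAsFactors = FALSE)
    }
  }
  ratios <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summary <- do.call(rbind, lapply(split(ratios, ratios$condition), function(d) {
    data.frame(condition = d$condition[1L],
               mean_ratio = mean(d$ratio, na.rm = TRUE),
               median_ratio = stats::median(d$ratio, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(ratios = ratios, summary = summary)
}

#' One-sided paired t-test between survival conditions
#'
#' Tests, across gRNA pairs, whether the targeting/control ratio in condition
#' `a` exceeds that in condition `b` (i.e. a drop in relative survival going
#' from `a` to `b`), with a one-sided paired Student's t-test.
#'
#' @param ratios The `ratios` data.frame from [targeting_ratios()].
#' @param condition_a,condition_b Condition labels to contrast.
#' @return A list with `p`, `mean_drop` (mean of a - b) and `n_pairs`.
#' @export
condition_comparison <- function(ratios, condition_a, condition_b) {
  ra <- ratios[ratios$condition == condition_a, , drop = FALSE]
  rb <- ratios[ratios$condition == condition_b, , drop = FALSE]
  m <- merge(ra, rb, by = "pair", suffixes = c("_a", "_b"))
  m <- m[stats::complete.cases(m[, c("ratio_a", "ratio_b")]), , drop = FALSE]
  if (nrow(m) < 2L) stop("at least 2 complete gRNA pairs required")
  tt <- stats::t.test(m$ratio_a, m$ratio_b, paired = TRUE,
                      alternative = "greater")
  list(p = tt$p.value, mean_drop = mean(m$ratio_a - m$ratio_b),
       n_pairs = nrow(m))
}
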