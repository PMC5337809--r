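# Repertoire statistics on simulation output or plain count tables: the
# gap-based clonal-expansion threshold, affinity classification at a
# percentile cut, the abundance-by-affinity contingency summary, and the
# per-step summary trajectories.

#' Clonal-expansion threshold from a count histogram
#'
#' Builds the frequency histogram `F(c)` of integer cell/read counts and
#' defines the threshold `T` as the lowest count `c >= 1` whose frequency
#' falls below `relax_p` (default 1, i.e. the lowest unobserved count).
#' Assuming the unobserved null distribution of unexpanded subclones has no
#' mass at or above `T`, subclones with counts strictly greater than `T` are
#' called expanded. If the counts have no gap below their maximum, `T` is
#' `max(counts) + 1` and nothing is expanded.
#'
#' @param counts nonnegative integer counts, one per subclone.
#' @param relax_p relaxation parameter `p >= 1` of the threshold rule.
#' @param ids optional subclone identifiers (defaults to indices).
#' @return List with `threshold` (T), `expanded_ids`, `relax_p` and the
#'   histogram `freq` (named vector `F(c)` for `c` in 1..max).
#' @export
expansion_threshold <- function(counts, relax_p = 1, ids = seq_along(counts)) {
  if (length(counts) == 0) stop("empty count vector")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (relax_p < 1) stop("relax_p must be >= 1")
  cmax <- max(counts)
  freq <- tabulate(counts[counts >= 1], nbins = max(cmax, 1L))
  below <- which(freq < relax_p)
  threshold <- if (length(below)) min(below) else cmax + 1L
  list(
    threshold = as.integer(threshold),
    expanded_ids = ids[counts > threshold],
    relax_p = relax_p,
    freq = stats::setNames(freq, seq_along(freq))
  )
}

#' Final-step centrocyte counts for expansion calling
#'
#' Repertoire sequencing is assumed to measure centrocytes (centroblasts
#' express little surface BCR), so the expansion threshold for simulated
#' data is determined from CC counts at the last time point, rounded to the
#' nearest integer; subclones rounding to zero are unobservable and dropped.
#'
#' @param result a `gcr_result`.
#' @return Data frame with `id`, `sigma`, `n_mut` and integer `count` for
#'   every subclone with rounded final CC >= 1.
#' @export
cc_counts_for_expansion <- function(result) {
  fin <- result$final
  cnt <- round(fin$cc)
  keep <- cnt >= 1
  data.frame(id = fin$id[keep], sigma = fin$sigma[keep],
             n_mut = fin$n_mut[keep], count = as.integer(cnt[keep]))
}

#' Affinities of every subclone produced during the reaction
#'
#' Founders plus every spawned subclone, each counted once with its fixed
#' absolute affinity (pruned subclones included).
#'
#' @param result a `gcr_result`.
#' @return Data frame `id`, `sigma`, `n_mut` (total mutations are not stored
#'   in events; `n_mut` is `NA` for spawns and 0 for founders -- use `final`
#'   or the trajectory for mutation counts of living subclones).
#' @export
subclone_affinities <- function(result) {
  ev <- result$events
  born <- ev$type %in% c("founder", "spawn")
  data.frame(id = ev$id[born], sigma = ev$sigma[born])
}

#' Percentile threshold separating high- from low-affinity subclones
#'
#' High affinity is defined relative to the affinities of all subclones ever
#' produced during the reaction: the threshold is the given percentile
#' (default 75th, linear interpolation between order statistics); subclones
#' strictly above it are "high affinity".
#'
#' @param sigmas absolute affinities of all subclones ever created.
#' @param percentile percentile in \[0, 100\] (default 75).
#' @return The affinity threshold, a single number.
#' @export
affinity_threshold <- function(sigmas, percentile = 75) {
  if (length(sigmas) == 0) stop("empty affinity vector")
  unname(stats::quantile(sigmas, percentile / 100, type = 7))
}

#' Cross-tabulate expansion status against affinity class
#'
#' The headline statistic of the analysis: calls expansion on rounded final
#' CC counts with the gap threshold, classifies every subclone ever produced
#' against the percentile affinity threshold, and summarizes the mixture of
#' affinities within the expanded and unexpanded compartments, the Spearman
#' rank correlation (average-rank ties) between final CC count and affinity,
#' and whether the most abundant subclone sits in the top affinity quartile
#' and/or is the single best binder.
#'
#' @param result a `gcr_result`.
#' @param percentile affinity percentile defining "high affinity"
#'   (default 75).
#' @param relax_p expansion-threshold relaxation (default 1).
#' @return List with `expansion` (the [expansion_threshold()] call),
#'   `affinity_threshold`, `table` (2x2 matrix expanded/unexpanded x
#'   high/low), `pct_low_affinity_expanded`, `pct_high_affinity_unexpanded`,
#'   `spearman_rho` (NA when fewer than 3 subclones are observable),
#'   `most_abundant_in_top_quartile`, `most_abundant_is_best_binder`, and
#'   the per-subclone `data` frame.
#' @export
affinity_abundance_summary <- function(result, percentile = 75,
                                       relax_p = 1) {
  obs <- cc_counts_for_expansion(result)
  if (nrow(obs) == 0) stop("no subclone has a rounded final CC count >= 1")
  thr <- affinity_threshold(subclone_affinities(result)$sigma, percentile)
  call <- expansion_threshold(obs$count, relax_p = relax_p, ids = obs$id)
  obs$expanded <- obs$count > call$threshold
  obs$high_affinity <- obs$sigma > thr

  tab <- matrix(c(
    sum(obs$expanded & obs$high_affinity),
    sum(obs$expanded & !obs$high_affinity),
    sum(!obs$expanded & obs$high_affinity),
    sum(!obs$expanded & !obs$high_affinity)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("expanded", "unexpanded"), c("high", "low")))

  rho <- if (nrow(obs) >= 3) {
    stats::cor(obs$count, obs$sigma, method = "spearman")
  } else NA_real_

  top <- which.max(obs$count)
  list(
    expansion = call,
    affinity_threshold = thr,
    table = tab,
    pct_low_affinity_expanded =
      if (sum(tab["expanded", ]) > 0) {
        100 * tab["expanded", "low"] / sum(tab["expanded", ])
      } else NA_real_,
    pct_high_affinity_unexpanded =
      if (sum(tab["unexpanded", ]) > 0) {
        100 * tab["unexpanded", "high"] / sum(tab["unexpanded", ])
      } else NA_real_,
    spearman_rho = rho,
    most_abundant_in_top_quartile = unname(obs$sigma[top] > thr),
    most_abundant_is_best_binder =
      unname(obs$sigma[top] >= max(obs$sigma)),
    data = obs
  )
}

#' Per-step summary trajectories
#'
#' Totals and diversity measures per 6-h step: total CB, total CC, their
#' ratio, the number of unique subclones (CC >= 1 -- sub-unit counts are kept
#' alive by the continuous equations but are not observable), the maximum
#' mutation count among those subclones, and the cell-weighted mean absolute
#' affinity. When the result carries a full trajectory, per-affinity-class
#' cell totals (CB + CC summed within affinity bins) are appended.
#'
#' @param result a `gcr_result`.
#' @param affinity_breaks bin edges for the affinity classes (used only with
#'   full trajectories).
#' @return Data frame with one row per recorded step.
#' @export
summary_trajectories <- function(result,
                                 affinity_breaks = c(0, 1, 2, 3, 4, 6, Inf)) {
  ss <- result$step_summary
  out <- data.frame(
    step = ss$step, time = ss$time,
    cb_total = ss$cb_total, cc_total = ss$cc_total,
    cb_cc_ratio = ifelse(ss$cc_total > 0, ss$cb_total / ss$cc_total, NA_real_),
    n_subclones = ss$n_cc1,
    max_mut = ss$max_mut_cc1,
    mean_affinity = ss$aff_mean_cell
  )
  if (!is.null(result$trajectory)) {
    tr <- result$trajectory
    cls <- cut(tr$sigma, affinity_breaks, right = FALSE)
    cells <- tr$cb + tr$cc
    agg <- tapply(cells, list(tr$step, cls), sum, default = 0)
    colnames(agg) <- paste0("cells_aff_", colnames(agg))
    out <- cbind(out, agg[match(out$step, rownames(agg)), , drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Clonal sizes
#'
#' Fraction of the total count carried by each subclone (a subclone's reads
#' or cells divided by the total).
#'
#' @param counts nonnegative counts, with positive total.
#' @return Fractions summing to 1.
#' @export
clonal_sizes <- function(counts) {
  if (length(counts) == 0) stop("empty count vector")
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  counts / total
}
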