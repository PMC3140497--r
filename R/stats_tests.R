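# The three inferential procedures: the pseudocount ratio statistic, the
# exact paired Wilcoxon signed-rank test by full sign-vector enumeration, and
# the Monte Carlo family-resampling test with its analytic binomial tail.

#' Ratio (pseudocount) configuration
#'
#' Both counts receive a pseudocount before the ratio is formed, so the ratio
#' is defined when either count is zero: (a + offset) / (b + offset).
#'
#' @param offset positive pseudocount added to numerator and denominator
#'   counts (default 1).
#' @return a `ratio_config` list.
#' @export
ratio_config <- function(offset = 1) {
  stopifnot(is.numeric(offset), length(offset) == 1, offset > 0)
  structure(list(offset = offset), class = "ratio_config")
}

#' Swimbladderless-to-swimbladdered prey ratio
#'
#' @param count_no_sb non-negative count (rationals permitted after replicate
#'   averaging) of prey in swimbladderless families.
#' @param count_sb non-negative count of prey in swimbladdered families.
#' @param cfg a [ratio_config()].
#' @return the positive, finite ratio `(count_no_sb + offset) / (count_sb + offset)`.
#' @export
swimbladder_ratio <- function(count_no_sb, count_sb, cfg = ratio_config()) {
  stopifnot(inherits(cfg, "ratio_config"))
  if (any(count_no_sb < 0) || any(count_sb < 0)) {
    stop_stage("ratio", "counts must be non-negative")
  }
  (count_no_sb + cfg$offset) / (count_sb + cfg$offset)
}

#' Construct a paired sample
#'
#' One pair per sampling unit (transect): the value of a statistic under
#' condition A (sponging) and under condition B (non-sponging).
#'
#' @param unit_ids unique unit identifiers, one per pair.
#' @param values_a,values_b numeric vectors, same length as `unit_ids`.
#' @return a `paired_sample` list.
#' @export
paired_sample <- function(unit_ids, values_a, values_b) {
  unit_ids <- as.character(unit_ids)
  stopifnot(length(values_a) == length(unit_ids),
            length(values_b) == length(unit_ids),
            !anyDuplicated(unit_ids))
  structure(list(unit_ids = unit_ids,
                 values_a = as.numeric(values_a),
                 values_b = as.numeric(values_b)),
            class = "paired_sample")
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("Paired sample over %d units\n", length(x$unit_ids)))
  print(data.frame(unit = x$unit_ids, a = x$values_a, b = x$values_b,
                   diff = x$values_a - x$values_b))
  invisible(x)
}

# Sum counts over a logical family subset, per (transect, mode); zero when no
# family in the subset was seen.
sum_by_transect_mode <- function(table, families, transect_ids) {
  sub <- table[table$family %in% families, , drop = FALSE]
  out <- matrix(0, nrow = length(transect_ids), ncol = length(MODES),
                dimnames = list(transect_ids, MODES))
  if (nrow(sub) > 0) {
    agg <- tapply(sub$count, list(sub$transect_id, sub$mode), sum)
    for (tid in intersect(rownames(agg), transect_ids)) {
      for (m in intersect(colnames(agg), MODES)) {
        v <- agg[tid, m]
        if (!is.na(v)) out[tid, m] <- v
      }
    }
  }
  out
}

#' Per-transect swimbladder-ratio pairs
#'
#' For each transect, totals prey in swimbladderless and swimbladdered
#' families under each mode and forms the pseudocount ratio, yielding one
#' (sponging, non-sponging) ratio pair per transect.  The table must already
#' be replicate-averaged and restricted to transects; every family present
#' must be annotated in the universe.
#'
#' @param table replicate-averaged, transects-only `abundance_table`.
#' @param universe a [family_universe()] covering every family in `table`.
#' @param cfg a [ratio_config()].
#' @param transect_ids optional full set of transect ids in the design; a
#'   transect with no retained prey then contributes the degenerate pair
#'   (1, 1).  Defaults to the transects present in `table`.
#' @return a [paired_sample()] of ratios.
#' @export
transect_ratio_pairs <- function(table, universe, cfg = ratio_config(),
                                 transect_ids = NULL) {
  if (any(table$site_kind != "transect")) {
    stop_stage("ratio-pairs", "table must be restricted to transects")
  }
  unknown <- setdiff(unique(table$family), universe$family)
  if (length(unknown) > 0) {
    stop_stage("ratio-pairs", "family not annotated in universe: %s",
               paste(unknown, collapse = ", "))
  }
  transect_ids <- as.character(transect_ids %||%
                                 sort(unique(table$transect_id)))
  no_sb <- universe$family[!universe$has_swimbladder]
  sb <- universe$family[universe$has_swimbladder]
  tot_no <- sum_by_transect_mode(table, no_sb, transect_ids)
  tot_sb <- sum_by_transect_mode(table, sb, transect_ids)
  paired_sample(
    transect_ids,
    swimbladder_ratio(tot_no[, "sponging"], tot_sb[, "sponging"], cfg),
    swimbladder_ratio(tot_no[, "non_sponging"], tot_sb[, "non_sponging"], cfg))
}

#' Per-transect abundance pairs over the sponging-extracted family set
#'
#' Restricts to the families with nonzero total sponging abundance and, for
#' each transect, sums sponging abundance (values_a) and non-sponging
#' abundance over the same family set (values_b).  A family never extracted
#' during sponging is excluded even if abundant during non-sponging.
#'
#' @param table replicate-averaged, transects-only `abundance_table`.
#' @param transect_ids optional full set of transect ids in the design.
#' @return a [paired_sample()] of summed abundances.
#' @export
extracted_family_abundance_pairs <- function(table, transect_ids = NULL) {
  if (any(table$site_kind != "transect")) {
    stop_stage("abundance-pairs", "table must be restricted to transects")
  }
  transect_ids <- as.character(transect_ids %||%
                                 sort(unique(table$transect_id)))
  sponging_tot <- tapply(table$count[table$mode == "sponging"],
                         table$family[table$mode == "sponging"], sum)
  fam_set <- names(sponging_tot)[sponging_tot > 0]
  tot <- sum_by_transect_mode(table, fam_set, transect_ids)
  paired_sample(transect_ids, tot[, "sponging"], tot[, "non_sponging"])
}

# Exact null distribution of the signed-rank statistic W over all 2^n
# equiprobable sign assignments, as a probability vector on the integer grid
# of doubled ranks (midranks are multiples of 1/2).  Iterative convolution is
# an exact, complete enumeration of the 2^n assignments.
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  support <- sum(r2)
  p <- numeric(support + 1)  # index i = doubled statistic i-1
  p[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), p[seq_len(length(p) - r)])
    p <- (p + shifted) / 2
  }
  p
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Computes the signed-rank statistic W (the sum of ranks of positive
#' differences, with zero differences dropped and midranks for tied absolute
#' differences) and its exact two-sided p-value by enumerating all
#' `2^n` sign assignments of the nonzero differences:
#' `p = min(1, 2 * min(Pr(W' <= W), Pr(W' >= W)))`.
#' No large-sample approximation is ever substituted: above the enumeration
#' cap the test refuses.
#'
#' @param x a [paired_sample()], or a numeric vector of condition-A values.
#' @param y numeric vector of condition-B values when `x` is numeric.
#' @param max_n enumeration cap on the number of nonzero differences
#'   (default 20, i.e. about a million sign vectors).
#' @return a `wilcoxon_result` list with fields `w_statistic`, `p_two_sided`,
#'   `n_effective` and `method = "exact-enumeration"`.
#' @export
wilcoxon_signed_rank_exact <- function(x, y = NULL, max_n = 20) {
  if (inherits(x, "paired_sample")) {
    d <- x$values_a - x$values_b
  } else {
    stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
    d <- x - y
  }
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0) {
    stop_stage("wilcoxon", "degenerate sample: all differences are zero")
  }
  if (n > max_n) {
    stop_stage("wilcoxon",
               paste("n_effective = %d exceeds the exact-enumeration cap (%d);",
                     "reduce the sample or raise max_n"), n, max_n)
  }
  ranks <- rank(abs(d))
  w <- sum(ranks[d > 0])
  null <- signed_rank_null(ranks)
  w2 <- as.integer(round(2 * w))
  p_le <- sum(null[seq_len(w2 + 1)])
  p_ge <- sum(null[seq.int(w2 + 1, length(null))])
  p <- min(1, 2 * min(p_le, p_ge))
  structure(list(w_statistic = w, p_two_sided = p, n_effective = n,
                 method = "exact-enumeration"),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Exact Wilcoxon signed-rank test (%s)\n", x$method))
  cat(sprintf("  W = %g, n = %d, two-sided P = %s\n",
              x$w_statistic, x$n_effective, signif(x$p_two_sided, 3)))
  invisible(x)
}

#' Exact binomial two-tail probability for the family-resampling null
#'
#' Sampling `n_draw` families with replacement from a universe of
#' `universe_size` families of which `k_no_sb` lack swimbladders makes the
#' swimbladderless count X ~ Binomial(n_draw, k_no_sb / universe_size).  The
#' two-tail probability follows either the deviation rule — the total mass of
#' outcomes at least as far from E[X] as the observed count — or the
#' tail-doubling rule `min(1, 2 * min(Pr(X <= obs), Pr(X >= obs)))`.
#'
#' @param universe_size number of candidate families (> 0).
#' @param k_no_sb swimbladderless families in the universe.
#' @param n_draw families drawn per resample.
#' @param observed observed swimbladderless count, in `0:n_draw`.
#' @param two_tail `"deviation"` (default) or `"doubling"`.
#' @return a probability in [0, 1].
#' @export
exact_binomial_twotail <- function(universe_size, k_no_sb, n_draw, observed,
                                   two_tail = c("deviation", "doubling")) {
  two_tail <- match.arg(two_tail)
  if (universe_size <= 0) stop_stage("binom-tail", "universe_size must be > 0")
  stopifnot(k_no_sb >= 0, k_no_sb <= universe_size,
            observed >= 0, observed <= n_draw)
  prob <- k_no_sb / universe_size
  if (two_tail == "doubling") {
    p <- 2 * min(stats::pbinom(observed, n_draw, prob),
                 1 - stats::pbinom(observed - 1, n_draw, prob))
    return(min(1, p))
  }
  e <- n_draw * prob
  x <- 0:n_draw
  keep <- abs(x - e) >= abs(observed - e) - 1e-9
  sum(stats::dbinom(x[keep], n_draw, prob))
}

#' Observed sponging family statistic
#'
#' From pooled (family, mode) counts and the annotated universe, counts the
#' families actually extracted during sponging and how many of them lack
#' swimbladders — the observed statistic fed to the resampling test.  It is
#' always computed from data, never assumed.
#'
#' @param pooled data frame `family, mode, count` (see [pool_counts()]).
#' @param universe a [family_universe()].
#' @return list with `n_families` (families with nonzero sponging count) and
#'   `n_no_sb` (those lacking swimbladders).
#' @export
sponging_family_stat <- function(pooled, universe) {
  sp <- pooled[pooled$mode == "sponging" & pooled$count > 0, , drop = FALSE]
  fams <- unique(sp$family)
  unknown <- setdiff(fams, universe$family)
  if (length(unknown) > 0) {
    stop_stage("family-stat", "family not annotated in universe: %s",
               paste(unknown, collapse = ", "))
  }
  no_sb <- universe$family[!universe$has_swimbladder]
  list(n_families = length(fams), n_no_sb = sum(fams %in% no_sb))
}

#' Monte Carlo family-resampling test
#'
#' Draws `n_draw` families uniformly with replacement from the universe,
#' `reps` times, counts the swimbladderless families per draw, and estimates
#' the two-tailed probability of a count as extreme as the observed one.  The
#' default two-tail rule counts resamples whose deviation from the null
#' expectation `E[X] = n_draw * k / N` is at least the observed deviation;
#' tail-doubling is available as an alternative.  The analytic binomial tail
#' ([exact_binomial_twotail()]) is computed alongside as a cross-check.
#'
#' @param universe a [family_universe()]; its size and swimbladderless count
#'   define the null.
#' @param n_draw families drawn per resample (default 8, the number of
#'   families extracted during sponging).
#' @param observed_no_sb observed swimbladderless family count, `<= n_draw`.
#' @param reps number of resamples (default 10000).
#' @param seed integer RNG seed; results are reproducible bit-for-bit.
#' @param two_tail `"deviation"` (default) or `"doubling"`.
#' @return a `resampling_result` list echoing the configuration plus `p_mc`
#'   and `p_exact`.
#' @export
family_resampling_test <- function(universe, n_draw = 8, observed_no_sb,
                                   reps = 10000, seed = 1,
                                   two_tail = c("deviation", "doubling")) {
  two_tail <- match.arg(two_tail)
  if (reps <= 0) stop_stage("resampling", "reps must be positive")
  if (nrow(universe) == 0) stop_stage("resampling", "universe is empty")
  stopifnot(observed_no_sb >= 0, observed_no_sb <= n_draw)
  n_u <- nrow(universe)
  k <- sum(!universe$has_swimbladder)

  set.seed(as.integer(seed))
  draws <- matrix(sample.int(n_u, n_draw * reps, replace = TRUE),
                  nrow = n_draw)
  x <- colSums(matrix(!universe$has_swimbladder[draws], nrow = n_draw))

  e <- n_draw * k / n_u
  if (two_tail == "deviation") {
    p_mc <- mean(abs(x - e) >= abs(observed_no_sb - e) - 1e-9)
  } else {
    p_mc <- min(1, 2 * min(mean(x <= observed_no_sb),
                           mean(x >= observed_no_sb)))
  }
  p_exact <- exact_binomial_twotail(n_u, k, n_draw, observed_no_sb, two_tail)
  structure(list(p_mc = p_mc, p_exact = p_exact, reps = as.integer(reps),
                 n_draw = as.integer(n_draw),
                 observed_no_sb = as.integer(observed_no_sb),
                 universe_size = n_u, k_no_sb = k,
                 seed = as.integer(seed), two_tail = two_tail),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("Family-resampling test (with replacement)\n")
  cat(sprintf("  universe %d families (%d without swimbladder); drew %d, observed %d without\n",
              x$universe_size, x$k_no_sb, x$n_draw, x$observed_no_sb))
  cat(sprintf("  %d resamples (seed %d, %s rule): P = %s  [analytic binomial tail %s]\n",
              x$reps, x$seed, x$two_tail,
              signif(x$p_mc, 3), signif(x$p_exact, 3)))
  invisible(x)
}
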