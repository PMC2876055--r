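#' ROC-based estimate of the low-intensity filtration cutoff
#'
#' Reconstructs in spirit the multi-step filtration used on MAS-scaled
#' intensities: each probe is labelled "reproducible" when its
#' between-replicate log2 difference stays below a concordance bound in every
#' replicate pair, and the probe's maximum intensity over the replicate arrays
#' — the same statistic [filter_low_intensity()] thresholds — is scanned as a
#' single-value classifier of that label. The returned cutoff maximizes
#' Youden's J (sensitivity + specificity - 1) over candidate cutoffs taken
#' from observed intensity quantiles. The exact multi-step recipe of the
#' original screen is published only by citation, so this routine is a
#' documented reconstruction, not a line-by-line port.
#'
#' @param m Raw-scale `ExpressionMatrix`.
#' @param replicate_pairs List of length-2 integer vectors of column indices,
#'   each a pair of replicate arrays.
#' @param concordance_bound Max |log2 ratio| between replicates for a probe to
#'   count as reproducible (default `log2(1.5)`).
#' @param probs Quantile grid defining candidate cutoffs.
#' @return The selected intensity cutoff (smallest candidate on ties; the
#'   minimum candidate when the label is degenerate).
#' @export
estimate_intensity_cutoff <- function(m, replicate_pairs,
                                      concordance_bound = log2(1.5),
                                      probs = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "raw") stop("intensity filtration applies to raw intensities")
  if (length(replicate_pairs) < 1L) stop("at least one replicate pair is required")
  v <- m$values
  cols <- unique(unlist(replicate_pairs))
  intensity <- apply(v[, cols, drop = FALSE], 1L, max)
  repro <- rep(TRUE, nrow(v))
  for (pr in replicate_pairs) {
    if (length(pr) != 2L) stop("each replicate pair must have two columns")
    repro <- repro & abs(log2(v[, pr[1L]] / v[, pr[2L]])) <= concordance_bound
  }
  candidates <- sort(unique(stats::quantile(intensity, probs, names = FALSE)))
  if (all(repro) || all(!repro)) return(candidates[1L])
  j <- vapply(candidates, function(c0) {
    mean(intensity[repro] > c0) - mean(intensity[!repro] > c0)
  }, numeric(1L))
  candidates[which.max(j)]
}

#' Remove probes below the intensity cutoff
#'
#' A probe is retained when its intensity exceeds the cutoff in at least one
#' array of either condition.
#'
#' @param m Raw-scale `ExpressionMatrix`.
#' @param cutoff Intensity cutoff, typically from
#'   [estimate_intensity_cutoff()].
#' @return Filtered `ExpressionMatrix`; a message reports retained/removed
#'   counts.
#' @export
filter_low_intensity <- function(m, cutoff) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "raw") stop("intensity filtration applies to raw intensities")
  keep <- apply(m$values > cutoff, 1L, any)
  if (!any(keep)) stop("intensity cutoff removes every probe")
  message(sum(keep), " probe(s) retained, ", sum(!keep),
          " removed by intensity filtration")
  expression_matrix(m$values[keep, , drop = FALSE], "raw")
}

check_two_conditions <- function(m, condition_labels, condition, control) {
  if (length(condition_labels) != ncol(m$values))
    stop("condition_labels must have one entry per array")
  if (!all(condition_labels %in% c(condition, control)))
    stop("condition_labels contains labels other than the two conditions")
  list(cond = which(condition_labels == condition),
       ctrl = which(condition_labels == control))
}

#' Linear-scale fold changes between two conditions
#'
#' `fold = mean(condition arrays) / mean(control arrays)` per probe, on the
#' raw intensity scale.
#'
#' @param m Raw-scale `ExpressionMatrix`.
#' @param condition_labels Character vector, one label per array.
#' @param condition,control The two label values; folds are condition over
#'   control.
#' @return Named numeric vector of per-probe fold changes.
#' @export
fold_changes <- function(m, condition_labels, condition = "condition",
                         control = "control") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "raw") stop("fold changes are computed on raw intensities")
  idx <- check_two_conditions(m, condition_labels, condition, control)
  mc <- rowMeans(m$values[, idx$cond, drop = FALSE])
  m0 <- rowMeans(m$values[, idx$ctrl, drop = FALSE])
  if (any(m0 <= 0)) stop("control mean <= 0")
  stats::setNames(mc / m0, features(m))
}

#' SAM-style moderated d statistics
#'
#' Per probe, `d = (mean(condition) - mean(control)) / (s + s0)` on log2
#' intensities, where `s` is the pooled two-sample standard error and `s0` a
#' fudge factor stabilizing low-variance probes. The default policy sets `s0`
#' to the median of the `s_i` (a deliberate simplification of the
#' coefficient-of-variation minimization of the original procedure, which is
#' unstable with duplicated pooled arrays); pass a number or a function of the
#' `s_i` vector to override.
#'
#' @param m `ExpressionMatrix`; raw matrices are log2-transformed internally,
#'   normalized matrices are used as-is.
#' @param condition_labels,condition,control As in [fold_changes()].
#' @param s0_policy `"median"`, a non-negative number, or
#'   `function(s) -> s0`.
#' @return List with `d` (named vector), `s` (per-probe standard errors) and
#'   `s0`.
#' @export
sam_d_statistics <- function(m, condition_labels, condition = "condition",
                             control = "control", s0_policy = "median") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  idx <- check_two_conditions(m, condition_labels, condition, control)
  if (length(idx$cond) < 2L || length(idx$ctrl) < 2L)
    stop("each condition needs at least 2 arrays")
  x <- if (m$scale == "raw") log2(m$values) else m$values
  d_from_groups(x, idx$cond, idx$ctrl, s0_policy = s0_policy)
}

# d statistics for explicit column groups of a log2 matrix
d_from_groups <- function(x, g1, g2, s0 = NULL, s0_policy = "median") {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- rowMeans(x[, g1, drop = FALSE])
  m2 <- rowMeans(x[, g2, drop = FALSE])
  ss <- rowSums((x[, g1, drop = FALSE] - m1)^2) +
    rowSums((x[, g2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  if (is.null(s0)) {
    s0 <- if (is.function(s0_policy)) s0_policy(s)
    else if (identical(s0_policy, "median")) stats::median(s)
    else if (is.numeric(s0_policy) && length(s0_policy) == 1L && s0_policy >= 0)
      s0_policy
    else stop("invalid s0_policy")
  }
  list(d = (m1 - m2) / (s + s0), s = s, s0 = s0)
}

#' Permutation false-discovery table over a delta grid
#'
#' All distinct relabelings of the arrays into two groups of the observed
#' sizes are enumerated exhaustively (with duplicated 2+2 arrays that is 6
#' relabelings). The null reference is built from the relabelings that break
#' the observed contrast — the observed grouping and its complement are
#' enumerated but not used as null draws, since at such small designs they
#' would leak a third of any real signal into the null expectation. Observed
#' d statistics are sorted and compared to the quantile-matched expected
#' order statistics (mean of the sorted null-relabeling d). For each delta,
#' the first sorted position (on each side of the origin) whose deviation
#' from the expected order statistic reaches delta defines a cut point, and
#' every probe beyond a cut point is called — the classic SAM rule, which
#' keeps the call set contiguous in d. The expected number of false calls is
#' the mean over the null relabelings of the number of permuted d beyond the
#' same cut points (the original SAM formulation; with only four null
#' relabelings the median of small integer counts is zero-inflated and
#' degenerates at extreme deltas), and `fdr = min(1, expected_false /
#' called)`. The
#' selected delta minimizes the FDR among deltas calling at least one probe
#' (smallest delta on ties); deltas calling nothing report `fdr = 0` and are
#' excluded from the minimization. Under a complete null this minimization is
#' known to be optimistic (see the package vignette); with planted signal it
#' recovers the intended call set.
#'
#' @param sam Result of [sam_d_statistics()].
#' @param m,condition_labels,condition,control The inputs that produced `sam`.
#' @param delta_grid Optional increasing vector of deltas; by default 50
#'   deltas equally spaced over the observed deviation range.
#' @param n_delta Grid size when `delta_grid` is `NULL`.
#' @return Object of class `SamFdr`: list with `table`
#'   (delta/called/expected_false/fdr), `chosen_delta`, `fdr_at_chosen`,
#'   `called` (named logical, original probe order, at the chosen delta),
#'   `n_permutations`, `d_expected`.
#' @export
sam_permutation_fdr <- function(sam, m, condition_labels,
                                condition = "condition", control = "control",
                                delta_grid = NULL, n_delta = 50L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  idx <- check_two_conditions(m, condition_labels, condition, control)
  x <- if (m$scale == "raw") log2(m$values) else m$values
  n <- ncol(x)
  n1 <- length(idx$cond)
  sets <- utils::combn(n, n1)
  if (ncol(sets) < 2L) stop("fewer than 2 distinct relabelings")
  obs <- sort(idx$cond)
  comp <- sort(idx$ctrl)
  is_null_set <- apply(sets, 2L, function(g1)
    !identical(sort(g1), obs) && !identical(sort(g1), comp))
  if (!any(is_null_set)) stop("no contrast-breaking relabeling available")
  dperm <- apply(sets[, is_null_set, drop = FALSE], 2L, function(g1) {
    d_from_groups(x, g1, setdiff(seq_len(n), g1), s0 = sam$s0)$d
  })
  d_expected <- rowMeans(apply(dperm, 2L, sort))
  d_sorted <- unname(sort(sam$d))
  dev_obs <- d_sorted - d_expected
  i0 <- which.min(abs(d_expected))
  pos <- seq_along(d_sorted)
  cuts_at <- function(de) {
    up <- which(dev_obs >= de & pos >= i0)
    lo <- which(dev_obs <= -de & pos <= i0)
    c(lo = if (length(lo)) d_sorted[max(lo)] else -Inf,
      up = if (length(up)) d_sorted[min(up)] else Inf)
  }
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(dev_obs)), length.out = n_delta + 1L)[-1L]
  stats_at <- vapply(delta_grid, function(de) {
    cu <- cuts_at(de)
    c(called = sum(sam$d >= cu["up"] | sam$d <= cu["lo"]),
      expected_false = mean(colSums(dperm >= cu["up"] | dperm <= cu["lo"])))
  }, c(called = 0, expected_false = 0))
  called <- stats_at["called", ]
  expected_false <- stats_at["expected_false", ]
  fdr <- ifelse(called >= 1, pmin(1, expected_false / pmax(called, 1)), 0)
  tab <- data.frame(delta = delta_grid, called = as.integer(called),
                    expected_false = expected_false, fdr = fdr)
  eligible <- which(called >= 1)
  if (!length(eligible)) stop("no delta calls any probe")
  chosen <- eligible[which.min(fdr[eligible])]
  cu <- cuts_at(delta_grid[chosen])
  called_flag <- sam$d >= cu["up"] | sam$d <= cu["lo"]
  names(called_flag) <- names(sam$d)
  structure(list(table = tab,
                 chosen_delta = delta_grid[chosen],
                 fdr_at_chosen = fdr[chosen],
                 called = called_flag,
                 n_permutations = ncol(sets),
                 d_expected = d_expected,
                 s0 = sam$s0),
            class = "SamFdr")
}

#' @export
print.SamFdr <- function(x, ...) {
  cat(sprintf(
    "SAM permutation FDR: %d relabelings, delta = %.4g, %d called, est. FDR = %.3f\n",
    x$n_permutations, x$chosen_delta, sum(x$called), x$fdr_at_chosen))
  invisible(x)
}

#' Select the differential gene set
#'
#' A probe is significant when it passes the two-sided linear fold cutoff
#' (`>= fold_cutoff` up or `<= 1/fold_cutoff` down) AND is called by the SAM
#' band at the selected delta. Significant probes are collapsed to unique
#' gene symbols; unannotated significant probes are dropped.
#'
#' @param fold Per-probe folds from [fold_changes()].
#' @param sam_fdr A `SamFdr` from [sam_permutation_fdr()].
#' @param ann A [probe_annotation()].
#' @param d Optional per-probe d statistics to carry into the result table.
#' @param fold_cutoff Linear fold cutoff (default 2).
#' @return A `data.frame` of class `DifferentialResult` with columns
#'   `probe_id`, `gene_symbol`, `fold_change`, `d_stat`, `significant`, and
#'   attributes `genes` (unique significant symbols, empty with a warning when
#'   nothing passes), `chosen_delta`, `estimated_fdr`, `s0`.
#' @export
select_differential_genes <- function(fold, sam_fdr, ann, d = NULL,
                                      fold_cutoff = 2) {
  stopifnot(inherits(sam_fdr, "SamFdr"), inherits(ann, "ProbeAnnotation"))
  probes <- names(fold)
  if (is.null(probes) || !identical(probes, names(sam_fdr$called)))
    stop("fold changes and SAM calls must be aligned on the same probes")
  pass_fold <- fold >= fold_cutoff | fold <= 1 / fold_cutoff
  sig <- pass_fold & sam_fdr$called
  sym <- ann$gene_symbol[match(probes, ann$probe_id)]
  res <- data.frame(probe_id = probes,
                    gene_symbol = ifelse(is.na(sym), "", sym),
                    fold_change = unname(fold),
                    d_stat = if (is.null(d)) NA_real_ else unname(d),
                    significant = unname(sig))
  genes <- sort(unique(sym[sig & !is.na(sym)]))
  if (!length(genes))
    warning("no gene passes both the fold cutoff and the SAM call")
  attr(res, "genes") <- genes
  attr(res, "chosen_delta") <- sam_fdr$chosen_delta
  attr(res, "estimated_fdr") <- sam_fdr$fdr_at_chosen
  attr(res, "s0") <- sam_fdr$s0
  class(res) <- c("DifferentialResult", "data.frame")
  res
}
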