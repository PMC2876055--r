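test_that("ROC cutoff separates a known background/signal intensity mixture", {
  set.seed(17)
  n_bg <- 500; n_sig <- 1500
  bg_base <- rnorm(n_bg, 100, 10)
  sig_base <- rnorm(n_sig, 1000, 100)
  arrays <- vapply(1:4, function(i) {
    c(pmax(bg_base, 1) * 2^rnorm(n_bg, 0, 1),        # discordant replicates
      pmax(sig_base, 1) * 2^rnorm(n_sig, 0, 0.1))    # concordant replicates
  }, numeric(n_bg + n_sig))
  rownames(arrays) <- sprintf("P%04d", seq_len(n_bg + n_sig))
  colnames(arrays) <- c("c1", "c2", "t1", "t2")
  m <- expression_matrix(arrays, "raw")
  pairs <- list(c(1, 2), c(3, 4))
  cutoff <- estimate_intensity_cutoff(m, pairs)
  expect_gt(cutoff, 150)
  expect_lt(cutoff, 800)
  f <- suppressMessages(filter_low_intensity(m, cutoff))
  bg_ids <- rownames(arrays)[seq_len(n_bg)]
  expect_lt(mean(bg_ids %in% features(f)), 0.05)      # background mostly gone
  expect_gt(mean(setdiff(rownames(arrays), bg_ids) %in% features(f)), 0.95)
})

test_that("degenerate cutoff scans behave as documented", {
  v <- matrix(rep(c(100, 1000), each = 4), 2, 4, byrow = TRUE,
              dimnames = list(c("P1", "P2"), letters[1:4]))
  m <- expression_matrix(v, "raw")  # identical replicates: all reproducible
  pairs <- list(c(1, 2), c(3, 4))
  cand <- sort(unique(quantile(apply(v, 1, max), seq(0.01, 0.99, 0.01),
                               names = FALSE)))
  expect_equal(estimate_intensity_cutoff(m, pairs), cand[1])
  # single-candidate grid is returned as-is
  expect_equal(estimate_intensity_cutoff(m, pairs, probs = 0.5),
               unname(quantile(apply(v, 1, max), 0.5)))
  expect_error(estimate_intensity_cutoff(m, list()), "replicate pair")
})

test_that("intensity filter keeps any-array exceedances and logs counts", {
  v <- matrix(c(10, 10, 10, 10,
                10, 500, 10, 10,
                500, 500, 500, 500), 3, 4, byrow = TRUE,
              dimnames = list(c("low", "one_array", "high"), letters[1:4]))
  m <- expression_matrix(v, "raw")
  expect_message(f <- filter_low_intensity(m, 100), "2 probe\\(s\\) retained")
  expect_setequal(features(f), c("one_array", "high"))
  expect_error(filter_low_intensity(m, 1e6), "every probe")
})

test_that("fold changes are ratios of linear-scale condition means", {
  m <- toy_matrix(matrix(c(2, 2, 4, 4,
                           2, 2, 3, 3,
                           2, 2, 2, 8), 3, 4, byrow = TRUE))
  lab <- c("control", "control", "condition", "condition")
  fold <- fold_changes(m, lab)
  expect_equal(unname(fold), c(2, 1.5, 2.5))
})

test_that("SAM d statistics follow the moderated formula", {
  # explicit 4-array case checked against the formula computed by hand
  x <- matrix(c(5.0, 5.2, 6.1, 6.5,
                3.0, 3.0, 3.0, 3.0,
                4.0, 4.4, 4.1, 4.3), 3, 4, byrow = TRUE,
              dimnames = list(c("up", "flat", "mild"),
                              c("c1", "c2", "t1", "t2")))
  m <- expression_matrix(2^x, "raw")
  lab <- c("control", "control", "condition", "condition")
  sam <- sam_d_statistics(m, lab, s0_policy = 0.1)
  hand_s <- function(g1, g2) {
    sqrt((1 / 2 + 1 / 2) * (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / 2)
  }
  for (i in 1:3) {
    g_ctrl <- x[i, 1:2]; g_cond <- x[i, 3:4]
    d_hand <- (mean(g_cond) - mean(g_ctrl)) / (hand_s(g_cond, g_ctrl) + 0.1)
    expect_equal(unname(sam$d[i]), d_hand, tolerance = 1e-12)
  }
  expect_equal(unname(sam$d["flat"]), 0)

  # s0 -> infinity drives every d to zero
  sam_inf <- sam_d_statistics(m, lab, s0_policy = 1e9)
  expect_lt(max(abs(sam_inf$d)), 1e-8)

  # antisymmetry under swapping the condition labels
  sam_swap <- sam_d_statistics(m, lab, condition = "control",
                               control = "condition", s0_policy = 0.1)
  expect_equal(sam_swap$d, -sam$d)

  expect_error(sam_d_statistics(toy_matrix(matrix(1:4 * 1.0, 2, 2)),
                                c("control", "condition")),
               "at least 2 arrays")
})

test_that("permutation FDR enumerates 2+2 relabelings exhaustively", {
  set.seed(23)
  m <- toy_matrix(matrix(2^rnorm(400 * 4, 8, 0.5), 400, 4))
  lab <- c("control", "control", "condition", "condition")
  sam <- sam_d_statistics(m, lab)
  fdr <- sam_permutation_fdr(sam, m, lab)
  expect_identical(fdr$n_permutations, 6L)         # choose(4, 2)
  tab <- fdr$table
  expect_true(all(diff(tab$called) <= 0))          # monotone in delta
  expect_true(all(tab$fdr[tab$called == 0] == 0))  # empty calls report 0
  expect_gte(sum(fdr$called), 1)
  expect_true(all(tab$fdr >= 0 & tab$fdr <= 1))
  # the call set is contiguous in d: everything beyond the weakest call
  called_d <- sam$d[fdr$called]
  if (any(fdr$called) && any(!fdr$called)) {
    up <- called_d[called_d > 0]
    if (length(up))
      expect_true(all(sam$d[!fdr$called] < min(up) | sam$d[!fdr$called] < 0))
  }
})

test_that("null tail counts are exchangeable with the relabeling counts", {
  # under a complete null the observed labeling and the contrast-breaking
  # relabelings are exchangeable, so at any FIXED |d| threshold the observed
  # tail count and the mean relabeled tail count agree in expectation; their
  # mean difference over replicates must sit within Monte-Carlo error
  set.seed(29)
  lab <- rep(c("control", "condition"), each = 2)
  # the two relabelings that mix one array of each condition into each group
  mix1 <- c("control", "condition", "control", "condition")
  mix2 <- c("control", "condition", "condition", "control")
  thresholds <- c(1, 1.5, 2)
  diffs <- matrix(0, 60, length(thresholds))
  for (r in 1:60) {
    m <- expression_matrix(
      matrix(2^rnorm(2000, 8, 0.5), 500, 4,
             dimnames = list(sprintf("P%03d", 1:500),
                             c("c1", "c2", "t1", "t2"))), "raw")
    sam <- sam_d_statistics(m, lab)
    perm_d <- cbind(
      sam_d_statistics(m, mix1, s0_policy = sam$s0)$d,
      sam_d_statistics(m, mix2, s0_policy = sam$s0)$d)
    for (j in seq_along(thresholds)) {
      diffs[r, j] <- sum(abs(sam$d) >= thresholds[j]) -
        mean(colSums(abs(perm_d) >= thresholds[j]))
    }
  }
  for (j in seq_along(thresholds)) {
    se <- sd(diffs[, j]) / sqrt(nrow(diffs))
    expect_lt(abs(mean(diffs[, j])), 4 * se + 0.5)
  }
})

test_that("differential selection is the fold/SAM conjunction collapsed to genes", {
  s <- simulate_cell_line_arrays(cell_line_sim_config(seed = 1))
  f <- suppressMessages(filter_low_intensity(
    s$expr, estimate_intensity_cutoff(s$expr, s$replicate_pairs)))
  fold <- fold_changes(f, s$condition_labels)
  sam <- sam_d_statistics(f, s$condition_labels)
  fdr <- sam_permutation_fdr(sam, f, s$condition_labels)
  res <- select_differential_genes(fold, fdr, s$annotation, d = sam$d)

  sig <- res$significant
  expect_true(all((fold[sig] >= 2 | fold[sig] <= 0.5)))
  expect_true(all(fdr$called[sig]))
  # probes passing fold but not the SAM band are excluded
  fold_only <- (fold >= 2 | fold <= 0.5) & !fdr$called
  if (any(fold_only)) expect_false(any(res$significant[fold_only]))

  genes <- attr(res, "genes")
  truthg <- c(s$truth$planted_genes_up, s$truth$planted_genes_down)
  expect_gte(mean(truthg %in% genes), 0.9)   # recall on planted ground truth
  expect_gte(mean(genes %in% truthg), 0.8)   # precision
})

test_that("probes of one gene collapse to a single selected symbol", {
  s <- simulate_cell_line_arrays(cell_line_sim_config(
    n_probes = 60, n_planted_up = 6, n_planted_down = 0,
    n_background_probes = 0, seed = 4))
  # annotate the six planted probes onto just three genes
  ann <- probe_annotation(
    s$annotation$probe_id,
    c(rep(c("GA", "GB", "GC"), 2), s$annotation$gene_symbol[-(1:6)]))
  fold <- fold_changes(s$expr, s$condition_labels)
  sam <- sam_d_statistics(s$expr, s$condition_labels)
  fdr <- sam_permutation_fdr(sam, s$expr, s$condition_labels)
  res <- select_differential_genes(fold, fdr, ann, d = sam$d)
  called_planted <- res$significant[1:6]
  genes <- attr(res, "genes")
  expect_lte(sum(genes %in% c("GA", "GB", "GC")), 3)
  expect_false(anyDuplicated(genes) > 0)
})
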