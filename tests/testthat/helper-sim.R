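# Small fixture builders shared across test files.

toy_matrix <- function(values, features = NULL, samples = NULL,
                       scale = "raw") {
  v <- as.matrix(values)
  if (is.null(features))
    features <- if (!is.null(rownames(v))) rownames(v)
    else sprintf("F%02d", seq_len(nrow(v)))
  if (is.null(samples))
    samples <- if (!is.null(colnames(v))) colnames(v)
    else sprintf("S%02d", seq_len(ncol(v)))
  dimnames(v) <- list(features, samples)
  expression_matrix(v, scale)
}

# a hand-built 2-cluster partition without running k-means
toy_partition <- function(cluster, expressor = 1L) {
  structure(list(cluster = cluster, expressor = expressor, k = 2L,
                 inertia = NA_real_, n_restarts = 0L,
                 sizes = as.vector(table(cluster))),
            class = "PatientPartition")
}

# gene vector over 10+10 patients with exactly `lost` of the 100
# between-cluster pairs inverted: AUC = (100 - lost) / 100
auc_controlled_gene <- function(lost) {
  stopifnot(lost >= 0, lost <= 9)
  neg <- c(1:9, 10.5 + lost)   # the last negative overtakes `lost` positives
  pos <- 11:20
  c(pos, neg)
}

toy_clinical <- function(n, times, events, t_stage = "T1", n_stage = "N0",
                         grade = "2", ids = sprintf("PT%03d", seq_len(n))) {
  clinical_table(data.frame(
    patient_id = ids,
    time_months = times, event = events,
    t_stage = t_stage, n_stage = n_stage, grade = grade,
    stringsAsFactors = FALSE))
}

# exhaustive two-group log-rank permutation distribution (small n only)
logrank_permutation_p <- function(times, events, groups) {
  g1_size <- sum(groups == unique(groups)[1])
  obs <- logrank_test(times, events, groups)$chi_square
  sets <- utils::combn(length(times), g1_size)
  chis <- apply(sets, 2L, function(idx) {
    g <- rep("b", length(times)); g[idx] <- "a"
    logrank_test(times, events, g)$chi_square
  })
  mean(chis >= obs - 1e-12)
}
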