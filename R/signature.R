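#' Eliminate genes with uniform expression across patients
#'
#' Genes whose interquartile range across patients falls below
#' `spread_threshold` carry no stratifying information and are removed before
#' clustering (in the original derivation this dropped 87 of 254 genes).
#'
#' @param m Normalized-scale `ExpressionMatrix` (genes x patients).
#' @param spread_threshold Minimum IQR in log2 units (default 0.5).
#' @return Filtered `ExpressionMatrix`; a message reports the count removed.
#' @export
remove_uniform_genes <- function(m, spread_threshold = 0.5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "normalized")
    stop("uniform-gene elimination expects a normalized matrix")
  iqr <- apply(m$values, 1L, stats::IQR)
  keep <- iqr >= spread_threshold
  if (!any(keep)) stop("spread threshold removes every gene")
  message(sum(!keep), " uniform gene(s) removed, ", sum(keep), " retained")
  expression_matrix(m$values[keep, , drop = FALSE], "normalized")
}

#' Partition patients by k-means in gene space
#'
#' Squared-Euclidean k-means on patients using the normalized values of the
#' supplied genes, best of `n_restarts` random starts, deterministic under
#' `seed`. The cluster with the higher mean expression over the candidate
#' genes is flagged as the expressor candidate. Outcome data never enter this
#' step: the partition is derived from expression alone.
#'
#' @param m Normalized-scale `ExpressionMatrix`.
#' @param genes Genes to cluster on (default: all rows of `m`).
#' @param k Number of clusters (default 2).
#' @param n_restarts Random restarts (default 50).
#' @param seed Integer seed for reproducible restarts.
#' @return Object of class `PatientPartition`: list with `cluster` (named
#'   integer vector in `1:k`), `expressor` (the expressor-candidate cluster
#'   id), `k`, `inertia` (total within-cluster sum of squares), `n_restarts`,
#'   `sizes`.
#' @export
kmeans_partition <- function(m, genes = NULL, k = 2L, n_restarts = 50L,
                             seed = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(genes)) genes <- features(m)
  missing_genes <- setdiff(genes, features(m))
  if (length(missing_genes))
    stop("genes not in matrix: ", paste(utils::head(missing_genes, 5), collapse = ", "))
  x <- t(m$values[genes, , drop = FALSE])
  if (k > nrow(x)) stop("k exceeds the number of patients")
  km <- with_seed(seed,
    suppressWarnings(stats::kmeans(x, centers = k, nstart = n_restarts,
                                   iter.max = 100L)))
  cl <- stats::setNames(km$cluster, rownames(x))
  mean_by_cluster <- vapply(seq_len(k), function(i) mean(x[cl == i, ]), numeric(1L))
  structure(list(cluster = cl,
                 expressor = which.max(mean_by_cluster),
                 k = k,
                 inertia = km$tot.withinss,
                 n_restarts = n_restarts,
                 sizes = km$size),
            class = "PatientPartition")
}

#' @export
print.PatientPartition <- function(x, ...) {
  cat(sprintf("PatientPartition: k = %d, sizes = %s, expressor candidate = cluster %d\n",
              x$k, paste(x$sizes, collapse = "/"), x$expressor))
  invisible(x)
}

#' F-test-guided t-test selection of cluster-discriminant genes
#'
#' Per gene, a variance-ratio F test between the two patient clusters decides
#' which two-sample t statistic to use (unequal-variance when the F test
#' rejects at 0.05, pooled otherwise); genes whose two-sided t p-value falls
#' below `alpha` are selected. No multiple-testing correction is applied by
#' default, replicating the original derivation; set `bh_correct = TRUE` to
#' select on Benjamini-Hochberg adjusted p-values instead.
#'
#' @param m Normalized-scale `ExpressionMatrix`.
#' @param partition A 2-cluster [kmeans_partition()].
#' @param alpha Per-test significance level (default 0.05).
#' @param bh_correct Apply Benjamini-Hochberg before thresholding (default
#'   `FALSE`).
#' @return A `data.frame` of class `GeneSelection`: per gene `f_p`, `t_p`,
#'   `t_variant` (`"pooled"` / `"unequal_variance"`), `selected`.
#' @export
select_discriminant_genes <- function(m, partition, alpha = 0.05,
                                      bh_correct = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(partition, "PatientPartition"))
  if (partition$k != 2L) stop("gene selection expects a 2-cluster partition")
  cl <- partition$cluster[samples(m)]
  if (anyNA(cl)) stop("partition does not cover all patients in the matrix")
  if (min(table(cl)) < 2L) stop("each cluster needs at least 2 patients")
  in1 <- cl == partition$expressor
  res <- t(apply(m$values, 1L, function(v) {
    f_p <- stats::var.test(v[in1], v[!in1])$p.value
    if (is.na(f_p)) f_p <- 1  # zero variance in both groups
    equal_var <- f_p >= 0.05
    t_p <- tryCatch(
      stats::t.test(v[in1], v[!in1], var.equal = equal_var)$p.value,
      error = function(e) 1)  # constant data: t undefined, never selected
    c(f_p = f_p, t_p = t_p, pooled = as.numeric(equal_var))
  }))
  out <- data.frame(gene = features(m),
                    f_p = res[, "f_p"],
                    t_p = res[, "t_p"],
                    t_variant = ifelse(res[, "pooled"] == 1, "pooled",
                                       "unequal_variance"),
                    row.names = NULL)
  p_sel <- if (bh_correct) stats::p.adjust(out$t_p, "BH") else out$t_p
  out$selected <- p_sel < alpha
  class(out) <- c("GeneSelection", "data.frame")
  out
}

#' Empirical AUC of a single gene as a cluster classifier
#'
#' The probability that a randomly drawn expressor-cluster patient has a
#' higher value than a randomly drawn non-expressor patient, with half credit
#' for ties, computed by explicit enumeration of all between-cluster pairs.
#' This is the empirical (Mann-Whitney) AUC; the proper-binormal fit used by
#' the legacy PROPROC program is deliberately not reproduced — for
#' well-separated genes at cohort sample sizes the two agree closely.
#'
#' @param values Named numeric vector of one gene's normalized values, or a
#'   plain vector aligned with `positive`.
#' @param positive Logical vector: `TRUE` for expressor-cluster patients.
#' @return The oriented AUC in `[0, 1]` (orientation: positive class =
#'   expressor cluster; values below 0.5 mean the gene is lower in
#'   expressors).
#' @export
gene_auc <- function(values, positive) {
  if (length(values) != length(positive))
    stop("values and positive must have equal length")
  pos <- values[positive]
  neg <- values[!positive]
  if (!length(pos) || !length(neg)) stop("both clusters must be non-empty")
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

#' Signature selection by AUC cutoff
#'
#' Builds the signature from the discriminant genes: each gene's empirical
#' AUC against the expressor cluster is oriented by the gene's direction (up
#' when its mean is higher in the expressor cluster, in which case the
#' oriented AUC is the raw AUC; down genes are flipped), and genes with
#' oriented AUC strictly above `auc_cutoff` are kept, ordered by AUC
#' descending with alphabetical tie-break.
#'
#' @param m Normalized-scale `ExpressionMatrix`.
#' @param partition A 2-cluster [kmeans_partition()].
#' @param genes Candidate genes (typically the selected genes of
#'   [select_discriminant_genes()]).
#' @param auc_cutoff Strict lower AUC bound (default 0.95).
#' @param auc_fun AUC routine, `function(values, positive) -> auc`
#'   (pluggable; default [gene_auc()]).
#' @return Object of class `SignatureSet`: data frame with `gene_symbol`,
#'   `auc` (oriented), `direction` (`"up"`/`"down"`), and attributes
#'   `auc_cutoff`, `k`. Empty (with a warning) when no gene passes.
#' @export
select_signature <- function(m, partition, genes, auc_cutoff = 0.95,
                             auc_fun = gene_auc) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(partition, "PatientPartition"))
  cl <- partition$cluster[samples(m)]
  positive <- cl == partition$expressor
  missing_genes <- setdiff(genes, features(m))
  if (length(missing_genes))
    stop("genes not in matrix: ", paste(utils::head(missing_genes, 5), collapse = ", "))
  rec <- lapply(genes, function(g) {
    v <- m$values[g, ]
    raw_auc <- auc_fun(v, positive)
    up <- mean(v[positive]) >= mean(v[!positive])
    data.frame(gene_symbol = g,
               auc = if (up) raw_auc else 1 - raw_auc,
               direction = if (up) "up" else "down")
  })
  rec <- do.call(rbind, rec)
  keep <- !is.null(rec) && nrow(rec) > 0
  sig <- rec[rec$auc > auc_cutoff, , drop = FALSE]
  if (nrow(sig) == 0L)
    warning("no gene exceeds the AUC cutoff; signature is empty")
  sig <- sig[order(-sig$auc, sig$gene_symbol), , drop = FALSE]
  rownames(sig) <- NULL
  signature_set(sig, auc_cutoff = auc_cutoff, k = partition$k)
}

#' Signature container
#'
#' @param df Data frame with columns `gene_symbol`, `auc`, `direction`.
#' @param auc_cutoff,k,alpha Derivation metadata stored as attributes.
#' @return A `SignatureSet`.
#' @export
signature_set <- function(df, auc_cutoff = NA_real_, k = NA_integer_,
                          alpha = NA_real_) {
  stopifnot(all(c("gene_symbol", "auc", "direction") %in% names(df)))
  if (any(df$auc < 0 | df$auc > 1)) stop("auc must lie in [0, 1]")
  if (!all(df$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  structure(as.data.frame(df),
            auc_cutoff = auc_cutoff, k = k, alpha = alpha,
            class = c("SignatureSet", "data.frame"))
}

#' Read / write a signature file
#'
#' Tab-separated `gene_symbol`, `auc`, `direction` with a leading `#` comment
#' line carrying the derivation metadata.
#'
#' @param sig A `SignatureSet`.
#' @param path File path.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "SignatureSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# auc_cutoff=%s k=%s alpha=%s",
                     attr(sig, "auc_cutoff"), attr(sig, "k"),
                     attr(sig, "alpha")), con)
  utils::write.table(as.data.frame(sig), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- c(auc_cutoff = NA_real_, k = NA_real_, alpha = NA_real_)
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1L]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1L]]
      meta[parts[1L]] <- suppressWarnings(as.numeric(parts[2L]))
    }
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  signature_set(df, auc_cutoff = meta[["auc_cutoff"]], k = meta[["k"]],
                alpha = meta[["alpha"]])
}

#' Score patients against a signature
#'
#' Per patient, the relative expression score is the mean of the available
#' signature genes' normalized log2 values, with down-direction genes
#' sign-flipped before averaging; a strictly positive score classifies the
#' patient as an expressor (`MAPS_pos`). Signature genes absent from the
#' matrix are skipped and `n_genes_used` records how many entered the mean.
#'
#' @param m Normalized-scale `ExpressionMatrix`.
#' @param sig A `SignatureSet` with at least one gene present in `m`.
#' @return A `data.frame` of class `ScoreTable`: `patient_id`, `score`,
#'   `class` (`"MAPS_pos"`/`"MAPS_neg"`), `n_genes_used`.
#' @export
maps_score <- function(m, sig) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(sig, "SignatureSet"))
  if (m$scale != "normalized")
    stop("scoring expects a normalized matrix")
  present <- sig$gene_symbol %in% features(m)
  if (!any(present)) stop("no signature gene present in the matrix")
  genes <- sig$gene_symbol[present]
  signs <- ifelse(sig$direction[present] == "up", 1, -1)
  v <- m$values[genes, , drop = FALSE] * signs
  score <- colMeans(v)
  res <- data.frame(patient_id = samples(m),
                    score = unname(score),
                    class = ifelse(score > 0, "MAPS_pos", "MAPS_neg"),
                    n_genes_used = length(genes))
  class(res) <- c("ScoreTable", "data.frame")
  res
}

#' Ward ordering of genes for heatmap display
#'
#' Hierarchical clustering (Ward linkage on Euclidean distances) used purely
#' to order rows in exported tables and heatmaps; it gates no selection step.
#'
#' @param m Normalized-scale `ExpressionMatrix`.
#' @return Character vector of gene ids in dendrogram order.
#' @export
ward_gene_order <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (nrow(m$values) < 3L) return(features(m))
  hc <- stats::hclust(stats::dist(m$values), method = "ward.D2")
  features(m)[hc$order]
}
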