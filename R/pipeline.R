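#' Pipeline configuration
#'
#' Collects every input and tunable of the end-to-end derivation. Inputs may
#' be given as file paths (read with the package readers) or as the in-memory
#' objects the readers produce.
#'
#' @param cell_expr Raw cell-line matrix (`ExpressionMatrix` or path).
#' @param cell_condition_labels Per-array condition labels
#'   (`"condition"`/`"control"`).
#' @param replicate_pairs Within-condition replicate column pairs for the
#'   intensity filtration.
#' @param cohort_expr Raw cohort matrix (`ExpressionMatrix` or path).
#' @param clinical `ClinicalTable` or CSV path.
#' @param annotation `ProbeAnnotation` or 2-column TSV path
#'   (probe_id, gene_symbol).
#' @param out_dir Optional output directory; when set, every stage writes its
#'   table there under fixed names.
#' @param fold_cutoff,alpha,auc_cutoff,k,spread_threshold,n_restarts Tunables
#'   (defaults: 2.0-fold, 0.05, 0.95, 2 clusters, 0.5 log2 IQR, 50 restarts).
#' @param seed Integer seed controlling every stochastic step.
#' @param use_bh_correction,tie_method,concordance_bound,use_all_genes_for_kmeans
#'   Flags: Benjamini-Hochberg in the t-test stage (off replicates the
#'   original), Cox tie handling, replicate concordance bound of the
#'   filtration, and whether k-means uses all differential genes rather than
#'   the post-elimination set.
#' @param subgroups Optional normalization subgroups for the cohort.
#' @return A `PipelineConfig` list.
#' @export
maps_config <- function(cell_expr = NULL, cell_condition_labels = NULL,
                        replicate_pairs = NULL,
                        cohort_expr = NULL, clinical = NULL, annotation = NULL,
                        out_dir = NULL,
                        fold_cutoff = 2, alpha = 0.05, auc_cutoff = 0.95,
                        k = 2L, spread_threshold = 0.5, n_restarts = 50L,
                        seed = 1L,
                        use_bh_correction = FALSE,
                        tie_method = "efron",
                        concordance_bound = log2(1.5),
                        use_all_genes_for_kmeans = FALSE,
                        subgroups = NULL) {
  cfg <- as.list(environment())
  stopifnot(fold_cutoff > 1, alpha > 0, alpha < 1,
            auc_cutoff >= 0.5, auc_cutoff < 1, k >= 2,
            spread_threshold >= 0, n_restarts >= 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), f)
  unname(tools::md5sum(f))
}

load_expr <- function(x, scale) {
  if (inherits(x, "ExpressionMatrix")) x else read_expression_matrix(x, scale)
}

load_clinical <- function(x) {
  if (inherits(x, "ClinicalTable")) x else read_clinical_table(x)
}

load_annotation <- function(x) {
  if (inherits(x, "ProbeAnnotation")) return(x)
  df <- utils::read.table(x, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  probe_annotation(df[[1L]], df[[2L]])
}

write_with_header <- function(df, path, hash, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Survival evaluation of a scored cohort
#'
#' Kaplan-Meier per class, log-rank between classes, and univariate plus
#' multivariate Cox models of the binary clinical covariates and the
#' expressor class. This is the only stage that reads survival columns.
#'
#' @param scores A `ScoreTable`.
#' @param clinical A `ClinicalTable` covering the scored patients.
#' @param tie_method Cox tie handling.
#' @return List with `km` (per-class [km_fit()]s), `five_year` (survival at
#'   60 months per class), `logrank`, `cox_univariate` (list of `CoxFit`),
#'   `cox_multivariate` (`CoxFit` or NULL when a covariate is degenerate),
#'   `cox_table` (layout: variable, comparison, univariate p, multivariate p,
#'   multivariate HR).
#' @export
evaluate_survival <- function(scores, clinical, tie_method = "efron") {
  stopifnot(inherits(scores, "ScoreTable"), inherits(clinical, "ClinicalTable"))
  idx <- match(scores$patient_id, clinical$patient_id)
  if (anyNA(idx)) stop("clinical table does not cover all scored patients")
  clin <- clinical[idx, ]
  maps_pos <- as.integer(scores$class == "MAPS_pos")
  km <- lapply(split(seq_along(idx), scores$class),
               function(i) km_fit(clin$time_months[i], clin$event[i]))
  five_year <- vapply(km, function(f)
    suppressWarnings(survival_at(f, 60)), numeric(1L))
  lr <- logrank_test(clin$time_months, clin$event, scores$class)

  bin <- encode_clinical_binary(clin)
  covs <- list(t_high = bin$t_high, n_pos = bin$n_pos,
               grade_high = bin$grade_high, maps = maps_pos)
  comparisons <- c(t_high = "T1-T2 vs T3-T4",
                   n_pos = "N0 vs N1-N2",
                   grade_high = "grade 1 vs 2-3",
                   maps = "MAPS- vs MAPS+")
  fit1 <- function(v) {
    tryCatch(suppressMessages(
      cox_fit(clin$time_months, clin$event, data.frame(x = v),
              ties = tie_method)),
      error = function(e) NULL)
  }
  uni <- lapply(covs, fit1)
  multi <- tryCatch(suppressMessages(
    cox_fit(clin$time_months, clin$event, as.data.frame(covs),
            ties = tie_method)),
    error = function(e) NULL)
  tab <- data.frame(
    variable = names(covs),
    comparison = unname(comparisons[names(covs)]),
    p_univariate = vapply(uni, function(f)
      if (is.null(f)) NA_real_ else f$coefficients$p[1L], numeric(1L)),
    p_multivariate = if (is.null(multi)) NA_real_ else multi$coefficients$p,
    hr_multivariate = if (is.null(multi)) NA_real_ else multi$coefficients$hr)
  list(km = km, five_year = five_year, logrank = lr,
       cox_univariate = uni, cox_multivariate = multi, cox_table = tab)
}

#' Run the full signature derivation
#'
#' Executes the whole chain: intensity filtration and SAM selection on the
#' two-condition arrays; cohort median normalization, probe averaging and
#' restriction to the differential genes; uniform-gene elimination; k-means
#' patient partition; F-test-guided t-test selection; AUC ranking and
#' signature selection; scoring; survival evaluation. Counts are collected
#' into a run report whose reduction chain is asserted non-increasing. No
#' stage before the survival evaluation reads outcome columns.
#'
#' @param config A [maps_config()] with all inputs set.
#' @return List with `signature`, `report` (a `RunReport`), `differential`,
#'   `partition`, `selection`, `scores`, `survival` (see
#'   [evaluate_survival()]).
#' @export
run_derivation <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  hash <- config_hash(config)
  cell <- load_expr(config$cell_expr, "raw")
  cohort <- load_expr(config$cohort_expr, "raw")
  clinical <- load_clinical(config$clinical)
  ann <- load_annotation(config$annotation)

  # -- cell-line contrast ---------------------------------------------------
  cutoff <- estimate_intensity_cutoff(cell, config$replicate_pairs,
                                      concordance_bound = config$concordance_bound)
  filtered <- suppressMessages(filter_low_intensity(cell, cutoff))
  fold <- fold_changes(filtered, config$cell_condition_labels)
  sam <- sam_d_statistics(filtered, config$cell_condition_labels)
  fdr <- sam_permutation_fdr(sam, filtered, config$cell_condition_labels)
  differential <- select_differential_genes(fold, fdr, ann, d = sam$d,
                                            fold_cutoff = config$fold_cutoff)
  diff_genes <- attr(differential, "genes")
  if (!length(diff_genes))
    stop("diffexpr stage produced no genes; derivation halted")

  # -- cohort, outcome-blind ------------------------------------------------
  norm <- cohort_median_normalize(cohort, config$subgroups)
  gene_level <- if (any(features(norm) %in% ann$probe_id))
    suppressMessages(collapse_probes_to_genes(norm, ann)) else norm
  avail <- intersect(diff_genes, features(gene_level))
  if (!length(avail))
    stop("no differential gene is present on the cohort matrix")
  cohort_diff <- expression_matrix(
    gene_level$values[avail, , drop = FALSE], "normalized")
  kept <- suppressMessages(
    remove_uniform_genes(cohort_diff, config$spread_threshold))
  cluster_genes <- if (config$use_all_genes_for_kmeans) features(cohort_diff)
  else features(kept)
  cluster_matrix <- if (config$use_all_genes_for_kmeans) cohort_diff else kept
  partition <- kmeans_partition(cluster_matrix, cluster_genes, k = config$k,
                                n_restarts = config$n_restarts,
                                seed = config$seed)
  selection <- select_discriminant_genes(kept, partition,
                                         alpha = config$alpha,
                                         bh_correct = config$use_bh_correction)
  candidates <- selection$gene[selection$selected]
  signature <- suppressWarnings(
    select_signature(kept, partition, candidates,
                     auc_cutoff = config$auc_cutoff))
  attr(signature, "alpha") <- config$alpha

  report_counts <- c(n_probes_input = nrow(cell$values),
                     n_probes_after_filtration = nrow(filtered$values),
                     n_differential_genes = length(diff_genes),
                     n_after_uniform_removal = nrow(kept$values),
                     n_discriminant_genes = length(candidates),
                     n_signature_genes = nrow(signature))
  chain <- report_counts[3:6]
  if (any(diff(chain) > 0))
    stop("gene-count reduction chain is not non-increasing")

  if (nrow(signature) == 0L) {
    report <- structure(list(counts = report_counts,
                             partition_sizes = partition$sizes,
                             five_year = NULL, logrank_p = NA_real_,
                             cox_table = NULL, intensity_cutoff = cutoff,
                             chosen_delta = attr(differential, "chosen_delta"),
                             estimated_fdr = attr(differential, "estimated_fdr"),
                             seed = config$seed, config_hash = hash),
                        class = "RunReport")
    out <- list(signature = signature, report = report,
                differential = differential, partition = partition,
                selection = selection, scores = NULL, survival = NULL)
    if (!is.null(config$out_dir)) write_run_outputs(out, config, hash)
    return(out)
  }

  scores <- maps_score(kept, signature)

  # -- survival evaluation (first and only outcome-aware stage) -------------
  surv <- evaluate_survival(scores, clinical, tie_method = config$tie_method)

  report <- structure(list(counts = report_counts,
                           partition_sizes = partition$sizes,
                           five_year = surv$five_year,
                           logrank_p = surv$logrank$p,
                           cox_table = surv$cox_table,
                           intensity_cutoff = cutoff,
                           chosen_delta = attr(differential, "chosen_delta"),
                           estimated_fdr = attr(differential, "estimated_fdr"),
                           seed = config$seed,
                           config_hash = hash),
                      class = "RunReport")
  out <- list(signature = signature, report = report,
              differential = differential, partition = partition,
              selection = selection, scores = scores, survival = surv)
  if (!is.null(config$out_dir)) write_run_outputs(out, config, hash)
  out
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Run report (seed ", x$seed, ", config ", substr(x$config_hash, 1, 8),
      ")\n", sep = "")
  for (nm in names(x$counts)) cat(sprintf("  %-28s %d\n", nm, x$counts[[nm]]))
  cat("  partition sizes:", paste(x$partition_sizes, collapse = "/"), "\n")
  if (!is.null(x$five_year)) {
    for (nm in names(x$five_year))
      cat(sprintf("  5-year survival %s: %.1f%%\n", nm, 100 * x$five_year[[nm]]))
    cat(sprintf("  log-rank p: %.4g\n", x$logrank_p))
  }
  invisible(x)
}

write_run_outputs <- function(out, config, hash) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_with_header(as.data.frame(out$differential), p("differential.tsv"), hash)
  write_with_header(data.frame(patient_id = names(out$partition$cluster),
                               cluster = unname(out$partition$cluster)),
                    p("partition.csv"), hash, sep = ",")
  write_with_header(as.data.frame(out$selection), p("selection.tsv"), hash)
  write_with_header(as.data.frame(out$signature), p("signature.tsv"), hash)
  if (!is.null(out$scores))
    write_with_header(as.data.frame(out$scores), p("scores.csv"), hash,
                      sep = ",")
  if (!is.null(out$survival)) {
    for (cls in names(out$survival$km))
      write_with_header(km_table(out$survival$km[[cls]]),
                        p(paste0("km_", cls, ".tsv")), hash)
    write_with_header(out$survival$cox_table, p("cox.tsv"), hash)
  }
  rep_lines <- utils::capture.output(print(out$report))
  writeLines(c(paste0("# config_hash: ", hash), rep_lines), p("report.txt"))
  invisible(config$out_dir)
}

#' Cohort-side signature derivation
#'
#' The outcome-blind cohort stages in one call: median normalization (and
#' probe collapsing when an annotation is given), optional restriction to a
#' candidate gene set, uniform-gene elimination, k-means partition, F/t gene
#' selection, AUC ranking and signature selection, and scoring. Survival data
#' play no part.
#'
#' @param cohort_expr Raw cohort `ExpressionMatrix` (or path).
#' @param genes Optional candidate genes (e.g. a differential set); default
#'   all genes on the matrix.
#' @param annotation Optional [probe_annotation()] for probe-level matrices.
#' @param spread_threshold,alpha,auc_cutoff,k,n_restarts,seed,use_bh_correction
#'   As in [maps_config()].
#' @param subgroups Optional normalization subgroups.
#' @return List with `normalized` (post-elimination matrix), `partition`,
#'   `selection`, `signature`, `scores` (`NULL` when the signature is empty).
#' @export
derive_cohort_signature <- function(cohort_expr, genes = NULL,
                                    annotation = NULL,
                                    spread_threshold = 0.5, alpha = 0.05,
                                    auc_cutoff = 0.95, k = 2L,
                                    n_restarts = 50L, seed = NULL,
                                    use_bh_correction = FALSE,
                                    subgroups = NULL) {
  cohort <- load_expr(cohort_expr, "raw")
  norm <- cohort_median_normalize(cohort, subgroups)
  if (!is.null(annotation))
    norm <- suppressMessages(
      collapse_probes_to_genes(norm, load_annotation(annotation)))
  if (!is.null(genes)) {
    avail <- intersect(genes, features(norm))
    if (!length(avail)) stop("no candidate gene present on the cohort matrix")
    norm <- expression_matrix(norm$values[avail, , drop = FALSE], "normalized")
  }
  kept <- suppressMessages(remove_uniform_genes(norm, spread_threshold))
  partition <- kmeans_partition(kept, k = k, n_restarts = n_restarts,
                                seed = seed)
  selection <- select_discriminant_genes(kept, partition, alpha = alpha,
                                         bh_correct = use_bh_correction)
  signature <- suppressWarnings(
    select_signature(kept, partition, selection$gene[selection$selected],
                     auc_cutoff = auc_cutoff))
  attr(signature, "alpha") <- alpha
  scores <- if (nrow(signature) > 0L) maps_score(kept, signature)
  list(normalized = kept, partition = partition, selection = selection,
       signature = signature, scores = scores)
}

#' Score and evaluate an independent validation cohort
#'
#' The validation cohort is normalized within itself (its own medians), never
#' against the derivation cohort; patients are scored with whatever signature
#' genes its platform carries, and survival is compared between classes.
#'
#' @param signature A `SignatureSet` (or signature file path).
#' @param cohort_expr Raw validation matrix (`ExpressionMatrix` or path).
#' @param clinical `ClinicalTable` or CSV path.
#' @param annotation Optional `ProbeAnnotation` (or path) when the matrix is
#'   probe-level.
#' @param tie_method,subgroups As in [maps_config()].
#' @param out_dir Optional output directory.
#' @return List with `scores`, `survival`, `n_genes_used`, `report`.
#' @export
run_validation <- function(signature, cohort_expr, clinical,
                           annotation = NULL, tie_method = "efron",
                           subgroups = NULL, out_dir = NULL) {
  sig <- if (inherits(signature, "SignatureSet")) signature
  else read_signature(signature)
  cohort <- load_expr(cohort_expr, "raw")
  if (ncol(cohort$values) < 2L)
    stop("validation cohort needs at least 2 patients to normalize")
  clinical <- load_clinical(clinical)
  norm <- cohort_median_normalize(cohort, subgroups)
  gene_level <- if (!is.null(annotation)) {
    ann <- load_annotation(annotation)
    suppressMessages(collapse_probes_to_genes(norm, ann))
  } else norm
  present <- intersect(sig$gene_symbol, features(gene_level))
  if (!length(present)) stop("no signature gene present in the validation cohort")
  if (length(present) < nrow(sig))
    message(nrow(sig) - length(present),
            " signature gene(s) absent from the validation platform; ",
            "scoring uses the remaining ", length(present))
  scores <- maps_score(gene_level, sig)
  surv <- evaluate_survival(scores, clinical, tie_method = tie_method)
  report <- list(n_genes_used = length(present),
                 n_patients = ncol(cohort$values),
                 class_sizes = table(scores$class),
                 five_year = surv$five_year,
                 logrank_p = surv$logrank$p)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hash <- "validation"
    write_with_header(as.data.frame(scores),
                      file.path(out_dir, "scores.csv"), hash, sep = ",")
    for (cls in names(surv$km))
      write_with_header(km_table(surv$km[[cls]]),
                        file.path(out_dir, paste0("km_", cls, ".tsv")), hash)
  }
  list(scores = scores, survival = surv,
       n_genes_used = length(present), report = report)
}

#' Simulate a matched derivation study
#'
#' Convenience wrapper producing consistent cell-line and cohort inputs: the
#' planted cell-line up-genes include the cohort's module genes, so the
#' end-to-end derivation can recover the planted signature.
#'
#' @param cell_cfg,cohort_cfg Optional configs; defaults are the package's
#'   study conditions. Gene names are reconciled automatically.
#' @param seed Integer seed applied to both generators (cell gets `seed`,
#'   cohort `seed + 1`).
#' @return List with `cell` (see [simulate_cell_line_arrays()]), `cohort`
#'   (see [simulate_cohort()]), and `annotation` extended so that module
#'   genes map onto planted up-probes.
#' @export
simulate_study <- function(cell_cfg = NULL, cohort_cfg = NULL, seed = 1L) {
  if (is.null(cell_cfg)) cell_cfg <- cell_line_sim_config(seed = seed)
  if (is.null(cell_cfg$seed)) cell_cfg$seed <- seed
  if (is.null(cohort_cfg)) cohort_cfg <- cohort_sim_config(seed = seed + 1L)
  if (is.null(cohort_cfg$seed)) cohort_cfg$seed <- seed + 1L
  cell <- simulate_cell_line_arrays(cell_cfg)
  cohort <- simulate_cohort(cohort_cfg)
  # rename: module genes ride on planted up probes, the rest of the cohort
  # genes on the other planted and background-null probes
  ann <- cell$annotation
  planted <- c(cell$truth$planted_up, cell$truth$planted_down)
  others <- setdiff(ann$probe_id, planted)
  cohort_genes <- rownames(cohort$expr$values)
  module <- cohort$truth$module_genes
  n_mod <- length(module)
  if (n_mod > length(cell$truth$planted_up))
    stop("cohort module larger than the planted up set")
  map <- ann$gene_symbol
  names(map) <- ann$probe_id
  map[cell$truth$planted_up[seq_len(n_mod)]] <- module
  rest <- setdiff(cohort_genes, module)
  pool <- c(setdiff(cell$truth$planted_up, cell$truth$planted_up[seq_len(n_mod)]),
            cell$truth$planted_down, others)
  take <- pool[seq_len(min(length(rest), length(pool)))]
  map[take] <- rest[seq_along(take)]
  ann2 <- probe_annotation(names(map), unname(map))
  list(cell = cell, cohort = cohort, annotation = ann2)
}
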