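#' Expression matrix container
#'
#' A features x samples numeric matrix carrying an explicit scale flag:
#' `"raw"` for strictly positive fluorescence intensities, `"normalized"` for
#' log2 ratios to the per-feature cohort median (the output of
#' [cohort_median_normalize()]).
#'
#' @param values Numeric matrix with feature ids as rownames and sample ids as
#'   colnames. Feature ids must be unique; values must be finite, and strictly
#'   positive when `scale = "raw"`.
#' @param scale `"raw"` or `"normalized"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `scale`.
#' @export
expression_matrix <- function(values, scale = c("raw", "normalized")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature ids (rownames) and sample ids (colnames)")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate feature ids: ", paste(utils::head(dup, 5L), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("missing or non-finite expression values are not supported")
  if (scale == "raw" && any(values <= 0))
    stop("raw intensities must be strictly positive")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
features <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
samples <- function(x) colnames(x$values)

#' Read / write an expression matrix
#'
#' Delimited text with the header `feature_id` followed by sample ids, one row
#' per feature. Non-numeric cells, missing values, ragged rows and duplicated
#' feature ids are rejected.
#'
#' @param path File path.
#' @param scale Declared scale of the stored values (`"raw"` or
#'   `"normalized"`).
#' @param sep Field delimiter; tab by default, use `","` for CSV.
#' @return [read_expression_matrix()] returns an `ExpressionMatrix`;
#'   [write_expression_matrix()] invisibly returns `path`.
#' @export
read_expression_matrix <- function(path, scale = c("raw", "normalized"),
                                   sep = "\t") {
  scale <- match.arg(scale)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "#", fill = FALSE)
  if (ncol(df) < 2L) stop("expected a feature id column plus >= 1 sample column")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature ids in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, colnames(df)[-1L]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing value at feature ", ids[bad[1L]],
         ", sample ", colnames(vals)[bad[2L]])
  }
  expression_matrix(vals, scale)
}

#' @rdname read_expression_matrix
#' @param m An `ExpressionMatrix`.
#' @export
write_expression_matrix <- function(m, path, sep = "\t") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(feature_id = features(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Probe-to-gene annotation
#'
#' Many-to-one mapping from array probe (set) ids to gene symbols. Probes
#' absent from the mapping are treated as unannotated.
#'
#' @param probe_id,gene_symbol Character vectors of equal length; each probe
#'   may appear at most once.
#' @return A `data.frame` of class `ProbeAnnotation`.
#' @export
probe_annotation <- function(probe_id, gene_symbol) {
  probe_id <- as.character(probe_id)
  gene_symbol <- as.character(gene_symbol)
  if (length(probe_id) != length(gene_symbol))
    stop("probe_id and gene_symbol must have equal length")
  if (anyDuplicated(probe_id))
    stop("a probe may map to only one gene symbol")
  if (anyNA(probe_id) || anyNA(gene_symbol) || any(gene_symbol == ""))
    stop("empty annotations are not allowed; omit unannotated probes instead")
  structure(data.frame(probe_id = probe_id, gene_symbol = gene_symbol),
            class = c("ProbeAnnotation", "data.frame"))
}

#' Collapse probe-level rows to gene-level rows
#'
#' Multiple probes interrogating one gene are averaged (arithmetic mean, on
#' whatever scale the matrix is on) into a single representative row per
#' sample. Unannotated probes are dropped with a message reporting the count.
#'
#' @param m An `ExpressionMatrix` whose features are probe ids.
#' @param ann A [probe_annotation()].
#' @return An `ExpressionMatrix` with one row per gene symbol, same scale.
#' @export
collapse_probes_to_genes <- function(m, ann) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(ann, "ProbeAnnotation"))
  idx <- match(features(m), ann$probe_id)
  annotated <- !is.na(idx)
  if (!any(annotated))
    stop("no probe in the matrix is present in the annotation")
  n_dropped <- sum(!annotated)
  if (n_dropped > 0L)
    message(n_dropped, " unannotated probe(s) dropped during gene collapsing")
  sym <- ann$gene_symbol[idx[annotated]]
  v <- m$values[annotated, , drop = FALSE]
  sums <- rowsum(v, group = sym)
  counts <- as.vector(table(sym)[rownames(sums)])
  out <- sums / counts
  expression_matrix(out, m$scale)
}

#' Median-centre a raw cohort matrix on the log2 scale
#'
#' Every raw intensity is replaced by the log2 ratio to the median of its
#' feature across the normalization group: the whole cohort by default, or
#' each subgroup separately when `subgroups` is given (each subgroup is then
#' centred on its own medians).
#'
#' @param m Raw-scale `ExpressionMatrix`.
#' @param subgroups Optional factor (or vector coercible to one) of length
#'   `ncol(m$values)` partitioning the samples; every subgroup needs at least
#'   2 samples.
#' @return A normalized-scale `ExpressionMatrix`. Per feature and
#'   normalization group the median of the returned values is exactly 0 for
#'   odd group sizes; for even sizes it lies within the log-concavity gap of
#'   the two middle order statistics (the raw-scale median is their
#'   arithmetic mean).
#' @export
cohort_median_normalize <- function(m, subgroups = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$scale != "raw")
    stop("cohort_median_normalize expects a raw-scale matrix")
  v <- m$values
  if (is.null(subgroups)) subgroups <- rep("all", ncol(v))
  subgroups <- as.factor(subgroups)
  if (length(subgroups) != ncol(v))
    stop("`subgroups` must have one entry per sample")
  out <- v
  for (g in levels(subgroups)) {
    cols <- which(subgroups == g)
    if (length(cols) < 2L)
      stop("normalization subgroup '", g, "' has fewer than 2 samples")
    med <- apply(v[, cols, drop = FALSE], 1L, stats::median)
    if (any(med <= 0))
      stop("non-positive feature median in subgroup '", g, "'")
    out[, cols] <- log2(v[, cols, drop = FALSE] / med)
  }
  expression_matrix(out, "normalized")
}

#' Read a clinical table
#'
#' Comma-separated file with required columns `patient_id`, `time_months`,
#' `event`, `t_stage`, `n_stage`, `grade`. Empty stage/grade cells are kept as
#' `NA` ("unknown") and excluded case-wise from models using that covariate.
#'
#' @param path CSV file path.
#' @return A validated `data.frame` of class `ClinicalTable`.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  clinical_table(df)
}

#' @rdname read_clinical_table
#' @param df A data frame with the required columns (time and event numeric or
#'   numeric-coercible).
#' @export
clinical_table <- function(df) {
  required <- c("patient_id", "time_months", "event",
                "t_stage", "n_stage", "grade")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df$time_months <- as.numeric(df$time_months)
  df$event <- as.numeric(df$event)
  if (anyNA(df$time_months) || any(df$time_months < 0))
    stop("time_months must be numeric and >= 0")
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death)")
  blank_to_na <- function(x) { x <- as.character(x); x[!nzchar(x)] <- NA; x }
  df$t_stage <- blank_to_na(df$t_stage)
  df$n_stage <- blank_to_na(df$n_stage)
  df$grade <- blank_to_na(df$grade)
  chk <- function(x, allowed, what) {
    bad <- !is.na(x) & !(x %in% allowed)
    if (any(bad)) stop("invalid ", what, " value(s): ",
                       paste(unique(x[bad]), collapse = ", "))
  }
  chk(df$t_stage, paste0("T", 1:4), "t_stage")
  chk(df$n_stage, paste0("N", 0:2), "n_stage")
  chk(df$grade, as.character(1:3), "grade")
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id")
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' @rdname read_clinical_table
#' @param clin A `ClinicalTable`.
#' @export
write_clinical_table <- function(clin, path) {
  out <- as.data.frame(clin)
  out[is.na(out)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Binary clinical encodings used by the Cox models
#'
#' Stage, node and grade categories are dichotomized the way the survival
#' models use them: `t_high` = T3-T4 vs T1-T2, `n_pos` = N1-N2 vs N0,
#' `grade_high` = grade 2-3 vs grade 1. Unknown cells propagate as `NA`.
#'
#' @param clin A `ClinicalTable`.
#' @return A data frame with columns `patient_id`, `t_high`, `n_pos`,
#'   `grade_high` (0/1/NA).
#' @export
encode_clinical_binary <- function(clin) {
  stopifnot(inherits(clin, "ClinicalTable"))
  data.frame(
    patient_id = clin$patient_id,
    t_high = ifelse(is.na(clin$t_stage), NA,
                    as.integer(clin$t_stage %in% c("T3", "T4"))),
    n_pos = ifelse(is.na(clin$n_stage), NA,
                   as.integer(clin$n_stage %in% c("N1", "N2"))),
    grade_high = ifelse(is.na(clin$grade), NA,
                        as.integer(clin$grade %in% c("2", "3")))
  )
}

# Run `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
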