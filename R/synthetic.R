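#' Configuration for simulated two-condition cell-line arrays
#'
#' Emulates the design the differential stage assumes: duplicated arrays per
#' condition hybridized with pooled RNA (pooling shows up as a small replicate
#' noise), a body of well-measured probes, a planted set of induced/repressed
#' probes at a fixed linear fold, and a tail of low-intensity background
#' probes whose replicate agreement is poor — the population the intensity
#' filtration is meant to remove.
#'
#' @param n_probes Number of signal-range probes (planted probes are among
#'   these).
#' @param n_planted_up,n_planted_down Numbers of probes induced/repressed by
#'   `planted_fold` in the condition arrays.
#' @param planted_fold Linear fold change of planted probes (>= 2 mirrors the
#'   selection cutoff the screen uses).
#' @param n_background_probes Extra low-intensity, poorly reproducible probes.
#' @param noise_sd Replicate noise SD of signal probes, log2 scale.
#' @param n_arrays_per_condition Arrays per condition (default 2, duplicated
#'   arrays).
#' @param baseline_log2_mean,baseline_log2_sd Baseline log2 intensity
#'   distribution of signal probes.
#' @param background_log2_mean,background_log2_sd,background_noise_sd Same for
#'   background probes; `background_noise_sd` is their (large) replicate noise.
#' @param seed Integer seed; identical seeds give identical simulations.
#' @return A validated config list of class `CellLineSimConfig`.
#' @export
cell_line_sim_config <- function(n_probes = 3000,
                                 n_planted_up = 50,
                                 n_planted_down = 50,
                                 planted_fold = 2.5,
                                 n_background_probes = 1000,
                                 noise_sd = 0.12,
                                 n_arrays_per_condition = 2,
                                 baseline_log2_mean = 10,
                                 baseline_log2_sd = 1,
                                 background_log2_mean = 5,
                                 background_log2_sd = 0.4,
                                 background_noise_sd = 0.8,
                                 seed = NULL) {
  cfg <- as.list(environment())
  if (n_planted_up + n_planted_down > n_probes)
    stop("planted probe counts exceed n_probes")
  if (planted_fold < 1) stop("planted_fold must be >= 1")
  if (noise_sd <= 0 || background_noise_sd <= 0) stop("noise SDs must be > 0")
  if (n_arrays_per_condition < 1) stop("need >= 1 array per condition")
  class(cfg) <- "CellLineSimConfig"
  cfg
}

#' Simulate duplicated two-condition arrays with planted fold changes
#'
#' @param cfg A [cell_line_sim_config()].
#' @return A list with elements:
#'   * `expr` — raw-scale `ExpressionMatrix`, columns
#'     `control_1..n, condition_1..n`;
#'   * `condition_labels` — `"control"` / `"condition"` per column;
#'   * `replicate_pairs` — list of within-condition column index pairs;
#'   * `annotation` — [probe_annotation()] for signal probes (background
#'     probes are left unannotated);
#'   * `truth` — planted probe ids, directions and simulation parameters.
#' @export
simulate_cell_line_arrays <- function(cfg) {
  stopifnot(inherits(cfg, "CellLineSimConfig"))
  with_seed(cfg$seed, {
    n_arr <- cfg$n_arrays_per_condition
    n_sig <- cfg$n_probes
    n_bg <- cfg$n_background_probes
    probe_sig <- sprintf("P%05d_at", seq_len(n_sig))
    probe_bg <- if (n_bg > 0) sprintf("B%05d_at", seq_len(n_bg)) else character()
    up <- probe_sig[seq_len(cfg$n_planted_up)]
    down <- probe_sig[cfg$n_planted_up + seq_len(cfg$n_planted_down)]

    base_sig <- stats::rnorm(n_sig, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    base_bg <- stats::rnorm(n_bg, cfg$background_log2_mean, cfg$background_log2_sd)
    shift <- numeric(n_sig)
    shift[probe_sig %in% up] <- log2(cfg$planted_fold)
    shift[probe_sig %in% down] <- -log2(cfg$planted_fold)

    one_array <- function(in_condition) {
      sig <- base_sig + if (in_condition) shift else 0
      c(sig + stats::rnorm(n_sig, 0, cfg$noise_sd),
        base_bg + stats::rnorm(n_bg, 0, cfg$background_noise_sd))
    }
    cols <- c(replicate(n_arr, one_array(FALSE)),
              replicate(n_arr, one_array(TRUE)))
    v <- 2^matrix(cols, nrow = n_sig + n_bg)
    rownames(v) <- c(probe_sig, probe_bg)
    colnames(v) <- c(paste0("control_", seq_len(n_arr)),
                     paste0("condition_", seq_len(n_arr)))
    labels <- rep(c("control", "condition"), each = n_arr)
    pairs <- list()
    if (n_arr >= 2) {
      for (off in c(0L, n_arr))
        for (i in seq_len(n_arr - 1L))
          pairs[[length(pairs) + 1L]] <- off + c(i, i + 1L)
    }
    ann <- probe_annotation(probe_sig, sub("^P(\\d+)_at$", "G\\1", probe_sig))
    list(expr = expression_matrix(v, "raw"),
         condition_labels = labels,
         replicate_pairs = pairs,
         annotation = ann,
         truth = list(planted_up = up, planted_down = down,
                      planted_genes_up = sub("^P(\\d+)_at$", "G\\1", up),
                      planted_genes_down = sub("^P(\\d+)_at$", "G\\1", down),
                      background = probe_bg, cfg = cfg))
  })
}

#' Configuration for a simulated survival-annotated cohort
#'
#' The generator plants a one-factor "proliferation" module: a latent factor
#' `z` (two-component Gaussian mixture, so that a genuine 2-cluster structure
#' exists) loads on `module_size` genes with weight `loading` (log2 units) and
#' multiplies the death hazard by `exp(beta_z)` per unit. Binary stage/node
#' covariates are mildly correlated with `z` (odds ratio `covariate_or`) and
#' carry their own hazard effects, so multivariate adjustment is a meaningful
#' exercise. A `uniform_gene_fraction` of genes is near-constant, the
#' population the uniform-gene elimination step is meant to remove. Censoring
#' is administrative at a uniform random horizon calibrated to the requested
#' rate.
#'
#' @param n_patients Cohort size (default 441, the size of the derivation
#'   cohort after the one exclusion).
#' @param n_genes Genes on the emitted matrix (default 254, the size of the
#'   differential set the cohort stage starts from).
#' @param module_size Planted proliferation-module genes (default 7).
#' @param loading Log2 effect of `z` on module genes.
#' @param noise_sd Residual per-gene log2 noise of module and background
#'   genes.
#' @param uniform_gene_fraction Fraction of genes made near-constant
#'   (default 0.34, mirroring an 87/254 elimination).
#' @param uniform_noise_sd Log2 noise of the near-constant genes.
#' @param latent_weights,latent_means,latent_sds Two-component mixture of `z`.
#' @param beta_z Log hazard ratio per unit `z` (default `log(2)`).
#' @param beta_t,beta_n Log hazard ratios of the binary T-stage and node
#'   covariates.
#' @param baseline_hazard Exponential baseline hazard, events per month.
#' @param censoring_rate Target fraction censored (0 disables censoring).
#' @param covariate_or Odds ratio linking `z` to each binary covariate.
#' @param t_high_prob,n_pos_prob,grade_high_prob Marginal covariate
#'   prevalences at `z = 0` (defaults echo a stage I-III adenocarcinoma
#'   case mix).
#' @param baseline_log2_range Range of per-gene baseline log2 intensities.
#' @param gene_ids Optional gene symbols (length `n_genes`); by default the
#'   module genes take the canonical seven proliferation-signature names when
#'   `module_size <= 7`.
#' @param seed Integer seed.
#' @return A validated config list of class `CohortSimConfig`.
#' @export
cohort_sim_config <- function(n_patients = 441,
                              n_genes = 254,
                              module_size = 7,
                              loading = 1,
                              noise_sd = 0.5,
                              uniform_gene_fraction = 0.34,
                              uniform_noise_sd = 0.05,
                              latent_weights = c(0.5, 0.5),
                              latent_means = c(-1, 1),
                              latent_sds = c(0.5, 0.5),
                              beta_z = log(2),
                              beta_t = log(2.6),
                              beta_n = log(2.8),
                              baseline_hazard = 0.01,
                              censoring_rate = 0.4,
                              covariate_or = 1.5,
                              t_high_prob = 0.09,
                              n_pos_prob = 0.32,
                              grade_high_prob = 0.86,
                              baseline_log2_range = c(6, 12),
                              gene_ids = NULL,
                              seed = NULL) {
  cfg <- as.list(environment())
  if (module_size > n_genes) stop("module_size must be <= n_genes")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (noise_sd <= 0 || uniform_noise_sd <= 0) stop("noise SDs must be > 0")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  if (uniform_gene_fraction < 0 || uniform_gene_fraction > 1)
    stop("uniform_gene_fraction must be in [0, 1]")
  if (length(latent_weights) != 2L || abs(sum(latent_weights) - 1) > 1e-8)
    stop("latent_weights must be two weights summing to 1")
  if (!is.null(gene_ids) && length(gene_ids) != n_genes)
    stop("gene_ids must have length n_genes")
  class(cfg) <- "CohortSimConfig"
  cfg
}

maps_gene_names <- c("CCNB1", "CDC2", "CDC20", "CDKN3", "MAD2L1", "PRC1", "RRM2")

#' Simulate a survival-linked expression cohort with a planted module
#'
#' @param cfg A [cohort_sim_config()].
#' @return A list with elements:
#'   * `expr` — raw-scale `ExpressionMatrix` (genes x patients);
#'   * `clinical` — `ClinicalTable`;
#'   * `truth` — per-patient latent `z`, mixture component, true class
#'     (`TRUE` = high-z component), module and uniform gene ids, the true log
#'     hazard ratios, and the censoring horizon used.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "CohortSimConfig"))
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    p <- cfg$n_genes
    genes <- cfg$gene_ids
    if (is.null(genes)) {
      genes <- sprintf("G%04d", seq_len(p))
      if (cfg$module_size <= length(maps_gene_names))
        genes[seq_len(cfg$module_size)] <-
          maps_gene_names[seq_len(cfg$module_size)]
      else
        genes[seq_len(cfg$module_size)] <-
          sprintf("MOD%03d", seq_len(cfg$module_size))
    }
    module <- genes[seq_len(cfg$module_size)]
    n_unif <- floor(cfg$uniform_gene_fraction * p)
    n_unif <- min(n_unif, p - cfg$module_size)
    uniform <- genes[cfg$module_size + seq_len(n_unif)]

    comp <- sample(1:2, n, replace = TRUE, prob = cfg$latent_weights)
    z <- stats::rnorm(n, cfg$latent_means[comp], cfg$latent_sds[comp])

    base <- stats::runif(p, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])
    sd_gene <- rep(cfg$noise_sd, p)
    sd_gene[genes %in% uniform] <- cfg$uniform_noise_sd
    lods <- matrix(base, p, n) +
      matrix(stats::rnorm(p * n, 0, sd_gene), p, n)
    if (cfg$module_size > 0L) {
      mod_idx <- match(module, genes)
      lods[mod_idx, ] <- lods[mod_idx, ] +
        cfg$loading * matrix(z, cfg$module_size, n, byrow = TRUE)
    }
    v <- 2^lods
    rownames(v) <- genes
    colnames(v) <- sprintf("PT%04d", seq_len(n))

    draw_bin <- function(p0) {
      stats::rbinom(n, 1L, stats::plogis(stats::qlogis(p0) +
                                           log(cfg$covariate_or) * z))
    }
    t_high <- draw_bin(cfg$t_high_prob)
    n_pos <- draw_bin(cfg$n_pos_prob)
    g_high <- draw_bin(cfg$grade_high_prob)
    t_stage <- ifelse(t_high == 1, sample(c("T3", "T4"), n, TRUE),
                      sample(c("T1", "T2"), n, TRUE))
    n_stage <- ifelse(n_pos == 1, sample(c("N1", "N2"), n, TRUE), "N0")
    grade <- ifelse(g_high == 1, sample(c("2", "3"), n, TRUE), "1")

    rate <- cfg$baseline_hazard *
      exp(cfg$beta_z * z + cfg$beta_t * t_high + cfg$beta_n * n_pos)
    t_event <- stats::rexp(n, rate)
    if (cfg$censoring_rate > 0) {
      # administrative horizon tau: mean_i P(U(0,tau) < T_i) = target rate
      f <- function(tau) mean(pmin(t_event / tau, 1)) - cfg$censoring_rate
      hi <- max(t_event) / cfg$censoring_rate
      tau <- stats::uniroot(f, lower = min(t_event) * 1e-6, upper = hi,
                            tol = 1e-8)$root
      cens <- stats::runif(n, 0, tau)
      time <- pmin(t_event, cens)
      event <- as.numeric(t_event <= cens)
    } else {
      tau <- Inf
      time <- t_event
      event <- rep(1, n)
    }

    clin <- clinical_table(data.frame(
      patient_id = colnames(v), time_months = time, event = event,
      t_stage = t_stage, n_stage = n_stage, grade = grade,
      stringsAsFactors = FALSE))
    list(expr = expression_matrix(v, "raw"),
         clinical = clin,
         truth = list(z = stats::setNames(z, colnames(v)),
                      component = comp,
                      true_class = comp == which.max(cfg$latent_means),
                      module_genes = module,
                      uniform_genes = uniform,
                      betas = c(z = cfg$beta_z, t = cfg$beta_t, n = cfg$beta_n),
                      censor_horizon = tau,
                      cfg = cfg))
  })
}
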