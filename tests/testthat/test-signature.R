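test_that("uniform-gene elimination keeps only genes with spread", {
  v <- rbind(constant = rep(0, 20),
             spread = seq(-2, 2, length.out = 20))
  m <- toy_matrix(v, scale = "normalized")
  expect_message(out <- remove_uniform_genes(m), "1 uniform gene")
  expect_identical(features(out), "spread")
  expect_error(remove_uniform_genes(
    toy_matrix(rbind(rep(0, 5)), scale = "normalized")), "every gene")

  # planted near-constant genes in the cohort generator are caught
  sim <- simulate_cohort(cohort_sim_config(seed = 2))
  norm <- cohort_median_normalize(sim$expr)
  kept <- suppressMessages(remove_uniform_genes(norm))
  removed <- setdiff(features(norm), features(kept))
  expect_gte(mean(sim$truth$uniform_genes %in% removed), 0.95)
})

test_that("k-means recovers well-separated patient clouds deterministically", {
  set.seed(6)
  n <- 40
  centre <- rep(c(0, 10), each = n / 2)
  v <- rbind(g1 = centre + rnorm(n, 0, 0.5),
             g2 = centre + rnorm(n, 0, 0.5))
  m <- toy_matrix(v, scale = "normalized")
  part <- kmeans_partition(m, seed = 42)
  truth <- rep(1:2, each = n / 2)
  agree <- max(mean(part$cluster == truth), mean(part$cluster == 3 - truth))
  expect_equal(agree, 1)
  expect_identical(part$expressor,
                   unname(part$cluster[n]))  # high-mean side is the expressor

  part2 <- kmeans_partition(m, seed = 42)
  expect_identical(part$cluster, part2$cluster)

  # two distinct repeated points: centroids are the points, inertia zero
  v2 <- matrix(rep(c(0, 0, 5, 5), 2), 2, 4, byrow = TRUE,
               dimnames = list(c("a", "b"), sprintf("S%d", 1:4)))
  p2 <- kmeans_partition(expression_matrix(v2, "normalized"), seed = 1)
  expect_equal(p2$inertia, 0)
  expect_error(kmeans_partition(m, k = 99), "exceeds")
})

test_that("F-test-guided t-tests select shifted genes and respect alpha", {
  set.seed(8)
  n1 <- 200; n2 <- 200
  cl <- toy_partition(setNames(rep(1:2, c(n1, n2)), sprintf("S%03d", 1:400)))
  sd_pool <- 1
  v <- rbind(
    shifted = c(rnorm(n1, 5 * sd_pool, sd_pool), rnorm(n2, 0, sd_pool)),
    null1 = rnorm(400),
    hetero = c(rnorm(n1, 0, 4), rnorm(n2, 0, 0.5)),
    flat = rep(1, 400))
  m <- toy_matrix(v, samples = names(cl$cluster), scale = "normalized")
  sel <- select_discriminant_genes(m, cl)
  rec <- setNames(split(sel, seq_len(nrow(sel))), sel$gene)
  expect_true(rec$shifted$selected)            # 5-SD shift: power ~ 1
  expect_identical(rec$hetero$t_variant, "unequal_variance")
  expect_identical(rec$null1$t_variant, "pooled")
  expect_false(rec$flat$selected)              # identical values: t undefined

  # Benjamini-Hochberg flag tightens selection
  sel_bh <- select_discriminant_genes(m, cl, bh_correct = TRUE)
  expect_lte(sum(sel_bh$selected), sum(sel$selected))
})

test_that("empirical AUC enumerates pairs with half-credit ties", {
  expect_equal(gene_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(gene_auc(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.25)
  expect_equal(gene_auc(c(1, 1), c(TRUE, FALSE)), 0.5)
  expect_error(gene_auc(c(1, 2), c(TRUE, TRUE)), "non-empty")

  # rank-sum identity and complement symmetry on random instances
  set.seed(12)
  for (i in 1:50) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    vals <- c(rnorm(n1, 1), rnorm(n2))
    pos <- rep(c(TRUE, FALSE), c(n1, n2))
    r <- rank(vals)
    u <- sum(r[pos]) - n1 * (n1 + 1) / 2
    expect_equal(gene_auc(vals, pos), u / (n1 * n2), tolerance = 1e-12)
    expect_equal(gene_auc(vals, pos) + gene_auc(-vals, pos), 1,
                 tolerance = 1e-12)
  }
})

test_that("signature selection applies the strict AUC cutoff with ordering", {
  lost <- c(CD20 = 1, RRM = 2, CCN = 2, MAD = 2, PRC = 3, CDC = 3,
            CDK = 3, ODD = 6)            # AUCs .99 .98 .98 .98 .97 .97 .97 .94
  v <- t(vapply(lost, auc_controlled_gene, numeric(20)))
  m <- toy_matrix(v, features = names(lost), scale = "normalized")
  part <- toy_partition(setNames(rep(1:2, each = 10), samples(m)))
  sig <- select_signature(m, part, names(lost))
  expect_identical(nrow(sig), 7L)                   # 0.94 gene excluded
  expect_false("ODD" %in% sig$gene_symbol)
  expect_equal(sig$auc, sort(sig$auc, decreasing = TRUE))
  expect_identical(sig$gene_symbol[1], "CD20")
  # ties broken alphabetically within equal AUC
  tied <- sig$gene_symbol[sig$auc == 0.98]
  expect_identical(tied, sort(tied))
  expect_true(all(sig$direction == "up"))

  # boundary: AUC exactly at the cutoff is not selected
  v95 <- t(vapply(c(A = 5, B = 5), auc_controlled_gene, numeric(20)))
  m95 <- toy_matrix(v95, features = c("A", "B"), scale = "normalized")
  expect_warning(s95 <- select_signature(m95, part, c("A", "B")), "empty")
  expect_identical(nrow(s95), 0L)

  one <- toy_matrix(t(vapply(c(Z = 4), auc_controlled_gene, numeric(20))),
                    features = "Z", scale = "normalized")
  s1 <- select_signature(one, part, "Z")            # AUC 0.96
  expect_identical(s1$gene_symbol, "Z")
})

test_that("down-regulated genes are oriented and sign-flipped in scoring", {
  up <- auc_controlled_gene(2)
  m <- toy_matrix(rbind(UPG = up, DNG = -up),
                  scale = "normalized")
  part <- toy_partition(setNames(rep(1:2, each = 10), samples(m)))
  sig <- select_signature(m, part, c("UPG", "DNG"))
  expect_identical(nrow(sig), 2L)
  expect_setequal(sig$direction, c("up", "down"))
  expect_equal(sig$auc[1], sig$auc[2])
  sc <- maps_score(m, sig)
  # flipped down gene equals the up gene: score is just the up gene's value
  expect_equal(sc$score, unname(up))
})

test_that("relative expression scores classify strictly above zero", {
  sig <- signature_set(data.frame(
    gene_symbol = c("A", "B"), auc = c(0.99, 0.98),
    direction = c("up", "up")))
  m0 <- toy_matrix(matrix(0, 2, 3), features = c("A", "B"),
                   scale = "normalized")
  sc0 <- maps_score(m0, sig)
  expect_true(all(sc0$score == 0))
  expect_true(all(sc0$class == "MAPS_neg"))        # strict inequality

  m1 <- toy_matrix(matrix(1, 2, 3), features = c("A", "B"),
                   scale = "normalized")
  expect_true(all(maps_score(m1, sig)$class == "MAPS_pos"))

  # missing signature gene: scoring proceeds on the remainder
  mA <- toy_matrix(matrix(c(1, 2, 3), 1, 3), features = "A",
                   scale = "normalized")
  scA <- maps_score(mA, sig)
  expect_identical(unique(scA$n_genes_used), 1L)
  expect_equal(scA$score, c(1, 2, 3))
  expect_error(maps_score(toy_matrix(matrix(1, 1, 2), features = "ZZ",
                                     scale = "normalized"), sig),
               "no signature gene")

  # linearity: adding c to the signature-gene values shifts the score by c
  v <- matrix(rnorm(6), 2, 3, dimnames = list(c("A", "B"), c("p1", "p2", "p3")))
  base <- maps_score(expression_matrix(v, "normalized"), sig)$score
  shifted <- maps_score(expression_matrix(v + 0.7, "normalized"), sig)$score
  expect_equal(shifted, base + 0.7, tolerance = 1e-12)
})

test_that("signature files round-trip with derivation metadata", {
  sig <- signature_set(data.frame(
    gene_symbol = c("CCNB1", "PRC1"), auc = c(0.98, 0.97),
    direction = c("up", "up")), auc_cutoff = 0.95, k = 2, alpha = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$gene_symbol, sig$gene_symbol)
  expect_equal(back$auc, sig$auc)
  expect_equal(attr(back, "auc_cutoff"), 0.95)
})
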