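test_that("log normalisation follows the per-10k ln formula", {
  counts <- matrix(c(10, 0, 9990, 5, 0, 4995), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  lm <- log_normalize(counts)
  expect_equal(lm["g1", "c1"], log(11))   # 10 of 10000
  expect_equal(lm["g2", "c1"], 0)         # ln(1)
  expect_equal(lm["g1", "c2"], log(11))   # 5 of 5000: scale invariance
  # sparse input stays sparse and agrees with the dense path
  sp <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  expect_s4_class(log_normalize(sp), "dgCMatrix")
  expect_equal(as.matrix(log_normalize(sp)), lm)
  # zero-total cells are an error naming the cell
  counts0 <- cbind(counts, c0 = c(0, 0, 0))
  expect_error(log_normalize(counts0), "c0")
})

test_that("log normalisation round-trips back to integer counts", {
  sim <- simulate_expression(expression_sim_config(n_genes = 200,
                                                   n_cells = 80, seed = 9))
  lm <- as.matrix(log_normalize(sim$counts))
  totals <- Matrix::colSums(sim$counts)
  back <- sweep(exp(lm) - 1, 2, totals / 1e4, "*")
  expect_equal(round(back), as.matrix(sim$counts), ignore_attr = TRUE)
})

test_that("derive_signature applies strict AUC and adjusted-p thresholds", {
  set.seed(61)
  n <- 60
  target <- rep(c(TRUE, FALSE), each = n / 2)
  perfect <- c(stats::rnorm(n / 2, 10), stats::rnorm(n / 2, 0))
  flat <- stats::rnorm(n)
  lm <- rbind(gA = perfect, gB = flat)
  colnames(lm) <- sprintf("c%02d", seq_len(n))
  sig <- derive_signature(lm, target)
  expect_equal(sig$stats$auc[sig$stats$gene == "gA"], 1.0)
  expect_true("gA" %in% sig$genes)
  expect_false("gB" %in% sig$genes)
  # AUC exactly at the threshold is excluded (strict >)
  sig06 <- derive_signature(lm, target, auc_min = 1.0)
  expect_false("gA" %in% sig06$genes)
  expect_error(derive_signature(lm, c(TRUE, rep(FALSE, n - 1))), "at least 2")
})

test_that("per-gene AUC and p agree with wilcox.test on small data", {
  set.seed(62)
  lm <- matrix(stats::rnorm(50 * 40), 50, 40,
               dimnames = list(sprintf("g%02d", 1:50),
                               sprintf("c%02d", 1:40)))
  lm[1:5, 1:15] <- lm[1:5, 1:15] + 1.5
  target <- c(rep(TRUE, 15), rep(FALSE, 25))
  sig <- derive_signature(lm, target, adjust = "BH")
  for (g in c("g01", "g20", "g47")) {
    wt <- stats::wilcox.test(lm[g, target], lm[g, !target], exact = FALSE,
                             correct = FALSE)
    expect_equal(sig$stats$p_value[sig$stats$gene == g], wt$p.value,
                 tolerance = 1e-10)
    expect_equal(sig$stats$auc[sig$stats$gene == g],
                 unname(wt$statistic) / (15 * 25), tolerance = 1e-12)
  }
})

test_that("per-cell ranking centres on the population mean", {
  sim <- simulate_expression(expression_sim_config(n_genes = 100,
                                                   n_cells = 30, seed = 10))
  lm <- log_normalize(sim$counts)
  r <- per_cell_rank(lm, "BC00001")
  expect_equal(nrow(r), 100L)
  expect_true(all(diff(r$score) <= 0))
  # mean of scores over all cells is zero for every gene (centering identity)
  all_scores <- vapply(colnames(lm), function(cl) {
    rr <- per_cell_rank(lm, cl)
    rr$score[match(rownames(lm), rr$gene)]
  }, numeric(100))
  expect_equal(max(abs(rowMeans(all_scores))), 0, tolerance = 1e-12)
  # a cell identical to the mean profile scores zero everywhere
  lm2 <- cbind(as.matrix(lm), meancell = rowMeans(as.matrix(lm)))
  r2 <- per_cell_rank(lm2, "meancell")
  expect_equal(max(abs(r2$score)), 0, tolerance = 1e-12)
  # gene expressed in one cell only: top of that cell, bottom elsewhere
  lm3 <- matrix(0, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("a", "b")))
  lm3["g2", "a"] <- 2
  expect_equal(per_cell_rank(lm3, "a")$gene[1], "g2")
  rb <- per_cell_rank(lm3, "b")
  expect_equal(rb$gene[3], "g2")
  expect_lt(rb$score[3], 0)
})

test_that("enrichment_score equals the brute-force running-sum walk", {
  set.seed(63)
  for (rep in 1:40) {
    N <- 300
    scores <- sort(stats::rnorm(N), decreasing = TRUE)
    genes <- sprintf("g%04d", seq_len(N))
    ranked <- data.frame(gene = genes, score = scores)
    k <- sample(5:60, 1)
    set_genes <- sample(genes, k)
    es <- enrichment_score(ranked, set_genes)
    expect_equal(es, oracle_es(genes, scores, set_genes), tolerance = 1e-12)
    expect_gte(es, -1); expect_lte(es, 1)
  }
  # sign conventions at the extremes
  ranked <- data.frame(gene = sprintf("g%03d", 1:100),
                       score = seq(5, -5, length.out = 100))
  expect_gt(enrichment_score(ranked, ranked$gene[1:10]), 0)
  expect_lt(enrichment_score(ranked, ranked$gene[91:100]), 0)
  expect_error(enrichment_score(ranked, ranked$gene), "entire")
  expect_warning(es0 <- enrichment_score(ranked, c("nope1", "nope2")),
                 "skipped")
  expect_true(is.na(es0))
})

test_that("random sets on a flat ranking give near-zero centred ES", {
  set.seed(64)
  N <- 500
  ranked <- data.frame(gene = sprintf("g%04d", 1:N), score = rep(1, N))
  es <- vapply(1:200, function(i)
    enrichment_score(ranked, sample(ranked$gene, 25)), 0)
  expect_lt(abs(mean(es)), 0.05)
})

test_that("per-cell GSEA recovers a planted module and is seed-stable", {
  cfg <- expression_sim_config(
    n_genes = 600, n_cells = 150, n_clusters = 3,
    module_specs = list(list(name = "m1", n_genes = 30, clusters = 1,
                             effect = 1.2)),
    seed = 11)
  sim <- simulate_expression(cfg)
  lm <- log_normalize(sim$counts)
  sets <- list(m1 = sim$truth$module_genes$m1)
  res <- gsea_per_cell(lm, sets, n_perm = 200, seed = 12)
  expect_equal(nrow(res), 150L)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
  planted <- res$cell_id %in% sim$truth$module_cells$m1
  flag <- res$significant & res$nes > 0
  expect_gte(mean(flag[planted]), 0.75)
  expect_lt(mean(flag[!planted]), 0.1)
  # byte-stable under the same seed
  res2 <- gsea_per_cell(lm, sets, n_perm = 200, seed = 12)
  expect_identical(res, res2)
  expect_error(gsea_per_cell(lm, sets, n_perm = 5), "n_perm")
})

test_that("cluster summaries report fractions, quartiles and tests", {
  cfg <- expression_sim_config(
    n_genes = 400, n_cells = 120, n_clusters = 3,
    module_specs = list(list(name = "m1", n_genes = 25, clusters = 2,
                             effect = 1.2)),
    seed = 13)
  sim <- simulate_expression(cfg)
  lm <- log_normalize(sim$counts)
  res <- gsea_per_cell(lm, list(m1 = sim$truth$module_genes$m1),
                       n_perm = 200, seed = 14)
  clusters <- stats::setNames(sim$cells$cluster, sim$cells$cell_id)
  sc <- summarize_clusters(res, clusters)
  s <- sc$summary
  expect_equal(sort(unique(s$cluster)), c("1", "2", "3"))
  target <- s$frac_significant_pos[s$cluster == "2"]
  expect_true(all(target > s$frac_significant_pos[s$cluster != "2"]))
  # self-comparison of a cluster is degenerate (p = 1)
  self <- sc$tests[sc$tests$cluster_a == sc$tests$cluster_b, ]
  expect_true(all(self$p_value[!is.na(self$p_value)] == 1))
  # clusters with no significant cells produce empty distributions
  null_cl <- s[s$cluster != "2", ]
  expect_true(all(null_cl$frac_significant_pos < 0.2))
})

test_that("cluster expression stats z-score across clusters", {
  cfg <- expression_sim_config(
    n_genes = 200, n_cells = 90, n_clusters = 3,
    module_specs = list(list(name = "m1", n_genes = 10, clusters = 3,
                             effect = 2)),
    seed = 15)
  sim <- simulate_expression(cfg)
  clusters <- stats::setNames(sim$cells$cluster, sim$cells$cell_id)
  tg <- sim$truth$module_genes$m1
  st <- cluster_expression_stats(sim$counts, clusters, tg)
  # per gene: z over clusters has mean 0, sd 1
  for (g in tg[1:3]) {
    z <- st$z_score[st$gene == g]
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  }
  # the planted cluster carries the maximal z and expressing fraction
  for (g in tg) {
    sg <- st[st$gene == g, ]
    expect_equal(sg$cluster[which.max(sg$z_score)], "3")
  }
  # a constant gene yields all-zero z-scores
  counts <- matrix(5, 2, 30, dimnames = list(c("g1", "g2"),
                                             sprintf("c%02d", 1:30)))
  cl <- stats::setNames(rep(1:3, each = 10), colnames(counts))
  st2 <- cluster_expression_stats(counts, cl)
  expect_true(all(st2$z_score == 0))
  expect_error(cluster_expression_stats(counts, stats::setNames(
    rep(1, 30), colnames(counts))), "2 clusters")
})
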