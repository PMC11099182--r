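test_that("cdr3_identity is exact arithmetic with strict length contract", {
  expect_equal(cdr3_identity("ACGTACGTACGTACG", "ACGTACGTACGTACG"), 1.0)
  s <- "ACGTACGTACGTACG"  # 15 nt
  s3 <- mutate_nt(s, c(1, 5, 9))
  expect_equal(cdr3_identity(s, s3), 0.8)
  s2 <- mutate_nt(s, c(2, 7))
  expect_equal(cdr3_identity(s, s2), 13 / 15)
  expect_error(cdr3_identity("ACGT", "ACGTA"), "length")
  expect_error(cdr3_identity("", ""), "empty")
})

test_that("identity exactly 0.80 never co-clusters (strict >)", {
  set.seed(41)
  h <- "ACGTACGTACGTACG"
  pairs <- make_group_pairs(c(h, mutate_nt(h, c(1, 5, 9))),
                            rep("TGCTGGTGA", 2))
  part <- partition_families(pairs)
  expect_equal(length(part$families), 2L)
  # one mismatch fewer and they merge
  pairs2 <- make_group_pairs(c(h, mutate_nt(h, c(1, 5))), rep("TGCTGGTGA", 2))
  expect_equal(length(partition_families(pairs2)$families), 1L)
})

test_that("cells with matching keys and high identity form one family", {
  set.seed(42)
  h <- rand_nt(30); l <- rand_nt(24)
  pairs <- make_group_pairs(c(h, mutate_nt(h, 1), mutate_nt(h, c(2, 9))),
                            c(l, mutate_nt(l, 3), l))
  part <- partition_families(pairs)
  expect_equal(length(part$families), 1L)
  # a light-chain V mismatch splits regardless of identical CDR3s
  pairs$light_v_call[2] <- "VK9"
  expect_equal(length(partition_families(pairs)$families), 2L)
  # donors are never crossed
  pairs$light_v_call[2] <- "VK1"
  pairs$donor[3] <- "D02"
  expect_equal(length(partition_families(pairs)$families), 2L)
})

test_that("chained intermediate identities follow the linkage semantics", {
  # heavy CDR3s: a-b and b-c at distance 4/30, a-c at 8/30 (cut at > 6)
  set.seed(43)
  a <- rand_nt(30)
  b <- mutate_nt(a, 1:4)
  c_ <- mutate_nt(b, 5:8)
  l <- rand_nt(24)
  pairs <- make_group_pairs(c(a, b, c_), rep(l, 3))
  comp <- partition_families(pairs, clonal_params(linkage = "complete"))
  expect_equal(length(comp$families), 2L)
  # deterministic merge order: a-b merge first (smallest pair), c stays out
  expect_equal(comp$family_of_cell[["cell001"]],
               comp$family_of_cell[["cell002"]])
  sing <- partition_families(pairs, clonal_params(linkage = "single"))
  expect_equal(length(sing$families), 1L)
})

test_that("partitioning matches the Lance-Williams oracle on random groups", {
  set.seed(44)
  for (rep in 1:60) {
    n <- sample(3:10, 1)
    anc_h <- rand_nt(24); anc_l <- rand_nt(15)
    heavy <- vapply(seq_len(n), function(i)
      mutate_nt(anc_h, sample.int(24, sample(0:8, 1))), "")
    light <- vapply(seq_len(n), function(i)
      mutate_nt(anc_l, sample.int(15, sample(0:5, 1))), "")
    pairs <- make_group_pairs(heavy, light)
    for (lk in c("complete", "single")) {
      part <- partition_families(pairs, clonal_params(linkage = lk))
      mism <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- max(mism(heavy[i], heavy[j]) / 24,
                                  mism(light[i], light[j]) / 15)
      }
      ref <- oracle_agglomerate(d, cutoff = 0.2, linkage = lk)
      ref_fam <- integer(n)
      for (ci in seq_along(ref)) ref_fam[ref[[ci]]] <- ci
      expect_equal(adjusted_rand_index(part$family_of_cell[pairs$cell_id],
                                       ref_fam), 1)
    }
  }
})

test_that("the partition is invariant to input cell order", {
  set.seed(45)
  sim <- simulate_repertoire(repertoire_sim_config(n_cells = 40, n_clones = 8,
                                                   seed = 21))
  pairs <- select_contigs(sim$rearrangements)$pairs
  p1 <- partition_families(pairs)
  p2 <- partition_families(pairs[sample.int(nrow(pairs)), ])
  expect_identical(p1$family_of_cell[sort(names(p1$family_of_cell))],
                   p2$family_of_cell[sort(names(p2$family_of_cell))])
})

test_that("raising the identity threshold never decreases family counts", {
  sim <- simulate_repertoire(repertoire_sim_config(
    n_cells = 50, n_clones = 8, within_clone_divergence = 0.15, seed = 22))
  pairs <- select_contigs(sim$rearrangements)$pairs
  counts <- vapply(c(0.7, 0.8, 0.9, 0.95), function(th)
    length(partition_families(pairs, clonal_params(th))$families), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("family diversity counts distinct families per cluster", {
  fam <- c(a = "F1", b = "F1", c = "F2", d = "F3", e = "F2")
  part <- structure(list(family_of_cell = fam), class = "clonal_partition")
  cl <- c(a = "X", b = "Y", c = "X", d = "Y", e = "Y")
  div <- family_diversity(part, cl)
  expect_equal(div[["X"]], 2L)   # F1, F2
  expect_equal(div[["Y"]], 3L)   # F1, F3, F2
  # every cell its own family
  fam2 <- stats::setNames(paste0("F", 1:5), letters[1:5])
  part2 <- structure(list(family_of_cell = fam2), class = "clonal_partition")
  expect_equal(family_diversity(part2, cl)[["Y"]], 3L)
  expect_error(family_diversity(part, cl[1:3]), "cover")
})

test_that("simpson index matches its closed forms", {
  expect_equal(simpson_index(rep("F1", 7)), 0)
  expect_equal(simpson_index(c("F1", "F1", "F2", "F2")), 0.5)
  n <- 12
  singletons <- paste0("F", seq_len(n))
  expect_equal(simpson_index(singletons), 1 - 1 / n)
  expect_equal(simpson_index(singletons, method = "unbiased"), 1)
  expect_error(simpson_index(character(0)), "empty")
  x <- c(rep("F1", 3), rep("F2", 2), "F3")
  expect_gte(simpson_index(x), 0); expect_lte(simpson_index(x), 1)
})

test_that("overlap table equals the set-intersection oracle", {
  set.seed(46)
  fam <- stats::setNames(sample(paste0("F", 1:12), 60, replace = TRUE),
                         sprintf("c%02d", 1:60))
  cl <- stats::setNames(sample(LETTERS[1:4], 60, replace = TRUE), names(fam))
  part <- structure(list(family_of_cell = fam), class = "clonal_partition")
  ov <- overlap_table(part, cl)
  expect_true(isSymmetric(unname(ov)))
  expect_identical(diag(ov), family_diversity(part, cl)[rownames(ov)])
  for (a in rownames(ov)) for (b in colnames(ov)) {
    expect_equal(ov[a, b],
                 length(intersect(unique(fam[cl == a]), unique(fam[cl == b]))))
  }
  # disjoint family memberships give off-diagonal zeros
  fam2 <- stats::setNames(c("F1", "F1", "F2", "F2"), c("a", "b", "c", "d"))
  cl2 <- c(a = "X", b = "X", c = "Y", d = "Y")
  part2 <- structure(list(family_of_cell = fam2), class = "clonal_partition")
  expect_equal(overlap_table(part2, cl2)["X", "Y"], 0L)
})

test_that("the permutation p-value floors at the add-one estimator", {
  # a family spanning both clusters that no permutation can exceed
  fam <- stats::setNames(rep("F1", 6), sprintf("c%d", 1:6))
  cl <- stats::setNames(rep(c("X", "Y"), 3), names(fam))
  part <- structure(list(family_of_cell = fam), class = "clonal_partition")
  res <- permutation_overlap_test(part, cl, n_perm = 99, seed = 1)
  expect_equal(res$p_value["X", "Y"], 1)  # overlap always 1 under the null too
  # distinct families split across clusters: observed maximal overlap
  fam2 <- stats::setNames(rep(c("F1", "F2", "F3"), each = 2),
                          sprintf("c%d", 1:6))
  cl2 <- stats::setNames(rep(c("X", "Y"), 3), names(fam2))
  part2 <- structure(list(family_of_cell = fam2), class = "clonal_partition")
  res2 <- permutation_overlap_test(part2, cl2, n_perm = 200, seed = 2)
  expect_gte(res2$p_value["X", "Y"], 1 / 201)
  # determinism
  res3 <- permutation_overlap_test(part2, cl2, n_perm = 200, seed = 2)
  expect_identical(res2$p_value, res3$p_value)
})
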