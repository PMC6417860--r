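test_that("the enrichment statistic is exact observed/expected arithmetic", {
  u <- paste0("g", 1:10)
  s <- enrichment_statistic(u[1:5], u[c(1, 2, 3, 9)], u)
  expect_equal(s$fold, (3 / 5) / (4 / 10)) # = 1.5
  expect_equal(s$overlap_count, 3L)

  # gene_set = universe: fold is 1 for any target
  set.seed(1)
  for (k in c(1, 3, 7)) {
    expect_equal(enrichment_statistic(sample(u, k), u, u)$fold, 1.0)
  }

  expect_error(enrichment_statistic(character(0), u[1:2], u), "empty target")
  expect_error(enrichment_statistic(u[1:2], c("zz1", "zz2"), u),
               "no overlap with the universe")
  expect_error(enrichment_statistic(c("g1", "nope"), u[1:2], u),
               "outside the universe")
})

test_that("the statistic reproduces the published fold at published counts", {
  # observed 35/151 over an expected fraction back-computed from the
  # published 78/337 at fold 2.57
  n_univ <- 86609L
  n_set <- 7800L
  u <- sprintf("u%06d", seq_len(n_univ))
  gene_set <- u[seq_len(n_set)]
  target <- c(u[seq_len(35L)], u[(n_set + 1L):(n_set + 116L)])
  s <- enrichment_statistic(target, gene_set, u)
  expect_equal(s$observed_fraction, 35 / 151)
  expect_equal(round(s$fold, 2), 2.57)
})

test_that("permutation p matches the exhaustively enumerated null", {
  # worked instance: universe of 5, set {g1,g2}, target {g1,g3}
  u <- paste0("g", 1:5)
  res <- permutation_pvalue(c("g1", "g3"), c("g1", "g2"), u, n = 20000,
                            seed = 4)
  p_exact <- exhaustive_null_p(u, c("g1", "g2"), 2, res$overlap_count,
                               res$direction)
  expect_equal(p_exact, 0.7)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(res$p_value - p_exact), 3 * mc_se + 2 / 20000)

  # p is (r+1)/(n+1): never zero, and 1 when target = set = universe
  res1 <- permutation_pvalue(u, u, u, n = 500, seed = 1)
  expect_equal(res1$fold, 1.0)
  expect_equal(res1$p_value, 1.0)

  # fixed seed: identical p on repeat runs
  a <- permutation_pvalue(u[1:2], u[1:3], u, n = 2000, seed = 99)
  b <- permutation_pvalue(u[1:2], u[1:3], u, n = 2000, seed = 99)
  expect_identical(a$p_value, b$p_value)
  expect_error(permutation_pvalue(u, u[1:2], u[1:3]), "outside the universe")
})

test_that("permutation p agrees with the hypergeometric tail", {
  set.seed(7)
  u <- sprintf("h%03d", 1:60)
  for (rep in 1:10) {
    m <- sample(5:30, 1)
    k <- sample(5:25, 1)
    gene_set <- sample(u, m)
    target <- sample(u, k)
    res <- permutation_pvalue(target, gene_set, u, n = 4000, seed = rep)
    x <- res$overlap_count
    p_hyper <- if (res$direction == "enriched")
      stats::phyper(x - 1, m, 60 - m, k, lower.tail = FALSE)
    else stats::phyper(x, m, 60 - m, k)
    se <- sqrt(p_hyper * (1 - p_hyper) / 4000)
    expect_lt(abs(res$p_value - p_hyper), 3 * se + 2 / 4000)
  }
})

test_that("fold is invariant under relabeling of gene ids", {
  u <- sprintf("g%02d", 1:40)
  gene_set <- u[1:10]
  target <- u[c(1:4, 20:28)]
  f1 <- enrichment_statistic(target, gene_set, u)$fold
  relab <- stats::setNames(sprintf("X%02d", seq_along(u)), u)
  f2 <- enrichment_statistic(unname(relab[target]), unname(relab[gene_set]),
                             unname(relab))$fold
  expect_identical(f1, f2)
})

test_that("exclusion analysis removes shared-pathway genes before testing", {
  u <- sprintf("e%04d", 1:1000)
  gene_set <- u[1:100]

  # exclusion sets disjoint from the target: identical result
  target <- u[101:150]
  r0 <- permutation_pvalue(target, gene_set, u, n = 1000, seed = 5)
  r1 <- exclusion_enrichment(target, list(u[900:950]), gene_set, u,
                             n = 1000, seed = 5)
  expect_identical(r0$p_value, r1$p_value)
  expect_identical(r0$fold, r1$fold)
  expect_equal(r1$n_after_exclusion, 50L)

  # the enrichment is carried entirely by excluded genes: reduced fold = 1
  target2 <- c(u[1:50], u[101:145], u[96:100]) # 55/100 in set
  full <- enrichment_statistic(target2, gene_set, u)
  expect_equal(full$fold, (55 / 100) / (100 / 1000))
  r2 <- exclusion_enrichment(target2, list(u[1:50]), gene_set, u,
                             n = 1000, seed = 5)
  expect_equal(r2$fold, 1.0) # 5/50 observed vs 100/1000 expected
  expect_equal(r2$n_after_exclusion, 50L)

  # tiny remainder warns; empty remainder errors
  expect_warning(
    exclusion_enrichment(c("e0001", "e0002", "e0003"),
                         list(c("e0002", "e0003")), gene_set, u,
                         n = 200, seed = 1),
    "remain after exclusion")
  expect_error(
    exclusion_enrichment(c("e0001", "e0002"), list(c("e0001", "e0002"))
                         , gene_set, u),
    "removed every target gene")
})

test_that("a screen keeps going when one set fails", {
  set.seed(31)
  u <- sprintf("s%04d", 1:800)
  target <- sample(u, 60)
  collection <- lapply(stats::setNames(1:15, sprintf("set%02d", 1:15)),
                       function(i) sample(u, 40))
  # plant one strongly enriched set and one with no universe overlap
  collection$planted <- c(sample(target, 30), sample(setdiff(u, target), 50))
  collection$orphan <- c("nope1", "nope2")
  scr <- enrichment_screen(target, collection, u, n = 2000, seed = 8)
  expect_equal(scr$set_name, names(collection)) # input order preserved
  expect_equal(sum(scr$status == "ok"), 16)
  expect_match(scr$status[scr$set_name == "orphan"], "no overlap")
  expect_lt(scr$p_value[scr$set_name == "planted"], 0.001)
  expect_equal(scr$log2_fold, log2(scr$fold))
  # per-set seeds derive from set names: collection order cannot matter
  scr_rev <- enrichment_screen(target, rev(collection), u, n = 2000, seed = 8)
  expect_equal(scr_rev[match(scr$set_name, scr_rev$set_name), "p_value"],
               scr$p_value)
})
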