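test_that("a fixed spec and seed give byte-identical fixtures", {
  us <- universe_spec(n_genes = 300, seed = 7)
  ps <- plant_spec(n_targets = 20, n_targets_newly_evolved = 6,
                   library_size = 1e5)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_study(d1, us, ps, n_perm = 50, n_controls = 10)
  simulate_study(d2, us, ps, n_perm = 50, n_controls = 10)
  for (f in c("genes.gff3", "counts.tsv", "homology.tsv", "features.tsv",
              "h3k9me3.bedgraph", "gene_sets.gmt")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("realized newly-evolved fraction matches the spec", {
  u <- generate_universe(universe_spec(n_genes = 1000,
                                       frac_newly_evolved = 0.09, seed = 7))
  ci <- stats::qbinom(c(0.005, 0.995), 1000, 0.09) / 1000 # binomial 99% CI
  frac <- mean(u$newly_evolved)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])

  u0 <- generate_universe(universe_spec(n_genes = 400,
                                        frac_newly_evolved = 0, seed = 7))
  expect_equal(sum(u0$newly_evolved), 0)
  cls <- classify_universe(endosirna:::generate_homology(u0, 7), u0$gene_id)
  expect_equal(sum(cls$classes$conservation_class == "unique_to_focal"), 0)
})

test_that("count noise degenerates to Poisson at dispersion zero", {
  u <- generate_universe(universe_spec(n_genes = 10000, seed = 5))
  ps <- plant_spec(n_targets = 10, n_targets_newly_evolved = 0,
                   nb_dispersion = 0, library_size = 5e5, min_target_rpm = 0)
  cnt <- generate_counts(u, ps, seed = 5, sdlog = 0) # all means = 50
  expect_equal(unname(cnt$wt_mu[1]), 50)
  # mean of 10,000 Poisson(50) draws within 3 standard errors of 50
  se <- sqrt(50 / 10000)
  expect_lt(abs(mean(cnt$counts[, "wt"]) - 50), 3 * se)
})

test_that("planted depletion is recovered by the fold-change rule", {
  u <- generate_universe(universe_spec(n_genes = 2000, seed = 11))
  ps <- plant_spec(n_targets = 30, n_targets_newly_evolved = 8,
                   depletion_factor = 5, nb_dispersion = 0.1,
                   library_size = 1e6)
  flagged <- total <- 0
  for (s in 1:20) {
    cnt <- generate_counts(u, ps, seed = s)
    rpm <- rpm_normalize(cnt$counts)
    res <- fold_change_classify(rpm[, "wt"], rpm[, "mutant"])
    flagged <- flagged + sum(cnt$planted %in% res$down$genes)
    total <- total + length(cnt$planted)
  }
  expect_gte(flagged / total, 0.9)
})

test_that("unplanted genes under the null show a bounded, measured down-rate", {
  u <- generate_universe(universe_spec(n_genes = 2000, seed = 11))
  # depletion barely above 1: effectively a null experiment
  ps <- plant_spec(n_targets = 1, n_targets_newly_evolved = 0,
                   depletion_factor = 1.0001, nb_dispersion = 0.1,
                   library_size = 1e6)
  rates <- vapply(1:10, function(s) {
    cnt <- generate_counts(u, ps, seed = s)
    rpm <- rpm_normalize(cnt$counts)
    res <- fold_change_classify(rpm[, "wt"], rpm[, "mutant"])
    mean(setdiff(u$gene_id, cnt$planted) %in% res$down$genes)
  }, numeric(1))
  expect_gt(mean(rates), 0)       # the single-replicate rule is not FP-free
  expect_lt(mean(rates), 0.2)     # but stays far from the planted regime
  expect_lt(stats::sd(rates), 0.02) # and is stable across seeds
})

test_that("signal generator plants TSS elevation only when asked", {
  u <- generate_universe(universe_spec(n_genes = 240, seed = 13))
  genes <- u
  flagged <- genes[genes$newly_evolved, ]
  other <- genes[!genes$newly_evolved, ]

  # zero noise, elevation 1: perfectly constant track everywhere
  tr1 <- generate_signal(u, elevation = 1, seed = 1, noise_sd = 0)
  prof <- extract_gene_signal(tr1, other[1, ], window = 500, bin = 10)
  expect_true(all(prof == 1))

  # zero noise, elevation 3: flagged genes exactly 3x in the TSS window,
  # baseline off the window
  tr3 <- generate_signal(u, elevation = 3, seed = 1, noise_sd = 0)
  pf <- extract_gene_signal(tr3, flagged[1, ], window = 500, bin = 10)
  ctr <- which(abs(as.numeric(names(pf))) <= 200)
  expect_true(all(pf[ctr] == 3))
  expect_true(all(pf[abs(as.numeric(names(pf))) > 300] %in% c(1, 3)))

  # elevation 1 with noise: flagged set indistinguishable from controls
  trn <- generate_signal(u, elevation = 1, seed = 2, noise_sd = 0.2)
  mg <- metagene(trn, flagged, window = 500, bin = 10)
  cb <- control_band(trn, genes, set_size = nrow(flagged), n_sets = 150,
                     seed = 3, window = 500, bin = 10)
  inside <- mg$mean_signal >= cb$control_low & mg$mean_signal <= cb$control_high
  expect_gte(mean(inside), 0.85)

  expect_error(generate_signal(u, elevation = 0.5, seed = 1), ">= 1")
})

test_that("every generated file passes its own reader cleanly", {
  us <- universe_spec(n_genes = 250, seed = 21)
  ps <- plant_spec(n_targets = 15, n_targets_newly_evolved = 5,
                   library_size = 1e5)
  d <- file.path(tempdir(), "sim_clean")
  fix <- simulate_study(d, us, ps, n_perm = 50, n_controls = 10)
  expect_no_warning({
    u <- read_gff_genes(fix$paths$gff)
    cnt <- read_counts(fix$paths$counts)
    hom <- read_homology(fix$paths$homology)
    feat <- read_feature_table(fix$paths$features)
    trk <- read_bedgraph(fix$paths$bedgraph)
    sets <- read_gmt(fix$paths$gene_sets)
  })
  # the GFF3 round-trips the generator's gene models exactly
  u <- u[match(fix$universe$gene_id, u$gene_id), ]
  expect_equal(u$tss, fix$universe$tss)
  expect_equal(u$strand, fix$universe$strand)
  expect_equal(u$intron_count_mean, fix$universe$intron_count_mean)
  expect_equal(u$cds_length, fix$universe$cds_length)
  expect_equal(sort(rownames(cnt)), sort(fix$universe$gene_id))
  expect_equal(length(sets), 15L)
})

test_that("spec validation rejects impossible settings", {
  expect_error(universe_spec(n_genes = 0), "n_genes")
  expect_error(universe_spec(frac_newly_evolved = 0.7, frac_genus_only = 0.5),
               "<= 1")
  expect_error(plant_spec(depletion_factor = 1), "> 1")
  expect_error(plant_spec(n_targets = 10, n_targets_newly_evolved = 11),
               "n_targets_newly_evolved")
  u <- generate_universe(universe_spec(n_genes = 50, seed = 1))
  expect_error(generate_counts(u, plant_spec(n_targets = 60), seed = 1),
               "exceeds universe")
})
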