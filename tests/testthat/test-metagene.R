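test_that("signal extraction matches a per-bp brute-force oracle", {
  set.seed(19)
  for (rep in 1:6) {
    # random track with irregular bins and gaps on a 400 bp chromosome
    cuts <- sort(sample(0:400, sample(6:14, 1)))
    cuts <- unique(c(0, cuts, 400))
    df <- data.frame(chrom = "chrI", start = head(cuts, -1),
                     end = tail(cuts, -1),
                     value = round(runif(length(cuts) - 1), 3))
    df <- df[runif(nrow(df)) > 0.25, ] # knock out bins -> coverage gaps
    if (!nrow(df)) next
    track <- make_track(df$chrom, df$start, df$end, df$value)
    for (strand in c("+", "-")) {
      tss <- sample(50:350, 1)
      g <- tiny_universe(tss, strand)[1, ]
      got <- extract_gene_signal(track, g, window = 60, bin = 10)
      want <- brute_signal(df, "chrI", tss, strand, window = 60, bin = 10)
      expect_equal(unname(got), want, tolerance = 1e-12,
                   label = sprintf("rep %d strand %s tss %d", rep, strand, tss))
    }
  }
})

test_that("constant tracks give exactly constant profiles on both strands", {
  track <- make_track("chrI", 0, 5000, 2.5)
  for (strand in c("+", "-")) {
    g <- tiny_universe(2500, strand)[1, ]
    v <- extract_gene_signal(track, g, window = 1000, bin = 10)
    expect_true(all(v == 2.5))
    expect_length(v, 200)
  }
})

test_that("minus-strand genes are mirrored around the TSS", {
  # signal 9 one bp wide at genomic tss+10; everything else 0
  tss <- 200
  track <- make_track(rep("chrI", 3), c(0, tss + 10, tss + 11),
                      c(tss + 10, tss + 11, 400), c(0, 9, 0))
  gm <- tiny_universe(tss, "-")[1, ]
  v <- extract_gene_signal(track, gm, window = 20, bin = 1)
  pos <- as.numeric(names(v))
  expect_equal(unname(v[pos == -10 + 0.5]), 9) # bin [-10,-9) holds d = -10
  expect_true(all(v[pos != -10 + 0.5] == 0))
  gp <- tiny_universe(tss, "+")[1, ]
  vp <- extract_gene_signal(track, gp, window = 20, bin = 1)
  expect_equal(unname(vp[as.numeric(names(vp)) == 10 + 0.5]), 9)
})

test_that("chromosome edges yield missing values, not zeros", {
  track <- make_track("chrI", 0, 3000, 1)
  g <- tiny_universe(200, "+")[1, ]
  v <- extract_gene_signal(track, g, window = 1000, bin = 10)
  pos <- as.numeric(names(v))
  expect_true(all(is.na(v[pos < -200])))
  expect_true(all(v[pos > -190] == 1))
  expect_error(extract_gene_signal(track, tiny_universe(5, "+", "chrZ")[1, ],
                                   window = 100, bin = 10),
               "unknown chromosome")
  expect_error(extract_gene_signal(track, g, window = 105, bin = 10),
               "multiple of bin")
})

test_that("the metagene is the position-wise mean, order-invariant", {
  # two '+' genes whose windows sit on steps of value 1|3 and 3|5
  track <- make_track(rep("chrI", 4), c(90, 100, 290, 300),
                      c(100, 110, 300, 310), c(1, 3, 3, 5))
  genes <- tiny_universe(c(100, 300), c("+", "+"))
  mg <- suppressWarnings(metagene(track, genes, window = 10, bin = 10))
  expect_equal(unname(mg$mean_signal), c(2, 4))
  one <- suppressWarnings(metagene(track, genes[1, ], window = 10, bin = 10))
  expect_equal(unname(one$mean_signal), c(1, 3))
  flipped <- suppressWarnings(metagene(track, genes[2:1, ], window = 10,
                                       bin = 10))
  expect_equal(flipped$mean_signal, mg$mean_signal)
})

test_that("positions with no data in any gene are flagged", {
  track <- make_track("chrI", 100, 120, 1) # tiny covered island
  genes <- tiny_universe(c(110, 112), c("+", "+"))
  expect_warning(mg <- metagene(track, genes, window = 100, bin = 10),
                 "no data in any gene")
  expect_true(any(is.na(mg$mean_signal)))
  expect_true(any(mg$n_per_position == 0))
})

test_that("control bands collapse on constant tracks and are seeded", {
  track <- make_track("chrI", 0, 60000, 1.25)
  genes <- tiny_universe(seq(2000, 58000, by = 1000), "+")
  cb <- control_band(track, genes, set_size = 10, n_sets = 50, seed = 3,
                     window = 500, bin = 50)
  expect_true(all(cb$control_low == 1.25))
  expect_true(all(cb$control_high == 1.25))
  cb2 <- control_band(track, genes, set_size = 10, n_sets = 50, seed = 3,
                      window = 500, bin = 50)
  expect_identical(cb, cb2)

  expect_error(control_band(track, genes, set_size = 10, n_sets = 1),
               "at least 2")
  expect_error(control_band(track, genes, set_size = 1e5, n_sets = 10),
               "exceeds universe")
  expect_error(control_band(track, genes, set_size = 5, n_sets = 10,
                            quantiles = c(0.9, 0.1)), "degenerate quantiles")
})

test_that("flagged genes exceed the control band near the TSS at elevation 3", {
  u <- generate_universe(universe_spec(n_genes = 400, seed = 29))
  track <- generate_signal(u, elevation = 3, seed = 29, noise_sd = 0.2)
  prof <- metagene_profile(track, u[u$newly_evolved, ], u, window = 1000,
                           bin = 10, n_controls = 200, seed = 31)
  near <- abs(prof$positions) <= 200
  expect_true(all(prof$mean_signal[near] > prof$control_high[near]))
  # determinism of the whole profile object
  prof2 <- metagene_profile(track, u[u$newly_evolved, ], u, window = 1000,
                            bin = 10, n_controls = 200, seed = 31)
  expect_identical(as.data.frame(prof), as.data.frame(prof2))
})

test_that("a random gene set sits inside its own control band", {
  u <- generate_universe(universe_spec(n_genes = 300, seed = 37))
  track <- generate_signal(u, elevation = 2, seed = 37, noise_sd = 0.3)
  mat <- endosirna:::metagene_matrix(track, u, window = 400, bin = 20)
  n_sets <- 40L
  cb <- control_band(track, u, set_size = 25, n_sets = n_sets,
                     quantiles = c(0.5 / n_sets, 1 - 0.5 / n_sets),
                     seed = 41, window = 400, bin = 20, gene_matrix = mat)
  set.seed(43)
  inside <- replicate(100, {
    own <- colMeans(mat[sample.int(nrow(u), 25), ], na.rm = TRUE)
    mean(own >= cb$control_low & own <= cb$control_high)
  })
  # band covers 1 - 1/n_sets = 97.5% nominally; allow Monte-Carlo slack
  expect_gte(mean(inside), 0.9)
})
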