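## Synthetic study generator.
##
## Emulates the statistical structure of the real inputs — a ~20,000-gene
## protein-coding universe with a ~9% newly-evolved background, endo-siRNA
## count libraries with a planted >=2-fold depletion in the mutant, elevated
## H3K9me3 around the TSS of newly-evolved genes, and per-gene feature tables
## with a modestly lower PATC density on newly-evolved genes — so every
## downstream stage can be exercised end-to-end without any download.
## Everything is driven by integer seeds through R's Mersenne-Twister; a
## fixed spec and seed give byte-identical files.

GENUS_SPECIES <- c("C_brenneri", "C_briggsae", "C_remanei", "C_japonica")
OUTGROUP_SPECIES <- c("B_malayi", "O_volvulus", "P_pacificus", "S_ratti")
CHROMS <- c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrX")

#' Specification of a synthetic gene universe
#'
#' Defaults describe the study conditions: a nematode-sized protein-coding
#' universe in which roughly 9% of genes are newly evolved (no ortholog
#' outside the focal species), about a third carry a within-species paralog,
#' PATC density is log-normal with a ~10% lower median on newly-evolved
#' genes, intron counts are Poisson with a genome-like mean, and
#' newly-evolved genes carry `h3k9me3_elevation`-fold H3K9me3 around their
#' TSS.
#'
#' @param n_genes number of protein-coding genes.
#' @param frac_newly_evolved fraction of genes with no orthologs at all.
#' @param frac_genus_only fraction with orthologs only within the genus.
#' @param frac_duplicated fraction carrying a same-species paralog.
#' @param patc_lognormal_params `c(meanlog, sdlog)` of background PATC
#'   density (arbitrary density units).
#' @param patc_newly_evolved_factor multiplicative shift of the median PATC
#'   density of newly-evolved genes, applied on the log2(x+1) display scale
#'   on which density medians are summarized (< 1 means lower).
#' @param intron_poisson_mean mean intron count per transcript.
#' @param h3k9me3_elevation multiplicative H3K9me3 factor (>= 1) applied in a
#'   window around the TSS of newly-evolved genes.
#' @param seed integer; fully determines all generated output.
#' @return a `universe_spec` list.
#' @export
universe_spec <- function(n_genes = 20000L, frac_newly_evolved = 0.09,
                          frac_genus_only = 0.16, frac_duplicated = 0.33,
                          patc_lognormal_params = c(meanlog = 2, sdlog = 1),
                          patc_newly_evolved_factor = 0.9,
                          intron_poisson_mean = 4.5,
                          h3k9me3_elevation = 3, seed = 1L) {
  check_scalar_number(n_genes, "n_genes", lower = 1)
  check_scalar_number(frac_newly_evolved, "frac_newly_evolved", 0, 1)
  check_scalar_number(frac_genus_only, "frac_genus_only", 0, 1)
  if (frac_newly_evolved + frac_genus_only > 1)
    stop_format("frac_newly_evolved + frac_genus_only must be <= 1")
  check_scalar_number(frac_duplicated, "frac_duplicated", 0, 1)
  check_scalar_number(h3k9me3_elevation, "h3k9me3_elevation", lower = 1)
  check_scalar_number(intron_poisson_mean, "intron_poisson_mean", lower = 0)
  structure(list(n_genes = as.integer(n_genes),
                 frac_newly_evolved = frac_newly_evolved,
                 frac_genus_only = frac_genus_only,
                 frac_duplicated = frac_duplicated,
                 patc_lognormal_params = patc_lognormal_params,
                 patc_newly_evolved_factor = patc_newly_evolved_factor,
                 intron_poisson_mean = intron_poisson_mean,
                 h3k9me3_elevation = h3k9me3_elevation,
                 seed = as.integer(seed)),
            class = "universe_spec")
}

#' Specification of the planted endo-siRNA depletion
#'
#' Defaults mirror the scale of the study's mutant comparison: 151 target
#' genes of which 35 are newly evolved, a 5-fold loss of targeting
#' endo-siRNAs in the mutant, negative-binomial count noise and a
#' one-million-read library. The default dispersion (0.02) makes the null
#' spread of single-replicate fold changes small enough that the 2-fold
#' rule calls a target-set-sized gene list (hundreds of genes in a
#' 20,000-gene universe), the regime the analysis operates in.
#'
#' @param n_targets number of planted target genes.
#' @param n_targets_newly_evolved how many of them are newly evolved.
#' @param depletion_factor mutant mean counts of planted genes are divided by
#'   this (> 1).
#' @param nb_dispersion negative-binomial dispersion; 0 degenerates to
#'   Poisson.
#' @param library_size expected total mapped reads per sample.
#' @param min_target_rpm planted targets are drawn only among genes whose
#'   wild-type expected level is at least this many RPM. Target sets are by
#'   definition genes with *detected* endo-siRNAs: under the fold-change
#'   rule a gene below ~5/3 RPM cannot show a 2-fold loss even in
#'   expectation, so planting depletion there would specify an unobservable
#'   effect. The default matches the observed dynamic-range floor of
#'   changed genes (about 2^4 RPM).
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(n_targets = 151L, n_targets_newly_evolved = 35L,
                       depletion_factor = 5, nb_dispersion = 0.02,
                       library_size = 1e6, min_target_rpm = 16) {
  check_scalar_number(n_targets, "n_targets", lower = 1)
  check_scalar_number(n_targets_newly_evolved, "n_targets_newly_evolved",
                      0, n_targets)
  if (depletion_factor <= 1)
    stop_format("depletion_factor must be > 1 (got %s)", depletion_factor)
  check_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_scalar_number(library_size, "library_size", lower = 1)
  structure(list(n_targets = as.integer(n_targets),
                 n_targets_newly_evolved = as.integer(n_targets_newly_evolved),
                 depletion_factor = depletion_factor,
                 nb_dispersion = nb_dispersion,
                 library_size = library_size,
                 min_target_rpm = min_target_rpm),
            class = "plant_spec")
}

# deterministic exon layout for a transcript with k introns inside
# [start0, start0 + len): alternating equal-width exon/intron blocks, last
# exon padded to the gene end. Returns a 2-column matrix of 0-based
# half-open exon intervals.
exon_layout <- function(start0, len, k) {
  k <- min(k, (len - 1L) %/% 2L)
  unit <- len %/% (2L * k + 1L)
  s <- start0 + (0:k) * 2L * unit
  e <- s + unit
  e[k + 1L] <- start0 + len
  cbind(start = s, end = e)
}

#' Generate a synthetic gene universe
#'
#' Draws gene coordinates, strands, transcript structures, conservation
#' classes, paralog flags and feature values according to a
#' [universe_spec()].
#'
#' @param spec a [universe_spec()].
#' @return a `gene_universe` data.frame carrying, beyond the gene-model
#'   columns of [read_gff_genes()], the generating truth: `conservation_class`,
#'   `newly_evolved`, `duplicated`, `patc_density`, `splicing_divergence` and
#'   a `gene_len` column. The spec is attached as attribute `spec`.
#' @export
generate_universe <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  n <- spec$n_genes
  with_seed(derive_seed(spec$seed, "universe"), {
    gene_id <- sprintf("gene%05d", seq_len(n))
    chrom <- CHROMS[((seq_len(n) - 1L) %% length(CHROMS)) + 1L]
    idx_on_chrom <- ((seq_len(n) - 1L) %/% length(CHROMS))
    gene_len <- sample(seq(600L, 2400L, by = 200L), n, replace = TRUE)
    gstart <- 2000L + idx_on_chrom * 3000L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tss <- ifelse(strand == "+", gstart, gstart + gene_len - 1L)

    cls <- sample(c("unique_to_focal", "genus_only", "conserved_among_nematodes"),
                  n, replace = TRUE,
                  prob = c(spec$frac_newly_evolved, spec$frac_genus_only,
                           1 - spec$frac_newly_evolved - spec$frac_genus_only))
    newly <- cls == "unique_to_focal"
    duplicated <- stats::runif(n) < spec$frac_duplicated

    n_tx <- pmin(1L + stats::rpois(n, 0.5), 3L)
    intron_mean <- spec$intron_poisson_mean * ifelse(newly, 0.75, 1)
    intron_counts <- vector("list", n)
    cds_length <- integer(n)
    for (i in seq_len(n)) {
      k <- pmin(stats::rpois(n_tx[i], intron_mean[i]), 20L)
      k <- pmin(k, (gene_len[i] - 1L) %/% 2L)
      intron_counts[[i]] <- as.integer(k)
      # coding length of the longest coding transcript = fewest introns
      lay <- exon_layout(gstart[i], gene_len[i], min(k))
      cds_length[i] <- as.integer(sum(lay[, "end"] - lay[, "start"]))
    }

    # the PATC reduction of newly-evolved genes is specified on the
    # log2(x+1) display scale, the scale on which density medians are
    # conventionally summarized
    med_bg <- exp(spec$patc_lognormal_params[[1L]])
    med_ne <- max(2^(spec$patc_newly_evolved_factor * log2(med_bg + 1)) - 1,
                  1e-6)
    patc <- stats::rlnorm(n, meanlog = ifelse(newly, log(med_ne), log(med_bg)),
                          sdlog = spec$patc_lognormal_params[[2L]])
    spl <- stats::rnorm(n, mean = 0, sd = 1)

    out <- data.frame(gene_id = gene_id, chrom = chrom, tss = as.integer(tss),
                      strand = strand, cds_length = cds_length,
                      n_transcripts = n_tx, stringsAsFactors = FALSE)
    out$intron_counts <- intron_counts
    out$intron_count_mean <- vapply(intron_counts, mean, numeric(1))
    out$gene_start <- gstart
    out$gene_len <- gene_len
    out$conservation_class <- cls
    out$newly_evolved <- newly
    out$duplicated <- duplicated
    out$patc_density <- patc
    out$splicing_divergence <- spl
    attr(out, "spec") <- spec
    class(out) <- c("gene_universe", "data.frame")
    out
  })
}

#' Generate wild-type and mutant count libraries with planted depletion
#'
#' Per-gene expected counts are log-normal across genes (scaled to the
#' library size); observed counts are negative binomial around them
#' (Poisson when `nb_dispersion = 0`). Planted target genes have their
#' mutant means divided by `depletion_factor`. Planted genes are drawn
#' preferentially from newly-evolved genes so the downstream conservation
#' enrichment has the structure the study reports.
#'
#' @param universe a `gene_universe` from [generate_universe()].
#' @param plant a [plant_spec()].
#' @param seed integer seed.
#' @param meanlog,sdlog log-normal parameters of the per-gene expected
#'   counts before library scaling.
#' @return list with `counts` (gene x sample integer matrix, samples `wt`
#'   and `mutant`), `planted` (character vector of planted gene ids) and the
#'   expected means `wt_mu`, `mut_mu`.
#' @export
generate_counts <- function(universe, plant, seed, meanlog = log(30), sdlog = 1) {
  stopifnot(inherits(plant, "plant_spec"))
  n <- nrow(universe)
  if (plant$n_targets > n) stop_format("n_targets exceeds universe size")
  with_seed(derive_seed(seed, "counts"), {
    base <- stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    wt_mu <- base / sum(base) * plant$library_size
    names(wt_mu) <- universe$gene_id
    # targets are genes with detected endo-siRNAs: plant only where the
    # depletion is observable under the fold-change rule
    expressed <- wt_mu / plant$library_size * 1e6 >= plant$min_target_rpm
    ne_pool <- universe$gene_id[universe$newly_evolved & expressed]
    other_pool <- universe$gene_id[!universe$newly_evolved & expressed]
    n_ne <- min(plant$n_targets_newly_evolved, length(ne_pool))
    if (length(other_pool) < plant$n_targets - n_ne)
      stop_format("not enough expressed genes to plant %d targets",
                  plant$n_targets)
    planted <- c(sample(ne_pool, n_ne),
                 sample(other_pool, plant$n_targets - n_ne))
    mut_mu <- wt_mu
    mut_mu[planted] <- mut_mu[planted] / plant$depletion_factor

    draw <- function(mu) {
      if (plant$nb_dispersion == 0) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / plant$nb_dispersion)
    }
    counts <- cbind(wt = draw(wt_mu), mutant = draw(mut_mu))
    rownames(counts) <- universe$gene_id
    list(counts = counts, planted = sort(planted), wt_mu = wt_mu,
         mut_mu = mut_mu)
  })
}

#' Generate a binned H3K9me3-like signal track
#'
#' Background is a constant baseline plus (optionally) autocorrelated
#' noise; genes flagged as newly evolved receive `elevation`-fold signal in
#' a window around their TSS.
#'
#' @param universe a `gene_universe`.
#' @param elevation multiplicative factor >= 1 on flagged genes.
#' @param seed integer seed.
#' @param bin bin width in bp.
#' @param baseline background signal level.
#' @param noise_sd marginal standard deviation of the AR(1) background
#'   noise; 0 gives a perfectly constant background.
#' @param ar_rho lag-1 autocorrelation of the background noise.
#' @param flank half-width (bp) of the elevated window around the TSS.
#' @return a `signal_track`.
#' @export
generate_signal <- function(universe, elevation = 3, seed = 1L, bin = 10L,
                            baseline = 1, noise_sd = 0.2, ar_rho = 0.7,
                            flank = 250L) {
  if (elevation < 1) stop_format("elevation must be >= 1")
  with_seed(derive_seed(seed, "signal"), {
    pieces <- lapply(split(universe, universe$chrom), function(d) {
      L <- max(d$tss) + 2000L
      nb <- ceiling(L / bin)
      val <- rep(baseline, nb)
      if (noise_sd > 0) {
        eps <- stats::rnorm(nb, sd = noise_sd * sqrt(1 - ar_rho^2))
        val <- val + as.numeric(stats::filter(eps, ar_rho, method = "recursive"))
        val <- pmax(val, 0)
      }
      flagged <- d[d$newly_evolved, , drop = FALSE]
      if (nrow(flagged)) {
        for (i in seq_len(nrow(flagged))) {
          lo <- max(0L, (flagged$tss[i] - flank) %/% bin)
          hi <- min(nb - 1L, (flagged$tss[i] + flank) %/% bin)
          val[(lo:hi) + 1L] <- val[(lo:hi) + 1L] * elevation
        }
      }
      data.frame(chrom = d$chrom[1L], start = (seq_len(nb) - 1L) * bin,
                 end = pmin(seq_len(nb) * bin, L), value = val,
                 stringsAsFactors = FALSE)
    })
    new_signal_track(do.call(rbind, pieces))
  })
}

#' Lower the PATC density of planted target genes
#'
#' Re-draws the PATC density of the planted genes from the same reduced
#' distribution used for newly-evolved genes, so that the planted target
#' list shows the moderate (~10% of the log2-scale median) PATC reduction
#' that distinguishes endo-siRNA target genes.
#'
#' @param universe a `gene_universe` from [generate_universe()].
#' @param planted character vector of planted target gene ids.
#' @param seed integer seed.
#' @return the universe with updated `patc_density` for the planted genes.
#' @export
plant_patc_shift <- function(universe, planted, seed) {
  spec <- attr(universe, "spec")
  if (is.null(spec)) stop_format("universe carries no generator spec")
  idx <- match(planted, universe$gene_id)
  if (anyNA(idx)) stop_format("planted genes missing from universe")
  med_bg <- exp(spec$patc_lognormal_params[[1L]])
  med_lo <- max(2^(spec$patc_newly_evolved_factor * log2(med_bg + 1)) - 1,
                1e-6)
  with_seed(derive_seed(seed, "patc_plant"), {
    universe$patc_density[idx] <-
      stats::rlnorm(length(idx), meanlog = log(med_lo),
                    sdlog = spec$patc_lognormal_params[[2L]])
  })
  universe
}

# Homology rows realizing each gene's conservation class and paralog flag.
generate_homology <- function(universe, seed) {
  with_seed(derive_seed(seed, "homology"), {
    n <- nrow(universe)
    cls <- universe$conservation_class
    n_genus <- ifelse(cls == "unique_to_focal", 0L,
                      1L + stats::rbinom(n, 3L, 0.5))
    n_out <- ifelse(cls == "conserved_among_nematodes",
                    1L + stats::rbinom(n, 3L, 0.5), 0L)
    sp <- lapply(seq_len(n), function(i) {
      c(if (n_genus[i]) sample(GENUS_SPECIES, n_genus[i]) else character(0),
        if (n_out[i]) sample(OUTGROUP_SPECIES, n_out[i]) else character(0))
    })
    gene <- rep(universe$gene_id, lengths(sp))
    spv <- unlist(sp)
    orth <- if (length(gene))
      data.frame(gene_id = gene, type = "ortholog", species = spv,
                 partner_id = paste0(spv, "_", gene),
                 stringsAsFactors = FALSE)
    else NULL
    dup_idx <- which(universe$duplicated)
    par <- NULL
    if (length(dup_idx)) {
      # random partner offset in 1..n-1 guarantees mate != self
      mate_idx <- ((dup_idx - 1L +
                      sample.int(n - 1L, length(dup_idx), replace = TRUE)) %% n) + 1L
      par <- data.frame(gene_id = universe$gene_id[dup_idx], type = "paralog",
                        species = "C_elegans",
                        partner_id = universe$gene_id[mate_idx],
                        stringsAsFactors = FALSE)
    }
    out <- rbind(orth, par)
    rownames(out) <- NULL
    class(out) <- c("homology_table", "data.frame")
    out
  })
}

# GFF3 emission of the universe's gene models (1-based inclusive on disk).
write_universe_gff <- function(universe, path) {
  chunks <- vector("list", nrow(universe))
  for (i in seq_len(nrow(universe))) {
    g <- universe[i, ]
    gs <- g$gene_start + 1L
    ge <- g$gene_start + g$gene_len
    gl <- sprintf("%s\tendosirna\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=protein_coding",
                  g$chrom, gs, ge, g$strand, g$gene_id)
    ks <- g$intron_counts[[1L]]
    tx <- lapply(seq_along(ks), function(t) {
      tid <- sprintf("%s.t%d", g$gene_id, t)
      lay <- exon_layout(g$gene_start, g$gene_len, ks[t])
      c(sprintf("%s\tendosirna\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                g$chrom, gs, ge, g$strand, tid, g$gene_id),
        sprintf("%s\tendosirna\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                g$chrom, lay[, 1L] + 1L, lay[, 2L], g$strand, tid),
        sprintf("%s\tendosirna\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                g$chrom, lay[, 1L] + 1L, lay[, 2L], g$strand, tid))
    })
    chunks[[i]] <- c(gl, unlist(tx))
  }
  writeLines(c("##gff-version 3", unlist(chunks)), path)
  invisible(path)
}

#' Generate a gene-set collection with planted structure
#'
#' Builds a 15-set collection shaped like the published one (tissue
#' expression sets, Argonaute pathway target sets, piRNA targets): pathway
#' sets that should come out enriched among planted targets
#' (`hrde1_targets`, `wago1_targets`, `mutator_targets`, `ergo1_targets`,
#' `pirna_targets`) absorb a planted fraction of the target list, the
#' licensing-pathway set `csr1_targets` avoids targets, and tissue sets are
#' random draws.
#'
#' @param universe a `gene_universe`.
#' @param targets character vector of (planted) target gene ids.
#' @param seed integer seed.
#' @return named list of gene-id character vectors.
#' @export
generate_gene_sets <- function(universe, targets, seed) {
  ids <- universe$gene_id
  n <- length(ids)
  sizes <- c(germline_oocyte = 0.39, germline_sperm = 0.45, neurons = 0.57,
             intestine = 0.36, pharynx = 0.15, muscle = 0.13,
             csr1_targets = 0.21, hrde1_targets = 0.074,
             wago1_targets = 0.0044, alg34_targets = 0.02,
             mutator_targets = 0.091, ego1_targets = 0.036,
             ergo1_ip_targets = 0.0025, ergo1_depleted = 0.0039,
             pirna_targets = 0.017)
  take <- c(hrde1_targets = 0.5, wago1_targets = 0.15, mutator_targets = 0.4,
            ergo1_ip_targets = 0.1, ergo1_depleted = 0.1,
            pirna_targets = 0.3, germline_oocyte = 0.5)
  with_seed(derive_seed(seed, "gene_sets"), {
    sets <- vector("list", length(sizes))
    names(sets) <- names(sizes)
    for (nm in names(sizes)) {
      size <- max(5L, round(sizes[[nm]] * n))
      planted_in <- if (nm %in% names(take))
        sample(targets, min(round(take[[nm]] * length(targets)), size))
      else character(0)
      pool <- if (nm == "csr1_targets") setdiff(ids, targets)
              else setdiff(ids, planted_in)
      sets[[nm]] <- sort(c(planted_in, sample(pool, size - length(planted_in))))
    }
    sets
  })
}

#' Write a complete synthetic study fixture to a directory
#'
#' Produces every input of [run_pipeline()]: a GFF3 with gene models, a
#' wild-type/mutant count table, a homology table, a feature table, a binned
#' H3K9me3 bedGraph, a 15-set GMT collection and a ready-to-run YAML config.
#'
#' @param dir output directory (created if missing).
#' @param uspec a [universe_spec()].
#' @param pspec a [plant_spec()].
#' @param seed master seed for everything downstream of the universe spec.
#' @param n_perm,n_controls pipeline parameters written into the config.
#' @return invisibly, a list with the file `paths`, the `universe` and the
#'   planted truth.
#' @export
simulate_study <- function(dir, uspec = universe_spec(),
                           pspec = plant_spec(), seed = uspec$seed,
                           n_perm = 2000L, n_controls = 200L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  universe <- generate_universe(uspec)
  cnt <- generate_counts(universe, pspec, seed)
  universe <- plant_patc_shift(universe, cnt$planted, seed)
  track <- generate_signal(universe, elevation = uspec$h3k9me3_elevation,
                           seed = seed)
  homology <- generate_homology(universe, seed)
  sets <- generate_gene_sets(universe, cnt$planted, seed)

  p <- function(f) file.path(dir, f)
  paths <- list(gff = p("genes.gff3"), counts = p("counts.tsv"),
                homology = p("homology.tsv"), features = p("features.tsv"),
                bedgraph = p("h3k9me3.bedgraph"), gene_sets = p("gene_sets.gmt"),
                config = p("config.yaml"))
  write_universe_gff(universe, paths$gff)
  write_counts(cnt$counts, paths$counts)
  write_homology(homology, paths$homology)
  write_feature_table(universe[, c("gene_id", "patc_density",
                                   "splicing_divergence", "intron_count_mean",
                                   "cds_length")], paths$features)
  write_bedgraph(track, paths$bedgraph)
  write_gmt(sets, paths$gene_sets)

  cfg <- list(counts = paths$counts, gff = paths$gff,
              gene_sets = paths$gene_sets, bedgraph = paths$bedgraph,
              homology = paths$homology, features = paths$features,
              outdir = file.path(dir, "results"), seed = as.integer(seed),
              classifier = list(up_threshold = 2, down_threshold = 0.5,
                                pseudocount_rpm = 1),
              enrichment = list(n_perm = as.integer(n_perm),
                                exclude_sets = c("hrde1_targets",
                                                 "ergo1_ip_targets",
                                                 "wago1_targets",
                                                 "mutator_targets")),
              metagene = list(window = 1000L, bin = 10L,
                              n_controls = as.integer(n_controls)),
              conservation = list(genus_species = GENUS_SPECIES,
                                  outgroup_species = OUTGROUP_SPECIES))
  yaml::write_yaml(cfg, paths$config)
  invisible(list(paths = paths, universe = universe, planted = cnt$planted,
                 counts = cnt$counts))
}
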