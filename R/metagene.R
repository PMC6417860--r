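## Strand-aware TSS metagene profiles of binned chromatin signal, with a
## control band built from random same-size gene sets.
##
## Per-bp convention: for a '+' gene a base at genomic position p has
## relative offset d = p - tss; for a '-' gene d = tss - p. Relative bin i
## collects offsets d in [-W + i*b, -W + (i+1)*b); its value is the
## coverage-weighted mean of the track over the corresponding genomic
## interval, and NA where the track has no coverage (chromosome edges are
## missing data, never zeros).

rel_bin_starts <- function(window, bin) seq(-window, window - bin, by = bin)

# per-gene signal matrix (genes x relative bins) for a set of gene models
metagene_matrix <- function(track, genes, window = 1000L, bin = 10L) {
  if (window %% bin != 0) stop_format("window must be a multiple of bin")
  if (!nrow(genes)) stop_format("empty gene set")
  x <- rel_bin_starts(window, bin)
  m <- length(x)
  out <- matrix(NA_real_, nrow(genes), m,
                dimnames = list(genes$gene_id, x + bin / 2))
  for (cn in unique(genes$chrom)) {
    sel <- which(genes$chrom == cn)
    tss <- genes$tss[sel]
    plus <- genes$strand[sel] == "+"
    # genomic start of the interval for relative bin start x:
    #   '+' : [tss + x, tss + x + b)
    #   '-' : [tss - x - b + 1, tss - x + 1)
    lo <- outer(tss, x, function(t, xx) t + xx)
    lo[!plus, ] <- outer(tss[!plus], x, function(t, xx) t - xx - bin + 1L)
    vals <- track_interval_mean(track, cn, as.vector(lo), as.vector(lo) + bin)
    out[sel, ] <- matrix(vals, nrow = length(sel))
  }
  out
}

#' Extract the TSS-anchored signal vector of one gene
#'
#' @param track a `signal_track` (see [read_bedgraph()]).
#' @param gene a one-row `gene_universe` data.frame (or list) with `chrom`,
#'   `tss` (0-based), `strand`.
#' @param window half-width of the profile in bp (default 1000).
#' @param bin bin width in bp (must divide `window`).
#' @return numeric vector of length `2 * window / bin`, named by relative
#'   bin-center position; NA where the track has no coverage.
#' @export
extract_gene_signal <- function(track, gene, window = 1000L, bin = 10L) {
  g <- as.data.frame(gene[c("gene_id", "chrom", "tss", "strand")],
                     stringsAsFactors = FALSE)
  drop(metagene_matrix(track, g, window, bin))
}

#' Mean TSS metagene of a gene set
#'
#' Position-wise mean over the genes' individual profiles, ignoring missing
#' entries; positions where every gene is missing are flagged with a
#' warning and reported as NA.
#'
#' @inheritParams extract_gene_signal
#' @param genes `gene_universe` rows for the gene set.
#' @return list with `positions` (bin centers), `mean_signal` and
#'   `n_per_position`.
#' @export
metagene <- function(track, genes, window = 1000L, bin = 10L) {
  mat <- metagene_matrix(track, genes, window, bin)
  n_pos <- colSums(!is.na(mat))
  if (any(n_pos == 0L))
    warning(sprintf("%d profile position(s) have no data in any gene",
                    sum(n_pos == 0L)), call. = FALSE)
  list(positions = as.numeric(colnames(mat)),
       mean_signal = colMeans(mat, na.rm = TRUE), n_per_position = n_pos)
}

#' Random-set control band for a metagene profile
#'
#' Draws `n_sets` uniform random gene sets of size `set_size` from the
#' universe, computes each set's metagene, and summarizes them position-wise
#' by mean and quantiles.
#'
#' @inheritParams metagene
#' @param universe `gene_universe` rows for all genes eligible as controls.
#' @param set_size size of each random set.
#' @param n_sets number of random sets (>= 2).
#' @param quantiles `c(lo, hi)` probabilities of the band.
#' @param seed integer seed.
#' @param gene_matrix optional precomputed [metagene_matrix] of the
#'   universe, to avoid re-extracting signal.
#' @return list with `control_mean`, `control_low`, `control_high`,
#'   `n_control_sets`.
#' @export
control_band <- function(track, universe, set_size, n_sets = 1000L,
                         quantiles = c(0.025, 0.975), seed = 1L,
                         window = 1000L, bin = 10L, gene_matrix = NULL) {
  if (set_size > nrow(universe)) stop_format("set_size exceeds universe size")
  if (n_sets < 2L) stop_format("need at least 2 control sets")
  if (quantiles[1L] >= quantiles[2L])
    stop_format("degenerate quantiles: lo must be < hi")
  if (is.null(gene_matrix))
    gene_matrix <- metagene_matrix(track, universe, window, bin)
  sets_means <- with_seed(seed, {
    t(vapply(seq_len(n_sets), function(i) {
      colMeans(gene_matrix[sample.int(nrow(gene_matrix), set_size), ,
                           drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(gene_matrix))))
  })
  list(control_mean = colMeans(sets_means, na.rm = TRUE),
       control_low = apply(sets_means, 2L, stats::quantile,
                           probs = quantiles[1L], na.rm = TRUE, names = FALSE),
       control_high = apply(sets_means, 2L, stats::quantile,
                            probs = quantiles[2L], na.rm = TRUE, names = FALSE),
       n_control_sets = as.integer(n_sets))
}

#' Full metagene profile with control band
#'
#' @inheritParams control_band
#' @param genes `gene_universe` rows of the gene set of interest.
#' @return a `metagene_profile` object: positions, mean signal,
#'   per-position n, control mean/low/high, bookkeeping fields.
#' @export
metagene_profile <- function(track, genes, universe, window = 1000L,
                             bin = 10L, n_controls = 1000L,
                             quantiles = c(0.025, 0.975), seed = 1L) {
  prof <- metagene(track, genes, window, bin)
  ctrl <- control_band(track, universe, set_size = nrow(genes),
                       n_sets = n_controls, quantiles = quantiles,
                       seed = seed, window = window, bin = bin)
  structure(c(prof, ctrl,
              list(n_genes = nrow(genes), seed = as.integer(seed),
                   window = as.integer(window), bin = as.integer(bin),
                   quantiles = quantiles)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: %d genes, window +/-%d bp at %d bp bins, %d control sets\n",
              x$n_genes, x$window, x$bin, x$n_control_sets))
  cat(sprintf("  signal at TSS %.3f vs control %.3f [%.3f, %.3f]\n",
              x$mean_signal[which.min(abs(x$positions))],
              x$control_mean[which.min(abs(x$positions))],
              x$control_low[which.min(abs(x$positions))],
              x$control_high[which.min(abs(x$positions))]))
  invisible(x)
}

#' Plot a metagene profile against its control band
#' @param x a `metagene_profile`.
#' @param ... passed to [plot()].
#' @export
plot.metagene_profile <- function(x, ...) {
  ylim <- range(x$mean_signal, x$control_low, x$control_high, na.rm = TRUE)
  plot(x$positions, x$mean_signal, type = "l", lwd = 2, col = "firebrick",
       xlab = "distance from TSS (bp)", ylab = "mean signal", ylim = ylim, ...)
  graphics::polygon(c(x$positions, rev(x$positions)),
                    c(x$control_low, rev(x$control_high)),
                    col = grDevices::adjustcolor("grey50", 0.4), border = NA)
  graphics::lines(x$positions, x$control_mean, col = "grey30", lty = 2)
  graphics::lines(x$positions, x$mean_signal, col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
as.data.frame.metagene_profile <- function(x, ...) {
  data.frame(position = x$positions, mean_signal = x$mean_signal,
             n = x$n_per_position, control_mean = x$control_mean,
             control_low = x$control_low, control_high = x$control_high)
}
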