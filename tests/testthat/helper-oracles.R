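# Independent oracles and tiny fixture builders shared across tests.
# Oracles are deliberately naive (per-bp loops, exhaustive enumeration) and
# never call the code paths they check.

# exhaustive null tail probability of the enrichment permutation test:
# enumerate every size-k subset of the universe and measure how often its
# overlap with the gene set is at least as extreme as `obs` in `direction`
exhaustive_null_p <- function(universe, gene_set, k, obs, direction) {
  sets <- utils::combn(universe, k)
  ov <- apply(sets, 2L, function(s) length(intersect(s, gene_set)))
  if (direction == "enriched") mean(ov >= obs) else mean(ov <= obs)
}

# exact rank-sum p by enumeration of all assignments of the pooled values
# to group A (no ties expected); W is the Mann-Whitney statistic of A
enum_ranksum_p <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  na <- length(a)
  w_of <- function(idx) sum(rank(pooled)[idx]) - na * (na + 1) / 2
  w_obs <- w_of(seq_len(na))
  w_all <- apply(utils::combn(length(pooled), na), 2L, w_of)
  p_less <- mean(w_all <= w_obs)
  p_greater <- mean(w_all >= w_obs)
  switch(alternative,
         less = p_less, greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

# per-bp brute-force metagene extraction: value of every base from the raw
# track table, strand-mapped into relative bins, then averaged
brute_signal <- function(track_df, chrom, tss, strand, window, bin) {
  bp_value <- function(p) {
    row <- which(track_df$chrom == chrom & track_df$start <= p & p < track_df$end)
    if (length(row)) track_df$value[row[1L]] else NA_real_
  }
  d <- seq(-window, window - 1L)
  p <- if (strand == "+") tss + d else tss - d
  vals <- vapply(p, bp_value, numeric(1))
  grp <- (d + window) %/% bin
  out <- tapply(vals, grp, function(v) if (all(is.na(v))) NA_real_
                else mean(v, na.rm = TRUE))
  as.numeric(out)
}

# small handmade gene universe for metagene tests
tiny_universe <- function(tss, strand, chrom = "chrI") {
  out <- data.frame(gene_id = sprintf("t%03d", seq_along(tss)), chrom = chrom,
                    tss = as.integer(tss), strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_universe", "data.frame")
  out
}

make_track <- function(chrom, start, end, value) {
  endosirna:::new_signal_track(
    data.frame(chrom = chrom, start = start, end = end, value = value,
               stringsAsFactors = FALSE))
}

# write text lines to a temp file and return its path
tmp_lines <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  structure(as.character(tools::md5sum(files)),
            names = basename(files))
}
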