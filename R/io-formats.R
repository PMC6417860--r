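## Readers/writers for every external format the pipeline touches.
## Convention: every coordinate held in memory is 0-based half-open; the one
## and only conversion from GFF3's 1-based inclusive coordinates happens in
## read_gff_genes(). Writers emit deterministic column and line order
## (sorted by gene_id / chrom+start) so identical inputs give byte-identical
## files.

#' Read a per-gene small-RNA count table
#'
#' Expects an HTSeq-count style tab-separated table with a header row: a
#' `gene_id` column followed by one column of non-negative integer counts per
#' sample.
#'
#' @param path path to a tab-separated count file.
#' @return integer matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_format("count file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L)
    stop_format("count file %s must have a gene_id column plus >=1 sample", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop_format("duplicate gene_id '%s' in %s", dup, path)
  }
  m <- matrix(NA_integer_, nrow = nrow(df), ncol = ncol(df) - 1L,
              dimnames = list(ids, colnames(df)[-1L]))
  for (j in seq_len(ncol(df) - 1L)) {
    raw <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad))
      stop_format("invalid count '%s' at line %d of %s (must be a non-negative integer)",
                  raw[bad[1L]], bad[1L] + 1L, path)
    m[, j] <- as.integer(num)
  }
  m
}

#' Write a count table
#' @param counts integer matrix as returned by [read_counts()].
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  ord <- order(rownames(counts))
  df <- data.frame(gene_id = rownames(counts)[ord],
                   counts[ord, , drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`, `mRNA`/`transcript`, `exon` and `CDS` features into a gene
#' universe table. The transcription start site is the gene start for
#' `+`-strand genes and the gene end for `-`-strand genes, converted to a
#' 0-based coordinate; the intron count of a transcript is its exon count
#' minus one; the CDS length is the summed CDS width of the longest coding
#' transcript (falling back to summed exon width when no CDS rows exist).
#'
#' @param path path to a GFF3 file.
#' @param biotype keep only genes carrying one of these biotypes; genes
#'   without a biotype attribute are always kept. `NULL` disables the filter.
#'   The default restricts to protein-coding genes, the universe used
#'   throughout the analysis.
#' @return a `gene_universe` data.frame with columns `gene_id`, `chrom`,
#'   `tss` (0-based), `strand`, `cds_length`, `n_transcripts`,
#'   `intron_counts` (list column, one entry per transcript) and
#'   `intron_count_mean`.
#' @export
read_gff_genes <- function(path, biotype = "protein_coding") {
  if (!file.exists(path)) stop_format("GFF3 file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)

  is_gene <- type == "gene"
  if (!any(is_gene)) stop_format("no gene features in %s", path)
  gene_id <- as.character(mc$ID[is_gene])
  g_strand <- as.character(BiocGenerics::strand(gr))[is_gene]
  if (any(!g_strand %in% c("+", "-")))
    stop_format("strandless gene '%s' in %s",
                gene_id[which(!g_strand %in% c("+", "-"))[1L]], path)
  if (!is.null(biotype) && "biotype" %in% colnames(mc)) {
    bt <- as.character(mc$biotype[is_gene])
    keep <- is.na(bt) | bt %in% biotype
  } else keep <- rep(TRUE, sum(is_gene))

  g_start1 <- BiocGenerics::start(gr)[is_gene] # 1-based inclusive
  g_end1 <- BiocGenerics::end(gr)[is_gene]
  tss0 <- ifelse(g_strand == "+", g_start1 - 1L, g_end1 - 1L)
  chrom <- as.character(GenomicRanges::seqnames(gr))[is_gene]

  first_parent <- function(p) vapply(p, function(x)
    if (length(x)) as.character(x[[1L]]) else NA_character_, character(1))

  is_tx <- type %in% c("mRNA", "transcript")
  tx_id <- as.character(mc$ID[is_tx])
  tx_parent <- first_parent(mc$Parent[is_tx])

  is_exon <- type == "exon"
  exon_parent <- first_parent(mc$Parent[is_exon])
  exons_per_tx <- table(factor(exon_parent, levels = tx_id))

  is_cds <- type == "CDS"
  cds_parent <- first_parent(mc$Parent[is_cds])
  cds_w <- BiocGenerics::width(gr)[is_cds]
  cds_per_tx <- tapply(cds_w, factor(cds_parent, levels = tx_id), sum)
  exon_w <- BiocGenerics::width(gr)[is_exon]
  exonw_per_tx <- tapply(exon_w, factor(exon_parent, levels = tx_id), sum)

  tx_by_gene <- split(seq_along(tx_id), factor(tx_parent, levels = gene_id))
  intron_counts <- vector("list", length(gene_id))
  cds_length <- integer(length(gene_id))
  for (i in seq_along(gene_id)) {
    tids <- tx_by_gene[[i]]
    if (!length(tids))
      stop_format("gene '%s' has no transcript in %s", gene_id[i], path)
    intron_counts[[i]] <- as.integer(exons_per_tx[tids]) - 1L
    if (any(intron_counts[[i]] < 0L))
      stop_format("transcript of gene '%s' has no exons in %s", gene_id[i], path)
    len <- cds_per_tx[tids]
    if (all(is.na(len))) len <- exonw_per_tx[tids]
    cds_length[i] <- as.integer(max(len, na.rm = TRUE))
  }

  out <- data.frame(gene_id = gene_id, chrom = chrom, tss = as.integer(tss0),
                    strand = g_strand, cds_length = cds_length,
                    n_transcripts = lengths(tx_by_gene),
                    stringsAsFactors = FALSE)
  out$intron_counts <- intron_counts
  out$intron_count_mean <- vapply(intron_counts, mean, numeric(1))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_universe", "data.frame")
  out
}

#' Read a gene-set collection from a GMT file
#'
#' Members are deduplicated; empty sets and duplicated set names are
#' rejected.
#'
#' @param path path to a GMT file (name, description, members per line).
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("GMT file not found: %s", path)
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets)))
    stop_format("duplicate set name '%s' in %s",
                names(sets)[duplicated(names(sets))][1L], path)
  sets <- lapply(sets, function(x) unique(x[nzchar(x)]))
  empty <- lengths(sets) == 0L
  if (any(empty))
    stop_format("empty gene set '%s' in %s", names(sets)[empty][1L], path)
  sets
}

#' Write a gene-set collection to GMT
#' @param collection named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of per-set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(is.list(collection), !is.null(names(collection)))
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], descriptions[i],
            sort(unique(collection[[i]]))), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---- binned signal tracks ------------------------------------------------

# Internal container for a binned chromatin signal: per chromosome, sorted
# non-overlapping 0-based half-open intervals with a value, plus prefix
# integrals of value*width and of covered width, so the average signal over
# any interval is two findInterval() lookups.
new_signal_track <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% colnames(df)))
  if (any(df$end <= df$start))
    stop_format("malformed interval (end <= start) at row %d",
                which(df$end <= df$start)[1L])
  track <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (any(d$start[-1L] < d$end[-nrow(d)]))
      stop_format("overlapping bedGraph intervals on %s", d$chrom[1L])
    w <- d$end - d$start
    list(start = d$start, end = d$end, value = d$value,
         cum_sig = cumsum(d$value * w), cum_cov = cumsum(w))
  })
  structure(list(chroms = track), class = "signal_track")
}

# integral of signal (and covered bp) over [0, p) on one chromosome
.track_prefix <- function(ch, p) {
  idx <- findInterval(p, ch$start)
  full_sig <- ifelse(idx > 0L, ch$cum_sig[pmax(idx, 1L)], 0)
  full_cov <- ifelse(idx > 0L, ch$cum_cov[pmax(idx, 1L)], 0)
  # subtract the part of bin `idx` beyond p (if p falls inside it)
  over <- ifelse(idx > 0L, pmax(0, ch$end[pmax(idx, 1L)] - pmax(p, ch$start[pmax(idx, 1L)])), 0)
  list(sig = full_sig - ifelse(idx > 0L, ch$value[pmax(idx, 1L)] * over, 0),
       cov = full_cov - over)
}

# vectorized average signal over [lo, hi) intervals; NA where no coverage
track_interval_mean <- function(track, chrom, lo, hi) {
  ch <- track$chroms[[chrom]]
  if (is.null(ch)) stop_format("unknown chromosome '%s' in signal track", chrom)
  a <- .track_prefix(ch, lo)
  b <- .track_prefix(ch, hi)
  cov <- b$cov - a$cov
  ifelse(cov > 0, (b$sig - a$sig) / cov, NA_real_)
}

#' Read a bedGraph file into a signal track
#'
#' Intervals are 0-based half-open; overlapping intervals are an error.
#'
#' @param path path to a bedGraph file.
#' @return a `signal_track` object.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop_format("bedGraph file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L, # back to 0-based
                   end = BiocGenerics::end(gr),
                   value = S4Vectors::mcols(gr)$score,
                   stringsAsFactors = FALSE)
  new_signal_track(df)
}

#' Write a signal track to bedGraph
#' @param track a `signal_track` or a data.frame with chrom/start/end/value.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  df <- if (inherits(track, "signal_track")) as.data.frame(track) else track
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                     formatC(df$value, format = "g", digits = 15)), path)
  invisible(path)
}

#' @export
as.data.frame.signal_track <- function(x, ...) {
  do.call(rbind, lapply(names(x$chroms), function(cn) {
    ch <- x$chroms[[cn]]
    data.frame(chrom = cn, start = ch$start, end = ch$end, value = ch$value,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.signal_track <- function(x, ...) {
  n <- sum(vapply(x$chroms, function(ch) length(ch$start), numeric(1)))
  cat(sprintf("signal_track: %d intervals on %d chromosome(s)\n",
              n, length(x$chroms)))
  invisible(x)
}

## ---- homology and feature tables -----------------------------------------

#' Read a homology table
#'
#' Tab-separated with header `gene_id`, `type` (`ortholog` or `paralog`),
#' `species`, `partner_id`. A gene with no rows simply has no known orthologs
#' or paralogs.
#'
#' @param path path to the TSV.
#' @return a data.frame of class `homology_table`.
#' @export
read_homology <- function(path) {
  if (!file.exists(path)) stop_format("homology file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("gene_id", "type", "species", "partner_id")
  if (!all(need %in% colnames(df)))
    stop_format("homology table %s must have columns %s", path,
                paste(need, collapse = ", "))
  bad <- !df$type %in% c("ortholog", "paralog")
  if (any(bad))
    stop_format("invalid homology type '%s' in %s", df$type[bad][1L], path)
  if (any(df$type == "paralog" & df$gene_id == df$partner_id))
    stop_format("gene listed as its own paralog in %s", path)
  class(df) <- c("homology_table", "data.frame")
  df
}

#' Write a homology table
#' @param homology data.frame with gene_id/type/species/partner_id.
#' @param path output path.
#' @export
write_homology <- function(homology, path) {
  df <- homology[order(homology$gene_id, homology$type, homology$species,
                       homology$partner_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-gene feature table
#'
#' Tab-separated with a `gene_id` column and numeric feature columns
#' (e.g. `patc_density`, `splicing_divergence`, `intron_count_mean`,
#' `cds_length`).
#'
#' @param path path to the TSV.
#' @return data.frame keyed by `gene_id`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_format("feature table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!"gene_id" %in% colnames(df))
    stop_format("feature table %s lacks a gene_id column", path)
  if (anyDuplicated(df$gene_id))
    stop_format("duplicate gene_id in feature table %s", path)
  num <- setdiff(colnames(df), "gene_id")
  neg <- num[vapply(num, function(cn) {
    cn %in% c("patc_density", "cds_length", "intron_count_mean") &&
      any(df[[cn]] < 0, na.rm = TRUE)
  }, logical(1))]
  if (length(neg))
    stop_format("negative values in feature column '%s' of %s", neg[1L], path)
  df
}

#' Write a per-gene feature table
#' @param features data.frame with a `gene_id` column.
#' @param path output path.
#' @export
write_feature_table <- function(features, path) {
  df <- features[order(features$gene_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
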