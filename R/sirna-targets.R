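## RPM normalization and the single-replicate fold-change rule that defines
## endo-siRNA target sets, plus ingestion of externally computed
## differential-expression tables for the replicated case.

#' Normalize a count table to reads per million
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @return matrix of the same shape; each column sums to 1e6.
#' @export
#' @examples
#' rpm_normalize(cbind(s1 = c(g1 = 5, g2 = 10, g3 = 85)))
rpm_normalize <- function(counts) {
  if (is.null(dim(counts))) counts <- cbind(sample = counts)
  if (any(counts < 0)) stop_format("negative counts")
  tot <- colSums(counts)
  if (any(tot == 0))
    stop_format("sample '%s' has all-zero counts; RPM undefined",
                colnames(counts)[tot == 0][1L])
  sweep(counts, 2L, tot / 1e6, "/")
}

#' Configuration of the fold-change classifier
#'
#' The rule calls a gene's targeting endo-siRNAs changed when the
#' mutant/wild-type RPM ratio (after adding `pseudocount_rpm` to both) is
#' strictly above `up_threshold` or strictly below `down_threshold`. Genes
#' with both samples under `noise_floor_rpm` are not classified.
#'
#' @param up_threshold fold change above which a gene is `up` (default 2).
#' @param down_threshold fold change below which a gene is `down`
#'   (default 0.5).
#' @param pseudocount_rpm RPM pseudocount added to numerator and denominator
#'   (default 1, the smallest expressible unit at these library depths).
#' @param noise_floor_rpm genes with both RPM values below this are excluded
#'   from classification.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(up_threshold = 2, down_threshold = 0.5,
                              pseudocount_rpm = 1, noise_floor_rpm = 1) {
  if (!(down_threshold < 1 && 1 < up_threshold))
    stop_format("need down_threshold < 1 < up_threshold")
  check_scalar_number(pseudocount_rpm, "pseudocount_rpm", lower = 0)
  structure(list(up_threshold = up_threshold, down_threshold = down_threshold,
                 pseudocount_rpm = pseudocount_rpm,
                 noise_floor_rpm = noise_floor_rpm),
            class = "classifier_config")
}

new_target_set <- function(direction, genes, provenance) {
  structure(list(direction = direction, genes = sort(unique(genes)),
                 provenance = provenance), class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target_set: %d genes, direction=%s (%s)\n",
              length(x$genes), x$direction, x$provenance))
  invisible(x)
}

#' Classify genes by single-replicate RPM fold change
#'
#' Implements the rule used when only one biological sample per condition is
#' available: fold = (mutant RPM + pseudocount) / (wild-type RPM +
#' pseudocount); genes strictly below the down threshold lost their
#' targeting endo-siRNAs, genes strictly above the up threshold gained them.
#'
#' @param wt,mut named RPM vectors (or 1-column matrices) over the same gene
#'   universe.
#' @param cfg a [classifier_config()].
#' @return list with `down` and `up` [target_set]s, the `fold` vector, and
#'   `n_excluded` (genes under the noise floor in both samples).
#' @export
fold_change_classify <- function(wt, mut, cfg = classifier_config()) {
  wt <- drop(as.matrix(wt))[, drop = TRUE]
  mut <- drop(as.matrix(mut))[, drop = TRUE]
  if (is.null(names(wt)) || is.null(names(mut)))
    stop_format("RPM vectors must be named by gene_id")
  if (!setequal(names(wt), names(mut)) || length(wt) != length(mut))
    stop_format("wild-type and mutant tables cover different gene sets")
  mut <- mut[names(wt)]
  excluded <- wt < cfg$noise_floor_rpm & mut < cfg$noise_floor_rpm
  fold <- (mut + cfg$pseudocount_rpm) / (wt + cfg$pseudocount_rpm)
  down <- names(wt)[!excluded & fold < cfg$down_threshold]
  up <- names(wt)[!excluded & fold > cfg$up_threshold]
  list(down = new_target_set("down", down, "fold_change_rule"),
       up = new_target_set("up", up, "fold_change_rule"),
       fold = fold, n_excluded = sum(excluded))
}

#' Load target sets from an external differential-expression table
#'
#' Ingests the result table of a replicated differential-expression fit
#' (columns `gene_id`, `log2FoldChange`, `padj`); genes with adjusted p
#' strictly below `alpha` are split by fold-change sign.
#'
#' @param path TSV path.
#' @param alpha adjusted-p threshold (default 0.1).
#' @return list with `down` and `up` [target_set]s.
#' @export
load_external_de <- function(path, alpha = 0.1) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  need <- c("gene_id", "log2FoldChange", "padj")
  if (!all(need %in% colnames(df)))
    stop_format("DE table %s must have columns %s", path,
                paste(need, collapse = ", "))
  sig <- !is.na(df$padj) & df$padj < alpha
  if (any(sig & df$log2FoldChange == 0))
    stop_format("significant gene '%s' has log2FoldChange = 0; sign undefined",
                df$gene_id[sig & df$log2FoldChange == 0][1L])
  list(down = new_target_set("down", df$gene_id[sig & df$log2FoldChange < 0],
                             "external_DE"),
       up = new_target_set("up", df$gene_id[sig & df$log2FoldChange > 0],
                           "external_DE"))
}
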