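## Distribution comparisons of per-gene features (PATC density, intron
## number, CDS length, splicing divergence) between a target set and all
## protein-coding genes, with the rank-sum test and the log2(x+1) display
## transform; plus the corrected-total-cell-fluorescence (CTCF) utility.

#' log2(x + 1) display transform
#' @param x numeric vector.
#' @return `log2(x + 1)`.
#' @export
log2p1 <- function(x) log2(x + 1)

#' Mean intron count of a multi-transcript gene
#'
#' When a gene has several transcripts its intron number is the arithmetic
#' mean of the per-transcript intron counts.
#'
#' @param gene a one-row `gene_universe` entry (or anything with an
#'   `intron_counts` field), or directly a vector of per-transcript counts.
#' @return numeric scalar.
#' @export
mean_intron_count <- function(gene) {
  counts <- if (is.numeric(gene)) gene
            else if (!is.null(gene$intron_counts)) unlist(gene$intron_counts)
            else stop_format("no intron counts available")
  if (!length(counts)) stop_format("gene has no transcripts")
  mean(counts)
}

#' Compare two feature distributions with the rank-sum test
#'
#' Wilcoxon rank-sum test: exact when both samples are small (`min(n) <= 8`)
#' and tie-free, tie-corrected normal approximation with continuity
#' correction otherwise. The transform affects only the reported medians and
#' means — rank tests are invariant under strictly monotone transforms, so
#' the p-value is computed on the raw values.
#'
#' @param values_a,values_b numeric samples (non-empty; NAs dropped).
#' @param transform `"none"` or `"log2p1"`; scale on which medians/means are
#'   reported, matching how the distributions are displayed.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternative for `values_a` relative to `values_b`).
#' @param method `"auto"` picks exact vs approximation as above; `"exact"`
#'   and `"approx"` force one path.
#' @return list: `statistic` (rank-sum W), `p_value`, `median_a`,
#'   `median_b`, `mean_a`, `mean_b`, `n_a`, `n_b`, `method`, `transform`.
#' @export
compare_feature <- function(values_a, values_b,
                            transform = c("none", "log2p1"),
                            alternative = c("two.sided", "less", "greater"),
                            method = c("auto", "exact", "approx")) {
  transform <- match.arg(transform)
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b)) stop_format("both samples must be non-empty")
  tr <- if (transform == "log2p1") log2p1 else identity

  has_ties <- anyDuplicated(c(a, b)) > 0L
  exact <- switch(method,
                  auto = min(length(a), length(b)) <= 8L && !has_ties,
                  exact = TRUE, approx = FALSE)
  if (all(c(a, b) == c(a, b)[1L])) {
    # both samples a single shared constant: no evidence of any shift
    w <- length(a) * length(b) / 2
    p <- 1
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                              exact = exact, correct = TRUE))
    w <- unname(wt$statistic)
    p <- min(1, wt$p.value)
  }
  list(statistic = w, p_value = p,
       median_a = stats::median(tr(a)), median_b = stats::median(tr(b)),
       mean_a = mean(tr(a)), mean_b = mean(tr(b)),
       n_a = length(a), n_b = length(b),
       method = if (exact) "exact" else "normal_approx_tie_corrected",
       transform = transform)
}

#' Feature comparisons of target sets against all protein-coding genes
#'
#' For every target set and every feature column, compares the set's values
#' against all genes of the universe (the study's reference) with
#' [compare_feature()]. Genes of a set missing from the feature table are
#' dropped (their number is reported); a feature with no usable values is
#' flagged without aborting the rest.
#'
#' @param target_sets named list of [target_set]s or gene-id vectors.
#' @param universe character vector of all gene ids.
#' @param features feature data.frame (see [read_feature_table()]).
#' @param transforms named character vector mapping feature column ->
#'   transform; features not listed are compared untransformed. The default
#'   reports PATC density on the log2(x+1) display scale.
#' @return data.frame, one row per set x feature.
#' @export
feature_report <- function(target_sets, universe, features,
                           transforms = c(patc_density = "log2p1")) {
  feat_cols <- setdiff(colnames(features), "gene_id")
  features <- features[features$gene_id %in% universe, , drop = FALSE]
  rows <- list()
  for (set_name in names(target_sets)) {
    genes <- as_gene_set(target_sets[[set_name]])
    n_missing <- sum(!genes %in% features$gene_id)
    in_tab <- features[features$gene_id %in% genes, , drop = FALSE]
    for (fc in feat_cols) {
      tf <- unname(transforms[fc])
      if (is.na(tf)) tf <- "none"
      res <- tryCatch({
        if (!nrow(in_tab)) stop_format("set has no genes in the feature table")
        compare_feature(in_tab[[fc]], features[[fc]], transform = tf)
      }, error = function(e) conditionMessage(e))
      rows[[length(rows) + 1L]] <- if (is.character(res))
        data.frame(set_name = set_name, feature = fc, n_set = nrow(in_tab),
                   n_missing = n_missing, statistic = NA_real_,
                   p_value = NA_real_, median_set = NA_real_,
                   median_all = NA_real_, mean_set = NA_real_,
                   mean_all = NA_real_, transform = tf, status = res,
                   stringsAsFactors = FALSE)
      else
        data.frame(set_name = set_name, feature = fc, n_set = res$n_a,
                   n_missing = n_missing, statistic = res$statistic,
                   p_value = res$p_value, median_set = res$median_a,
                   median_all = res$median_b, mean_set = res$mean_a,
                   mean_all = res$mean_b, transform = tf, status = "ok",
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated density - area * mean background fluorescence`, the
#' standard background correction for fluorescence quantification of
#' segmented objects.
#'
#' @param integrated_density integrated density of the selected object.
#' @param area area of the selected object (> 0).
#' @param mean_background mean fluorescence of the background readings.
#' @return the corrected fluorescence value.
#' @export
#' @examples
#' ctcf(100, 10, 2) # 80
ctcf <- function(integrated_density, area, mean_background) {
  if (any(area <= 0)) stop_format("area must be positive")
  integrated_density - area * mean_background
}

#' Normalize a CTCF value to a control mean
#' @param value CTCF value(s).
#' @param control_mean mean CTCF of control animals (non-zero).
#' @return `value / control_mean`.
#' @export
normalize_ctcf <- function(value, control_mean) {
  if (any(control_mean == 0)) stop_format("control mean CTCF is zero")
  value / control_mean
}
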