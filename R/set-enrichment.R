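## The study's gene-set enrichment statistic and its permutation null.
##
## Enrichment = Observed / Expected, where Observed is the fraction of the
## target list belonging to the gene set and Expected is the gene set's
## fraction of the whole annotation universe. Significance comes from
## re-drawing random gene sets of the target's size from the universe,
## ranking their enrichment values, and reading the p-value off the rank of
## the observed value (tie-inclusive, (r+1)/(n+1), one-sided in the observed
## direction).

as_gene_set <- function(x) {
  if (inherits(x, "target_set")) x$genes else as.character(x)
}

#' Observed/expected enrichment of a gene set in a target list
#'
#' @param target character vector of target gene ids (or a [target_set]);
#'   must lie within the universe.
#' @param gene_set character vector of gene ids; intersected with the
#'   universe before anything else.
#' @param universe character vector: all genes of the annotation universe.
#' @return list with `observed_fraction`, `expected_fraction`, `fold`,
#'   `overlap_count` and `set_size_in_universe`.
#' @export
#' @examples
#' u <- paste0("g", 1:10)
#' enrichment_statistic(u[1:5], u[c(1, 2, 3, 9)], u)$fold # (3/5)/(4/10) = 1.5
enrichment_statistic <- function(target, gene_set, universe) {
  target <- unique(as_gene_set(target))
  if (!length(target)) stop_format("empty target set")
  if (!all(target %in% universe))
    stop_format("target contains genes outside the universe (e.g. '%s')",
                setdiff(target, universe)[1L])
  set_u <- intersect(unique(as_gene_set(gene_set)), universe)
  if (!length(set_u))
    stop_format("gene set has no overlap with the universe; expected fraction is 0")
  observed <- length(intersect(target, set_u)) / length(target)
  expected <- length(set_u) / length(universe)
  list(observed_fraction = observed, expected_fraction = expected,
       fold = observed / expected,
       overlap_count = length(intersect(target, set_u)),
       set_size_in_universe = length(set_u))
}

#' Permutation p-value for an enrichment
#'
#' Draws `n` uniform random subsets of the universe of the target's size
#' (without replacement within each subset), computes their enrichment
#' values, and returns the tie-inclusive one-sided rank p-value
#' `(1 + r)/(n + 1)` in the observed direction (`enriched` when the observed
#' fold exceeds 1, `depleted` otherwise).
#'
#' @inheritParams enrichment_statistic
#' @param n number of random sets (default 10000).
#' @param seed integer seed.
#' @param set_name label carried into the result.
#' @return an `enrichment_result` list: `set_name`, `observed_fraction`,
#'   `expected_fraction`, `fold`, `direction`, `p_value`, `n_permutations`,
#'   `seed`, `overlap_count`, `target_size`.
#' @export
permutation_pvalue <- function(target, gene_set, universe, n = 10000L,
                               seed = 1L, set_name = "set") {
  target <- unique(as_gene_set(target))
  stat <- enrichment_statistic(target, gene_set, universe)
  k <- length(target)
  if (k > length(universe)) stop_format("target larger than universe")
  if (n < 1) stop_format("need n >= 1 permutations")
  member <- universe %in% intersect(unique(as_gene_set(gene_set)), universe)
  nu <- length(universe)
  rand_overlap <- with_seed(seed, {
    vapply(seq_len(n), function(i) sum(member[sample.int(nu, k)]), integer(1))
  })
  direction <- if (stat$fold > 1) "enriched" else "depleted"
  # expected fraction is identical for every same-size set, so comparing
  # folds is comparing overlap counts
  r <- if (direction == "enriched") sum(rand_overlap >= stat$overlap_count)
       else sum(rand_overlap <= stat$overlap_count)
  structure(c(list(set_name = set_name), stat,
              list(direction = direction, p_value = (1 + r) / (n + 1),
                   n_permutations = as.integer(n), seed = as.integer(seed),
                   target_size = k)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: fold=%.3f (%d/%d vs %.4f) %s, p=%.4g (n=%d)\n",
              x$set_name, x$fold, x$overlap_count, x$target_size,
              x$expected_fraction, x$direction, x$p_value, x$n_permutations))
  invisible(x)
}

#' Enrichment after excluding genes shared with other pathways
#'
#' Re-runs [permutation_pvalue()] on the target list minus the union of the
#' exclusion sets, to ask whether an enrichment survives removal of genes
#' already claimed by other small-RNA pathways.
#'
#' @inheritParams permutation_pvalue
#' @param exclude_sets list of character vectors of gene ids to remove from
#'   the target.
#' @return an `enrichment_result` with an extra `n_after_exclusion` field.
#' @export
exclusion_enrichment <- function(target, exclude_sets, gene_set, universe,
                                 n = 10000L, seed = 1L, set_name = "set") {
  target <- unique(as_gene_set(target))
  drop <- unique(unlist(lapply(exclude_sets, as_gene_set)))
  reduced <- setdiff(target, drop)
  if (!length(reduced))
    stop_format("exclusion removed every target gene; nothing to test")
  if (length(reduced) < 5L)
    warning(sprintf("only %d target genes remain after exclusion",
                    length(reduced)), call. = FALSE)
  res <- permutation_pvalue(reduced, gene_set, universe, n = n, seed = seed,
                            set_name = set_name)
  res$n_after_exclusion <- length(reduced)
  res
}

#' Screen a target list against a whole gene-set collection
#'
#' One permutation test per named set; per-set failures (e.g. a set disjoint
#' from the universe) are flagged in the result table without aborting the
#' remaining sets. Each set draws its permutations from a seed derived from
#' `seed` and the set's name, so results do not depend on collection order.
#'
#' @inheritParams permutation_pvalue
#' @param collection named list of gene sets (see [read_gmt()]).
#' @return data.frame with one row per set, in collection order: fold,
#'   log2 fold, direction, p-value, overlap, sizes, and a `status` column
#'   (`"ok"` or the error message).
#' @export
enrichment_screen <- function(target, collection, universe, n = 10000L,
                              seed = 1L) {
  if (!length(collection)) stop_format("empty gene-set collection")
  rows <- lapply(names(collection), function(nm) {
    res <- tryCatch(
      permutation_pvalue(target, collection[[nm]], universe, n = n,
                         seed = derive_seed(seed, nm), set_name = nm),
      error = function(e) conditionMessage(e))
    if (is.character(res))
      data.frame(set_name = nm, observed_fraction = NA_real_,
                 expected_fraction = NA_real_, fold = NA_real_,
                 log2_fold = NA_real_, direction = NA_character_,
                 p_value = NA_real_, overlap_count = NA_integer_,
                 set_size_in_universe = NA_integer_,
                 target_size = NA_integer_, status = res,
                 stringsAsFactors = FALSE)
    else
      data.frame(set_name = nm, observed_fraction = res$observed_fraction,
                 expected_fraction = res$expected_fraction, fold = res$fold,
                 log2_fold = log2(res$fold), direction = res$direction,
                 p_value = res$p_value, overlap_count = res$overlap_count,
                 set_size_in_universe = res$set_size_in_universe,
                 target_size = res$target_size, status = "ok",
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
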