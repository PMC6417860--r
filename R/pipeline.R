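## End-to-end orchestration: counts -> target sets -> enrichment screen +
## conservation-class enrichment (with pathway-exclusion variant) + TSS
## metagene profiles + feature comparisons, from one config, fully
## deterministic under the config's master seed. Every stochastic stage
## derives its own seed from the master seed and its stage name, so the
## report is byte-identical across runs and stages can be reproduced in
## isolation.

#' Build and validate a pipeline run configuration
#'
#' @param config either a path to a YAML file or a named list with fields
#'   `counts`, `gff`, `gene_sets`, `bedgraph`, `homology`, `features`
#'   (paths), optional `de_table`/`alpha`, `outdir`, `seed`, and optional
#'   parameter blocks `classifier`, `enrichment` (`n_perm`, `exclude_sets`),
#'   `metagene` (`window`, `bin`, `n_controls`, `quantiles`) and
#'   `conservation` (`genus_species`, `outgroup_species`).
#' @return a validated `run_config` list with all defaults filled in.
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (f in c("counts", "gff", "gene_sets", "bedgraph", "homology",
              "features")) {
    if (is.null(cfg[[f]])) stop_format("config field '%s' is required", f)
    if (!file.exists(cfg[[f]]))
      stop_format("config input '%s' does not exist: %s", f, cfg[[f]])
  }
  if (!is.null(cfg$de_table) && !file.exists(cfg$de_table))
    stop_format("config input 'de_table' does not exist: %s", cfg$de_table)
  if (is.null(cfg$seed)) stop_format("config field 'seed' is mandatory")
  if (is.null(cfg$outdir)) stop_format("config field 'outdir' is required")
  cl <- cfg$classifier %||% list()
  cfg$classifier <- classifier_config(
    up_threshold = cl$up_threshold %||% 2,
    down_threshold = cl$down_threshold %||% 0.5,
    pseudocount_rpm = cl$pseudocount_rpm %||% 1,
    noise_floor_rpm = cl$noise_floor_rpm %||% 1)
  en <- cfg$enrichment %||% list()
  cfg$enrichment <- list(n_perm = as.integer(en$n_perm %||% 10000L),
                         exclude_sets = en$exclude_sets %||% character(0))
  mg <- cfg$metagene %||% list()
  cfg$metagene <- list(window = as.integer(mg$window %||% 1000L),
                       bin = as.integer(mg$bin %||% 10L),
                       n_controls = as.integer(mg$n_controls %||% 1000L),
                       quantiles = as.numeric(unlist(mg$quantiles %||%
                                                       c(0.025, 0.975))))
  cv <- cfg$conservation %||% list()
  cfg$conservation <- list(
    genus_species = cv$genus_species %||% default_genus_species(),
    outgroup_species = cv$outgroup_species %||% default_outgroup_species())
  cfg$alpha <- cfg$alpha %||% 0.1
  class(cfg) <- "run_config"
  cfg
}

#' Conservation-class enrichment of target sets
#'
#' Classifies the universe by conservation, then tests each target set for
#' enrichment or depletion of every conservation class (newly-evolved,
#' genus-only, nematode-conserved, duplicated) with the permutation null.
#' When `exclude_sets` is given, an exclusion variant is added for each
#' class: the same test on the target list minus genes claimed by those
#' pathways.
#'
#' @param target_sets named list of [target_set]s or gene-id vectors.
#' @param homology a `homology_table`.
#' @param universe character vector of all gene ids.
#' @param n number of permutations.
#' @param seed integer seed.
#' @param genus_species,outgroup_species species vocabularies.
#' @param exclude_sets optional named list of gene sets whose members are
#'   removed from the targets in the exclusion variant.
#' @return data.frame: one row per target set x class (x variant).
#' @export
run_newly_evolved_analysis <- function(target_sets, homology, universe,
                                       n = 10000L, seed = 1L,
                                       genus_species = default_genus_species(),
                                       outgroup_species = default_outgroup_species(),
                                       exclude_sets = NULL) {
  cls <- classify_universe(homology, universe, genus_species,
                           outgroup_species)
  rows <- list()
  for (ts_name in names(target_sets)) {
    target <- as_gene_set(target_sets[[ts_name]])
    scr <- enrichment_screen(target, cls$collection, universe, n = n,
                             seed = derive_seed(seed, ts_name))
    scr <- cbind(target_set = ts_name, variant = "full", scr,
                 stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- scr
    if (length(exclude_sets)) {
      reduced <- setdiff(target, unique(unlist(lapply(exclude_sets,
                                                      as_gene_set))))
      if (length(reduced)) {
        scr2 <- enrichment_screen(reduced, cls$collection, universe, n = n,
                                  seed = derive_seed(seed,
                                                     paste0(ts_name, "_excl")))
        rows[[length(rows) + 1L]] <-
          cbind(target_set = ts_name, variant = "excluding_shared", scr2,
                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "classes") <- cls$classes
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: input validation and loading; RPM
#' normalization and target classification (fold-change rule, plus the
#' external differential-expression table when configured); gene-set
#' enrichment screen for both target directions; conservation
#' classification and conservation-class enrichment with the
#' pathway-exclusion variant; TSS metagene profiles with random-set control
#' bands; feature-distribution comparisons. A failing stage is recorded in
#' the report and its dependents skipped; independent stages still run.
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @return a `run_report` list, invisibly; tables and a JSON summary are
#'   written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(cfg),
                 version = as.character(utils::packageVersion("endosirna")),
                 stages = list())
  fail <- function(stage, e) {
    report$stages[[stage]] <<- paste("failed:", conditionMessage(e))
    NULL
  }

  ## stage: load
  counts <- read_counts(cfg$counts)
  genes <- read_gff_genes(cfg$gff)
  collection <- read_gmt(cfg$gene_sets)
  track <- read_bedgraph(cfg$bedgraph)
  homology <- read_homology(cfg$homology)
  features <- read_feature_table(cfg$features)
  report$stages$load <- "ok"

  # genes present in counts but absent from the annotation are dropped: all
  # set arithmetic happens on the intersection of the data sources
  universe <- genes$gene_id
  dropped <- setdiff(rownames(counts), universe)
  if (length(dropped)) {
    message(sprintf("dropping %d count-table gene(s) absent from the GFF3",
                    length(dropped)))
    counts <- counts[rownames(counts) %in% universe, , drop = FALSE]
  }
  report$n_genes_dropped_from_counts <- length(dropped)
  report$n_universe <- length(universe)

  ## stage: classify
  targets <- tryCatch({
    rpm <- rpm_normalize(counts)
    res <- fold_change_classify(rpm[, "wt"], rpm[, "mutant"], cfg$classifier)
    report$stages$classify <- "ok"
    report$n_excluded_low_expression <- res$n_excluded
    res
  }, error = function(e) fail("classify", e))

  target_sets <- list()
  if (!is.null(targets)) {
    target_sets <- list(down = targets$down, up = targets$up)
    if (!is.null(cfg$de_table)) {
      de <- load_external_de(cfg$de_table, cfg$alpha)
      target_sets$de_down <- de$down
      target_sets$de_up <- de$up
    }
    target_sets <- Filter(function(ts) length(ts$genes) > 0, target_sets)
    report$target_set_sizes <- vapply(target_sets,
                                      function(ts) length(ts$genes),
                                      integer(1))
    write_gmt(lapply(target_sets, `[[`, "genes"),
              file.path(cfg$outdir, "target_sets.gmt"))
  }

  ## stage: enrichment screen
  if (length(target_sets)) {
    enr <- tryCatch({
      rows <- lapply(names(target_sets), function(nm) {
        cbind(target_set = nm,
              enrichment_screen(target_sets[[nm]], collection, universe,
                                n = cfg$enrichment$n_perm,
                                seed = derive_seed(cfg$seed,
                                                   paste0("screen_", nm))),
              stringsAsFactors = FALSE)
      })
      report$stages$enrichment <- "ok"
      do.call(rbind, rows)
    }, error = function(e) fail("enrichment", e))
    if (!is.null(enr)) {
      report$enrichment <- enr
      write_tsv(enr, file.path(cfg$outdir, "enrichment.tsv"))
    }
  } else report$stages$enrichment <- "skipped: no target sets"

  ## stage: conservation
  if (length(target_sets)) {
    cons <- tryCatch({
      excl <- collection[intersect(cfg$enrichment$exclude_sets,
                                   names(collection))]
      res <- run_newly_evolved_analysis(
        target_sets, homology, universe, n = cfg$enrichment$n_perm,
        seed = derive_seed(cfg$seed, "conservation"),
        genus_species = cfg$conservation$genus_species,
        outgroup_species = cfg$conservation$outgroup_species,
        exclude_sets = if (length(excl)) excl else NULL)
      report$stages$conservation <- "ok"
      res
    }, error = function(e) fail("conservation", e))
    if (!is.null(cons)) {
      report$class_enrichment <- cons
      write_tsv(cons, file.path(cfg$outdir, "class_enrichment.tsv"))
      write_tsv(attr(cons, "classes"),
                file.path(cfg$outdir, "conservation_classes.tsv"))
    }
  } else report$stages$conservation <- "skipped: no target sets"

  ## stage: metagene
  if (length(target_sets)) {
    mg <- tryCatch({
      profs <- lapply(names(target_sets), function(nm) {
        metagene_profile(track,
                         genes[genes$gene_id %in% as_gene_set(target_sets[[nm]]), ],
                         genes, window = cfg$metagene$window,
                         bin = cfg$metagene$bin,
                         n_controls = cfg$metagene$n_controls,
                         quantiles = cfg$metagene$quantiles,
                         seed = derive_seed(cfg$seed, paste0("metagene_", nm)))
      })
      names(profs) <- names(target_sets)
      report$stages$metagene <- "ok"
      profs
    }, error = function(e) fail("metagene", e))
    if (!is.null(mg)) {
      report$metagene <- mg
      for (nm in names(mg))
        write_tsv(as.data.frame(mg[[nm]]),
                  file.path(cfg$outdir, sprintf("metagene_%s.tsv", nm)))
    }
  } else report$stages$metagene <- "skipped: no target sets"

  ## stage: features
  if (length(target_sets)) {
    fr <- tryCatch({
      res <- feature_report(target_sets, universe, features)
      report$stages$features <- "ok"
      res
    }, error = function(e) fail("features", e))
    if (!is.null(fr)) {
      report$feature_report <- fr
      write_tsv(fr, file.path(cfg$outdir, "feature_report.tsv"))
    }
  } else report$stages$features <- "skipped: no target sets"

  ## machine-readable summary
  summary <- list(version = report$version,
                  seed = cfg$seed,
                  n_universe = report$n_universe,
                  n_genes_dropped_from_counts = report$n_genes_dropped_from_counts,
                  n_excluded_low_expression = report$n_excluded_low_expression,
                  target_set_sizes = as.list(report$target_set_sizes),
                  stages = report$stages)
  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("endosirna run_report\n")
  for (nm in names(x$stages)) cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]))
  if (!is.null(x$target_set_sizes)) {
    cat("  target sets:",
        paste(sprintf("%s=%d", names(x$target_set_sizes),
                      x$target_set_sizes), collapse = ", "), "\n")
  }
  invisible(x)
}
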