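## Gene-age classification from homology evidence.
##
## Three classes, following the WormBase-homology mining rules:
##   unique_to_focal            no ortholog in any surveyed species
##                              ("newly evolved")
##   genus_only                 >=1 ortholog within the genus, none outside
##   conserved_among_nematodes  >=1 ortholog within the genus and >=1 in the
##                              outgroup species
## A gene with an outgroup ortholog but no congener ortholog is not covered
## by these rules; it is assigned conserved_among_nematodes with a warning,
## since presence in an outgroup implies the gene predates the genus.
## "Duplicated" is orthogonal: the gene has a same-species paralog.

#' Default species vocabularies
#'
#' Congeneric species and outgroup nematode species used to score
#' conservation.
#' @return character vector of species labels.
#' @export
default_genus_species <- function() GENUS_SPECIES

#' @rdname default_genus_species
#' @export
default_outgroup_species <- function() OUTGROUP_SPECIES

#' Classify one gene's conservation
#'
#' @param ortholog_species character vector: the species in which the gene
#'   has at least one ortholog (multiplicity is irrelevant).
#' @param genus_species,outgroup_species species vocabularies (disjoint,
#'   non-empty).
#' @return one of `"unique_to_focal"`, `"genus_only"`,
#'   `"conserved_among_nematodes"`.
#' @export
classify_conservation <- function(ortholog_species,
                                  genus_species = default_genus_species(),
                                  outgroup_species = default_outgroup_species()) {
  if (!length(genus_species) || !length(outgroup_species))
    stop_format("species vocabularies must be non-empty")
  if (length(intersect(genus_species, outgroup_species)))
    stop_format("genus and outgroup species vocabularies overlap")
  ortholog_species <- unique(ortholog_species)
  unknown <- setdiff(ortholog_species, c(genus_species, outgroup_species))
  if (length(unknown))
    stop_format("ortholog species '%s' is in neither vocabulary", unknown[1L])
  in_genus <- any(ortholog_species %in% genus_species)
  in_out <- any(ortholog_species %in% outgroup_species)
  if (!in_genus && !in_out) return("unique_to_focal")
  if (in_genus && !in_out) return("genus_only")
  if (!in_genus && in_out) {
    warning("gene has outgroup orthologs but none in the genus; assigning conserved_among_nematodes",
            call. = FALSE)
  }
  "conserved_among_nematodes"
}

#' Classify a whole universe and derive conservation gene sets
#'
#' Genes absent from the homology table are treated as having no homology
#' evidence (hence `unique_to_focal`, i.e. newly evolved).
#'
#' @param homology a `homology_table` (see [read_homology()]).
#' @param universe character vector of gene ids to classify.
#' @param genus_species,outgroup_species species vocabularies.
#' @return list with `classes` (data.frame: gene_id, conservation_class,
#'   duplicated, newly_evolved) and `collection` (a gene-set list with the
#'   three classes plus `duplicated`, ready for [enrichment_screen()]).
#' @export
classify_universe <- function(homology, universe,
                              genus_species = default_genus_species(),
                              outgroup_species = default_outgroup_species()) {
  if (anyDuplicated(universe)) stop_format("duplicate gene ids in universe")
  orth <- homology[homology$type == "ortholog" &
                     homology$gene_id %in% universe, , drop = FALSE]
  if (anyDuplicated(orth[, c("gene_id", "species", "partner_id")]))
    stop_format("duplicate ortholog records in homology table")
  sp_by_gene <- split(orth$species, factor(orth$gene_id, levels = universe))
  cls <- vapply(sp_by_gene, classify_conservation, character(1),
                genus_species = genus_species,
                outgroup_species = outgroup_species)
  par <- homology[homology$type == "paralog", , drop = FALSE]
  dup <- universe %in% par$gene_id | universe %in% par$partner_id
  classes <- data.frame(gene_id = universe, conservation_class = unname(cls),
                        duplicated = dup,
                        newly_evolved = unname(cls) == "unique_to_focal",
                        stringsAsFactors = FALSE)
  collection <- list(
    unique_to_focal = universe[cls == "unique_to_focal"],
    genus_only = universe[cls == "genus_only"],
    conserved_among_nematodes = universe[cls == "conserved_among_nematodes"],
    duplicated = universe[dup])
  collection <- collection[lengths(collection) > 0L]
  list(classes = classes, collection = collection)
}
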