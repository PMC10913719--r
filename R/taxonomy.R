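#' Build a toy rank-annotated taxonomy
#'
#' Creates a rooted taxonomy with fixed ranks
#' root > domain > phylum > genus > species, the clade structure used by the
#' LCA classifier, species-level reestimation and genus aggregation. Species
#' are distributed over genera so that the first
#' `n_species - n_genera` genera carry two species each (with the default
#' 20 species / 18 genera community, two genera hold a congeneric pair).
#'
#' @param n_species Number of species leaves.
#' @param n_genera Number of genera; must satisfy `1 <= n_genera <= n_species`.
#' @param n_phyla Number of phyla the genera are spread over (round robin).
#' @param contaminant_ids Optional character vector of extra species ids to
#'   add as potential reagent contaminants, each under its own genus.
#' @return A tibble with columns `taxon_id`, `parent_id` (`NA` for the root),
#'   `rank` and `name`.
#' @examples
#' tax <- toy_taxonomy(20, 18)
#' taxonomy_lca(tax, "S1", "S19")
#' @export
toy_taxonomy <- function(n_species, n_genera, n_phyla = 4,
                         contaminant_ids = character()) {
  if (n_genera < 1 || n_genera > n_species) {
    stop("need 1 <= n_genera <= n_species", call. = FALSE)
  }
  n_phyla <- min(n_phyla, n_genera)
  root <- tibble(taxon_id = "root", parent_id = NA_character_,
                 rank = "root", name = "root")
  dom <- tibble(taxon_id = "D1", parent_id = "root",
                rank = "domain", name = "Bacteria")
  phyla <- tibble(taxon_id = paste0("P", seq_len(n_phyla)), parent_id = "D1",
                  rank = "phylum", name = paste0("Phylum_", seq_len(n_phyla)))
  genus_phylum <- paste0("P", ((seq_len(n_genera) - 1L) %% n_phyla) + 1L)
  genera <- tibble(taxon_id = paste0("G", seq_len(n_genera)),
                   parent_id = genus_phylum,
                   rank = "genus", name = paste0("Genus_", seq_len(n_genera)))
  sp_genus <- species_genus_map(n_species, n_genera)
  species <- tibble(taxon_id = paste0("S", seq_len(n_species)),
                    parent_id = sp_genus,
                    rank = "species",
                    name = paste0("Species_", seq_len(n_species)))
  tax <- dplyr::bind_rows(root, dom, phyla, genera, species)
  if (length(contaminant_ids) > 0) {
    cg <- paste0("G", contaminant_ids)
    tax <- dplyr::bind_rows(
      tax,
      tibble(taxon_id = cg, parent_id = "P1", rank = "genus",
             name = paste0("Genus_", contaminant_ids)),
      tibble(taxon_id = contaminant_ids, parent_id = cg, rank = "species",
             name = paste0("Contaminant_", seq_along(contaminant_ids)))
    )
  }
  validate_taxonomy(tax)
}

# genus id for each species: genus i holds species i; leftover species are
# assigned as second members of the first genera.
species_genus_map <- function(n_species, n_genera) {
  g <- integer(n_species)
  g[seq_len(n_genera)] <- seq_len(n_genera)
  extra <- seq_len(n_species - n_genera)
  g[n_genera + extra] <- extra
  paste0("G", g)
}

#' Validate a taxonomy table
#'
#' Checks the structural invariants: exactly one root, every non-root parent
#' exists, ranks strictly decrease from parent to child, species are leaves,
#' and the parent graph is acyclic.
#'
#' @param taxonomy A taxonomy tibble as returned by [toy_taxonomy()].
#' @return The taxonomy, invisibly coerced to a tibble, or an error.
#' @export
validate_taxonomy <- function(taxonomy) {
  taxonomy <- as_tibble(taxonomy)
  need <- c("taxon_id", "parent_id", "rank", "name")
  if (!all(need %in% names(taxonomy))) {
    stop("taxonomy needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(taxonomy$taxon_id)) stop("duplicate taxon_id", call. = FALSE)
  roots <- which(is.na(taxonomy$parent_id))
  if (length(roots) != 1) stop("taxonomy must have exactly one root", call. = FALSE)
  if (taxonomy$rank[roots] != "root") stop("root node must have rank 'root'", call. = FALSE)
  known <- c(root = 0L, domain = 1L, phylum = 2L, genus = 3L, species = 4L)
  if (!all(taxonomy$rank %in% names(known))) {
    stop("unknown rank(s): ",
         paste(setdiff(taxonomy$rank, names(known)), collapse = ", "),
         call. = FALSE)
  }
  pid <- taxonomy$parent_id[!is.na(taxonomy$parent_id)]
  if (!all(pid %in% taxonomy$taxon_id)) stop("missing parent node(s)", call. = FALSE)
  pidx <- match(taxonomy$parent_id, taxonomy$taxon_id)
  ok <- is.na(pidx) |
    known[taxonomy$rank] > known[taxonomy$rank[pidx]]
  if (!all(ok)) stop("parent rank must be strictly higher than child rank", call. = FALSE)
  is_parent <- taxonomy$taxon_id %in% taxonomy$parent_id
  if (any(is_parent & taxonomy$rank == "species")) {
    stop("species nodes must be leaves", call. = FALSE)
  }
  # rank monotonicity on a finite rank set already rules out cycles
  taxonomy
}

# Integer indexing of a taxonomy for the C++ layer: 1-based parent vector
# (0 for the root) and depth (root = 0).
taxonomy_index <- function(taxonomy) {
  parent <- match(taxonomy$parent_id, taxonomy$taxon_id)
  parent[is.na(parent)] <- 0L
  depth <- integer(nrow(taxonomy))
  # ranks are fixed, so depth = rank level
  lv <- c(root = 0L, domain = 1L, phylum = 2L, genus = 3L, species = 4L)
  depth <- unname(lv[taxonomy$rank])
  list(ids = taxonomy$taxon_id, parent = as.integer(parent),
       depth = as.integer(depth))
}

#' Ancestors of a taxon (self first, root last)
#'
#' @param taxonomy A taxonomy tibble.
#' @param taxon_id A single taxon id.
#' @return Character vector of taxon ids from `taxon_id` up to the root.
#' @export
taxonomy_ancestors <- function(taxonomy, taxon_id) {
  out <- character()
  cur <- taxon_id
  while (!is.na(cur)) {
    i <- match(cur, taxonomy$taxon_id)
    if (is.na(i)) stop("unknown taxon: ", cur, call. = FALSE)
    out <- c(out, cur)
    cur <- taxonomy$parent_id[i]
  }
  out
}

#' Lowest common ancestor of a set of taxa
#'
#' @param taxonomy A taxonomy tibble.
#' @param ... Taxon ids (character), or a single character vector.
#' @return The taxon id of the LCA.
#' @examples
#' tax <- toy_taxonomy(4, 2)
#' taxonomy_lca(tax, "S1", "S3")  # congeneric pair -> their genus
#' @export
taxonomy_lca <- function(taxonomy, ...) {
  ids <- unlist(list(...), use.names = FALSE)
  if (length(ids) == 0) stop("no taxa given", call. = FALSE)
  Reduce(function(a, b) {
    pa <- rev(taxonomy_ancestors(taxonomy, a))
    pb <- rev(taxonomy_ancestors(taxonomy, b))
    n <- min(length(pa), length(pb))
    common <- which(pa[seq_len(n)] == pb[seq_len(n)])
    pa[max(common)]
  }, ids)
}

#' Species descending from a taxon
#'
#' @param taxonomy A taxonomy tibble.
#' @param taxon_id A single taxon id.
#' @return Character vector of descendant species ids (the taxon itself if it
#'   is a species).
#' @export
taxonomy_species_under <- function(taxonomy, taxon_id) {
  if (!taxon_id %in% taxonomy$taxon_id) stop("unknown taxon: ", taxon_id, call. = FALSE)
  frontier <- taxon_id
  species <- character()
  while (length(frontier) > 0) {
    rk <- taxonomy$rank[match(frontier, taxonomy$taxon_id)]
    species <- c(species, frontier[rk == "species"])
    frontier <- taxonomy$taxon_id[taxonomy$parent_id %in% frontier[rk != "species"]]
  }
  sort(species)
}

#' Read or write a taxonomy as 4-column TSV
#'
#' Columns: `taxon_id`, `parent_id` (empty for the root), `rank`, `name`.
#'
#' @param taxonomy A taxonomy tibble.
#' @param path File path.
#' @return `write_taxonomy_tsv()` returns `path` invisibly;
#'   `read_taxonomy_tsv()` returns a validated taxonomy tibble.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  readr::write_tsv(validate_taxonomy(taxonomy), path)
  invisible(path)
}

#' @rdname write_taxonomy_tsv
#' @export
read_taxonomy_tsv <- function(path) {
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  validate_taxonomy(tax)
}
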