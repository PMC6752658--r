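#' Read and annotate a two-species gene tree
#'
#' Parses a Newick gene tree of family members and labels every tip as
#' belonging to the focal or the outgroup species using a sidecar species map.
#' Unrooted input is midpoint-rooted with a warning, since detection of
#' focal-species-only clades depends on the rooting.
#'
#' @param newick Path to a Newick file, or a Newick string.
#' @param species_map A data frame with columns `gene_id` and `species`
#'   (values `"focal"` or `"outgroup"`), or a path to such a two-column TSV.
#' @return An object of class `"gene_tree"`: a list with elements `phylo`
#'   (the rooted [ape::read.tree()] tree) and `tips` (tibble of `gene_id`,
#'   `species`).
#' @export
#' @examples
#' sm <- tibble::tibble(
#'   gene_id = c("A1", "A2", "O1", "O2"),
#'   species = c("focal", "focal", "outgroup", "outgroup")
#' )
#' tr <- parse_gene_tree("((A1,A2),(O1,O2));", sm)
#' tr$tips
parse_gene_tree <- function(newick, species_map) {
  if (length(newick) == 1 && !grepl("[();]", newick) && file.exists(newick)) {
    phy <- ape::read.tree(newick)
  } else {
    phy <- ape::read.tree(text = paste(newick, collapse = "\n"))
  }
  if (is.null(phy)) abort("could not parse Newick input")
  if (is.character(species_map) && length(species_map) == 1) {
    species_map <- read_species_map(species_map)
  }
  species_map <- as_tibble(species_map)
  stopifnot(all(c("gene_id", "species") %in% names(species_map)))
  if (!all(species_map$species %in% c("focal", "outgroup"))) {
    abort("species must be 'focal' or 'outgroup'")
  }
  if (anyDuplicated(phy$tip.label)) abort("tip gene_ids must be unique")
  missing <- setdiff(phy$tip.label, species_map$gene_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "tips absent from species map: %s",
      paste(missing, collapse = ", ")
    ))
  }
  if (!ape::is.rooted(phy)) {
    warn("input tree is unrooted; rooting at the midpoint")
    if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
    phy <- phangorn::midpoint(phy)
  }
  tips <- tibble(
    gene_id = phy$tip.label,
    species = species_map$species[match(phy$tip.label, species_map$gene_id)]
  )
  structure(list(phylo = phy, tips = tips), class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf(
    "<gene_tree> %d tips (%d focal, %d outgroup)\n",
    nrow(x$tips), sum(x$tips$species == "focal"),
    sum(x$tips$species == "outgroup")
  ))
  invisible(x)
}

#' Read a gene-to-species map
#'
#' @param path TSV with columns `gene_id` and `species`.
#' @return A tibble.
#' @export
read_species_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' Write a gene-to-species map
#' @param species_map Tibble with `gene_id`, `species`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_species_map <- function(species_map, path) {
  readr::write_tsv(species_map, path)
  invisible(path)
}
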