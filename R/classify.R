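#' Find focal-species-only clusters in a gene tree
#'
#' A focal cluster is a maximal clade containing only focal-species tips and
#' at least two of them. "Maximal" means the parent clade contains at least
#' one outgroup tip, so a cluster marks a lineage-specific expansion after the
#' two species split. Singleton focal tips are never clusters, and a polytomy
#' mixing focal and outgroup tips is not focal-only.
#'
#' @param tree A `"gene_tree"` from [parse_gene_tree()].
#' @return Tibble with columns `cluster_id`, `gene_id`, `support` (the support
#'   label of the defining node, `NA` when absent). Clusters are disjoint.
#' @export
#' @examples
#' sm <- tibble::tibble(
#'   gene_id = c("A1", "A2", "O1"),
#'   species = c("focal", "focal", "outgroup")
#' )
#' find_focal_clusters(parse_gene_tree("((A1,A2),O1);", sm))
find_focal_clusters <- function(tree) {
  stopifnot(inherits(tree, "gene_tree"))
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  is_focal_tip <- tree$tips$species == "focal"
  if (!any(is_focal_tip)) abort("tree has no focal-species tips")
  if (all(is_focal_tip)) abort("tree has no outgroup tips; classification needs both species")

  n_node <- phy$Nnode
  all_focal <- logical(n_tip + n_node)
  all_focal[seq_len(n_tip)] <- is_focal_tip
  parent_of <- integer(n_tip + n_node)
  # postorder guarantees children are resolved before their parent
  po <- ape::reorder.phylo(phy, "postorder")
  agg <- rep(TRUE, n_tip + n_node)
  agg[seq_len(n_tip)] <- is_focal_tip
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]
    ch <- po$edge[k, 2]
    agg[p] <- agg[p] & agg[ch]
    parent_of[ch] <- p
  }
  all_focal <- agg

  root <- n_tip + 1L
  nodes <- (n_tip + 1L):(n_tip + n_node)
  is_maximal <- vapply(nodes, function(nd) {
    all_focal[nd] && (nd == root || !all_focal[parent_of[nd]])
  }, logical(1))
  maximal <- nodes[is_maximal]

  clusters <- lapply(maximal, function(nd) {
    tips <- tip_descendants(phy, nd)
    if (length(tips) < 2) return(NULL)
    tibble(
      gene_id = phy$tip.label[tips],
      support = node_support(phy, nd, n_tip)
    )
  })
  clusters <- clusters[!vapply(clusters, is.null, logical(1))]
  if (length(clusters) == 0) {
    return(tibble(
      cluster_id = character(), gene_id = character(),
      support = character()
    ))
  }
  # order clusters by smallest member id so output is ladderization-invariant
  ord <- order(vapply(clusters, function(cl) min(cl$gene_id), character(1)))
  bind_rows(lapply(seq_along(ord), function(i) {
    cl <- clusters[[ord[i]]]
    cl <- cl[order(cl$gene_id), ]
    mutate(cl, cluster_id = sprintf("C%02d", i), .before = 1)
  }))
}

tip_descendants <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(node)
  stack <- node
  tips <- integer(0)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  while (length(stack) > 0) {
    nd <- stack[[1]]
    stack <- stack[-1]
    ch <- children[[as.character(nd)]]
    tips <- c(tips, ch[ch <= n_tip])
    stack <- c(stack, ch[ch > n_tip])
  }
  sort(tips)
}

node_support <- function(phy, node, n_tip) {
  if (is.null(phy$node.label)) return(NA_character_)
  lab <- phy$node.label[node - n_tip]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) NA_character_ else lab
}

#' Assign type I / type II status to focal genes
#'
#' Type I genes belong to a focal cluster (lineage-specific expansion); all
#' other focal genes are type II, i.e. presumed single-copy descendants of
#' genes already present in the common ancestor of the two species.
#'
#' @param tree A `"gene_tree"`.
#' @param clusters Output of [find_focal_clusters()].
#' @return Tibble `gene_id`, `gene_type` (`"I"`/`"II"`) for all focal genes.
#' @export
assign_gene_types <- function(tree, clusters = find_focal_clusters(tree)) {
  focal <- tree$tips$gene_id[tree$tips$species == "focal"]
  tibble(
    gene_id = focal,
    gene_type = ifelse(focal %in% clusters$gene_id, "I", "II")
  )
}

#' Nearest outgroup tips of each focal gene
#'
#' For every focal tip, walks towards the root until the enclosing clade
#' contains outgroup tips; those outgroup tips are the gene's nearest
#' outgroup orthologs under the tree topology.
#'
#' @param tree A `"gene_tree"`.
#' @return Named list: focal gene_id -> character vector of outgroup gene_ids.
#' @export
build_ortholog_map <- function(tree) {
  phy <- tree$phylo
  n_tip <- length(phy$tip.label)
  is_out <- tree$tips$species == "outgroup"
  parent_of <- integer(n_tip + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  root <- n_tip + 1L
  focal_idx <- which(!is_out)
  out <- lapply(focal_idx, function(i) {
    nd <- i
    repeat {
      if (nd == root) break
      nd <- parent_of[nd]
      tips <- tip_descendants(phy, nd)
      o <- tips[is_out[tips]]
      if (length(o) > 0) return(phy$tip.label[o])
    }
    tips <- tip_descendants(phy, root)
    phy$tip.label[tips[is_out[tips]]]
  })
  setNames(out, phy$tip.label[focal_idx])
}

#' Outgroup evidence that a focal tandem pair is ancestral
#'
#' Checks whether some ortholog of the first gene and some ortholog of the
#' second form a tandem pair in the outgroup genome under the same pair rule.
#' Tandem arrangement of the orthologs corroborates that the focal pair arose
#' before the species split; its absence is not counter-evidence, since the
#' outgroup genome may have been rearranged.
#'
#' @param focal_pair Character vector of two focal gene_ids.
#' @param ortholog_map From [build_ortholog_map()].
#' @param outgroup_genes Gene tibble for the outgroup genome with
#'   `is_family_member` set for family genes.
#' @param config [analysis_config()].
#' @return Logical scalar; `FALSE` (with a note) when either ortholog set is
#'   empty.
#' @export
outgroup_tandem_evidence <- function(focal_pair, ortholog_map, outgroup_genes,
                                     config = analysis_config()) {
  o1 <- ortholog_map[[focal_pair[1]]]
  o2 <- ortholog_map[[focal_pair[2]]]
  o1 <- intersect(o1, outgroup_genes$gene_id)
  o2 <- intersect(o2, outgroup_genes$gene_id)
  if (length(o1) == 0 || length(o2) == 0) {
    inform(sprintf(
      "no outgroup orthologs available for pair %s/%s",
      focal_pair[1], focal_pair[2]
    ))
    return(FALSE)
  }
  for (a in o1) {
    for (b in o2) {
      if (a == b) next
      if (is_tandem_pair(outgroup_genes, a, b, config)) return(TRUE)
    }
  }
  FALSE
}

#' Classify tandem family genes as lineage-specific, ancestral, or both
#'
#' A tandem gene is *lineage-specific* when at least one of its direct tandem
#' partners (same repeat, pair rule satisfied between the two genes) belongs
#' to its own focal cluster — the duplication postdates the species split. It
#' is *ancestral* when it is a type II gene sitting in a repeat, or when it is
#' arrayed in tandem with a gene outside its cluster — the tandem arrangement
#' predates the split. A gene meeting both conditions is classed `both`.
#' Type II membership in a repeat suffices for "ancestral" even without
#' outgroup tandem evidence, because outgroup genome rearrangement can erase
#' the ortholog arrangement; [outgroup_tandem_evidence()] results are attached
#' as corroborating evidence only.
#'
#' @param repeats Output of [detect_tandem_repeats()].
#' @param clusters Output of [find_focal_clusters()].
#' @param types Output of [assign_gene_types()].
#' @param genes Gene tibble (focal genome), needed to test the direct pair
#'   rule between repeat co-members.
#' @param config [analysis_config()].
#' @param evidence Optional tibble `gene1`, `gene2`, `outgroup_tandem`
#'   (logical) from [outgroup_tandem_evidence()].
#' @return Tibble of labels for every focal gene in `types`: `gene_id`,
#'   `gene_type`, `tandem_class` (`lineage_specific`, `ancestral`, `both`,
#'   `none`), `evidence` (list of character).
#' @export
classify_tandem_genes <- function(repeats, clusters, types, genes,
                                  config = analysis_config(),
                                  evidence = NULL) {
  config <- as_analysis_config(config)
  missing <- setdiff(repeats$gene_id, types$gene_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "tandem genes absent from the gene tree: %s",
      paste(missing, collapse = ", ")
    ))
  }
  cluster_of <- setNames(clusters$cluster_id, clusters$gene_id)
  repeat_of <- setNames(repeats$repeat_id, repeats$gene_id)

  labels <- lapply(types$gene_id, function(g) {
    ev <- character(0)
    cl <- unname(cluster_of[g])
    if (!is.na(cl)) ev <- c(ev, sprintf("cluster:%s", cl))
    rid <- unname(repeat_of[g])
    if (is.na(rid)) {
      return(tibble(
        gene_id = g, tandem_class = "none", evidence = list(ev)
      ))
    }
    ev <- c(ev, sprintf("repeat:%s", rid))
    co <- repeats$gene_id[repeats$repeat_id == rid & repeats$gene_id != g]
    partners <- co[vapply(
      co, function(h) is_tandem_pair(genes, g, h, config), logical(1)
    )]
    in_cluster <- !is.na(cl) &
      vapply(partners, function(h) identical(unname(cluster_of[h]), cl), logical(1))
    ls <- any(in_cluster)
    type2 <- types$gene_type[types$gene_id == g] == "II"
    outside <- partners[!vapply(
      partners,
      function(h) !is.na(cl) && identical(unname(cluster_of[h]), cl),
      logical(1)
    )]
    anc <- type2 || length(outside) > 0
    if (ls) {
      ev <- c(ev, sprintf(
        "partner_in_cluster:%s",
        paste(partners[in_cluster], collapse = ",")
      ))
    }
    if (length(outside) > 0) {
      ev <- c(ev, sprintf(
        "partner_outside_cluster:%s", paste(outside, collapse = ",")
      ))
    }
    if (type2) ev <- c(ev, "type_II_in_repeat")
    cls <- if (ls && anc) "both" else if (ls) "lineage_specific" else "ancestral"
    tibble(gene_id = g, tandem_class = cls, evidence = list(ev))
  })
  out <- left_join(types, bind_rows(labels), by = "gene_id")
  if (!is.null(evidence) && nrow(evidence) > 0) {
    for (i in seq_len(nrow(evidence))) {
      for (g in c(evidence$gene1[i], evidence$gene2[i])) {
        j <- match(g, out$gene_id)
        if (!is.na(j)) {
          out$evidence[[j]] <- c(out$evidence[[j]], sprintf(
            "outgroup_tandem[%s/%s]:%s",
            evidence$gene1[i], evidence$gene2[i],
            evidence$outgroup_tandem[i]
          ))
        }
      }
    }
  }
  out
}

#' Summarise duplicate labels
#'
#' Gene-level and repeat-level tallies of the classification. Gene-level
#' counts follow inclusion-exclusion: genes classed `both` are counted inside
#' both the lineage-specific and the ancestral totals.
#'
#' @param labels Output of [classify_tandem_genes()].
#' @param repeats Output of [detect_tandem_repeats()].
#' @return A list of class `"tandem_class_summary"`.
#' @export
summarize_duplicate_labels <- function(labels, repeats) {
  tc <- labels$tandem_class
  n_tandem <- sum(tc != "none")
  n_both <- sum(tc == "both")
  n_ls <- sum(tc %in% c("lineage_specific", "both"))
  n_anc <- sum(tc %in% c("ancestral", "both"))
  rep_sizes <- repeats |>
    distinct(.data$repeat_id, .data$n_members)
  rep_class <- repeats |>
    left_join(labels, by = "gene_id") |>
    group_by(.data$repeat_id) |>
    summarise(
      has_ls = any(.data$tandem_class %in% c("lineage_specific", "both")),
      has_anc = any(.data$tandem_class %in% c("ancestral", "both"))
    )
  structure(list(
    n_focal_genes = nrow(labels),
    n_type_I = sum(labels$gene_type == "I"),
    n_type_II = sum(labels$gene_type == "II"),
    n_clusters = length(unique(unlist(lapply(
      labels$evidence,
      function(e) grep("^cluster:", e, value = TRUE)
    )))),
    n_tandem_genes = n_tandem,
    n_lineage_specific = n_ls,
    n_ancestral = n_anc,
    n_both = n_both,
    n_repeats = nrow(rep_sizes),
    mean_repeat_size = if (nrow(rep_sizes) > 0) mean(rep_sizes$n_members) else NA_real_,
    n_repeats_with_lineage_specific = sum(rep_class$has_ls),
    n_repeats_with_ancestral = sum(rep_class$has_anc),
    pct_tandem = percent(n_tandem, nrow(labels))
  ), class = "tandem_class_summary")
}

#' @export
print.tandem_class_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Tandem duplicate classification\n",
      "  focal genes: %d (type I %d in %d clusters, type II %d)\n",
      "  tandem genes: %d (%s) in %d repeats (mean size %.2f)\n",
      "  lineage-specific: %d, ancestral: %d, both: %d\n"
    ),
    x$n_focal_genes, x$n_type_I, x$n_clusters, x$n_type_II,
    x$n_tandem_genes, format_percent(x$n_tandem_genes, x$n_focal_genes),
    x$n_repeats, x$mean_repeat_size,
    x$n_lineage_specific, x$n_ancestral, x$n_both
  ))
  invisible(x)
}
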