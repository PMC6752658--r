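#' Intron counts and pairwise intron differences
#'
#' The intron count of a gene is its number of exons minus one. A duplicate
#' pair is "structure-divergent" when its absolute intron-count difference is
#' greater than zero.
#'
#' @param genes Gene tibble (see [parse_gff_genes()]); every gene needs at
#'   least one annotated exon.
#' @return `intron_counts()`: tibble `gene_id`, `n_introns`.
#' @export
#' @examples
#' genes <- parse_gff_genes(c(
#'   "##gff-version 3",
#'   "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1",
#'   "chr1\tsrc\texon\t300\t500\t.\t+\t.\tParent=g1"
#' ))
#' intron_counts(genes) # one intron
intron_counts <- function(genes) {
  n_ex <- vapply(genes$exons, nrow, integer(1))
  if (any(n_ex == 0)) {
    abort(sprintf(
      "gene(s) without exon annotation: %s",
      paste(genes$gene_id[n_ex == 0], collapse = ", ")
    ))
  }
  tibble(gene_id = genes$gene_id, n_introns = n_ex - 1L)
}

#' @rdname intron_counts
#' @param gene1,gene2 gene_ids of the pair.
#' @return `pair_intron_difference()`: non-negative integer.
#' @export
pair_intron_difference <- function(genes, gene1, gene2) {
  ic <- intron_counts(genes[genes$gene_id %in% c(gene1, gene2), ])
  n1 <- ic$n_introns[match(gene1, ic$gene_id)]
  n2 <- ic$n_introns[match(gene2, ic$gene_id)]
  if (is.na(n1) || is.na(n2)) {
    abort("both genes must be present with exon annotations")
  }
  abs(n1 - n2)
}

#' Motif-architecture difference between two proteins
#'
#' Scores the arrangement difference of two motif architectures as the size of
#' the symmetric difference of their motif-id multisets: presence/absence and
#' copy-number changes count, order does not.
#'
#' @param motifs Motif table ([read_motif_table()]): `gene_id`, `motif_id`,
#'   `start`.
#' @param gene1,gene2 gene_ids to compare.
#' @param motif_set Declared motif universe; defaults to the ids present in
#'   `motifs`. Ids outside the universe raise an error.
#' @return Non-negative integer.
#' @export
#' @examples
#' m <- tibble::tibble(
#'   gene_id = c("a", "a", "a", "b", "b", "b", "b"),
#'   motif_id = c("m1", "m2", "m5", "m1", "m2", "m7", "m8"),
#'   start = c(1L, 10L, 20L, 1L, 10L, 20L, 30L)
#' )
#' motif_difference(m, "a", "b") # 3
motif_difference <- function(motifs, gene1, gene2,
                             motif_set = unique(motifs$motif_id)) {
  bad <- setdiff(motifs$motif_id, motif_set)
  if (length(bad) > 0) {
    abort(sprintf("unknown motif id(s): %s", paste(unique(bad), collapse = ", ")))
  }
  m1 <- motifs$motif_id[motifs$gene_id == gene1]
  m2 <- motifs$motif_id[motifs$gene_id == gene2]
  t1 <- table(factor(m1, levels = motif_set))
  t2 <- table(factor(m2, levels = motif_set))
  sum(abs(t1 - t2))
}

#' Structural divergence over a set of gene pairs
#'
#' @param genes Gene tibble with exon annotations.
#' @param motifs Motif table, or `NULL` to skip motif scoring.
#' @param pairs Tibble `gene1`, `gene2`.
#' @return Tibble: `gene1`, `gene2`, `intron_difference`,
#'   `structure_divergent`, and `motif_difference` when motifs are given.
#' @export
structural_divergence_table <- function(genes, pairs, motifs = NULL) {
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs$gene1[i]
    g2 <- pairs$gene2[i]
    d <- pair_intron_difference(genes, g1, g2)
    row <- tibble(
      gene1 = g1, gene2 = g2,
      intron_difference = d, structure_divergent = d > 0
    )
    if (!is.null(motifs)) {
      row$motif_difference <- motif_difference(motifs, g1, g2)
    }
    row
  })
  bind_rows(out)
}
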