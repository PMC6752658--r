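#' Count non-family genes lying between two genes
#'
#' Counts the genes whose full span lies strictly inside the interval between
#' the end of the upstream gene and the start of the downstream gene and that
#' are not family members. Family members sitting in between are not counted
#' against the tandem criterion.
#'
#' @param genes Gene tibble (see [parse_gff_genes()]) providing the gene
#'   universe scanned for intervening genes.
#' @param gene1,gene2 gene_ids of the two genes (same chromosome).
#' @return Integer count.
#' @export
count_intervening <- function(genes, gene1, gene2) {
  g1 <- gene_row(genes, gene1)
  g2 <- gene_row(genes, gene2)
  if (g1$chromosome != g2$chromosome) {
    abort("count_intervening requires genes on the same chromosome")
  }
  if (g1$start > g2$start) {
    tmp <- g1
    g1 <- g2
    g2 <- tmp
  }
  lo <- g1$end
  hi <- g2$start
  sum(
    genes$chromosome == g1$chromosome &
      !genes$is_family_member &
      genes$start > lo & genes$end < hi
  )
}

gene_row <- function(genes, id) {
  i <- match(id, genes$gene_id)
  if (is.na(i)) abort(sprintf("gene '%s' not found", id))
  genes[i, ]
}

pair_gap <- function(g1, g2, mode) {
  if (mode == "anchor") {
    abs(g2$start - g1$start)
  } else {
    if (g1$start > g2$start) {
      tmp <- g1
      g1 <- g2
      g2 <- tmp
    }
    max(0L, g2$start - g1$end)
  }
}

#' Test the tandem pair criterion for two family genes
#'
#' Two family genes form a tandem pair when they lie on the same chromosome,
#' within `max_pair_distance_bp` of each other (inner gap by default), and are
#' separated by at most `max_intervening` non-family genes. Strand plays no
#' role.
#'
#' @inheritParams count_intervening
#' @param config [analysis_config()].
#' @return Logical scalar.
#' @export
is_tandem_pair <- function(genes, gene1, gene2, config = analysis_config()) {
  config <- as_analysis_config(config)
  g1 <- gene_row(genes, gene1)
  g2 <- gene_row(genes, gene2)
  if (!g1$is_family_member || !g2$is_family_member) {
    abort("is_tandem_pair is defined for family members only")
  }
  if (g1$chromosome != g2$chromosome) return(FALSE)
  if (pair_gap(g1, g2, config$distance_mode) > config$max_pair_distance_bp) {
    return(FALSE)
  }
  count_intervening(genes, gene1, gene2) <= config$max_intervening
}

#' Detect tandem repeats of family genes
#'
#' Evaluates the tandem pair criterion between all family-gene pairs and
#' chains qualifying pairs by single linkage into maximal repeats, so a repeat
#' is the connected component of the qualifying-pair graph. Output order is
#' deterministic: repeats sorted by (chromosome, span start), members by start
#' coordinate.
#'
#' @param genes Gene tibble with family flags set.
#' @param config [analysis_config()].
#' @return A tibble with one row per repeat member: `repeat_id`, `chromosome`,
#'   `gene_id`, `span_start`, `span_end`, `n_members`.
#' @export
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = c("g1", "g2", "g3"),
#'   chromosome = "chr1",
#'   start = c(1000L, 5000L, 900000L),
#'   end = c(2000L, 6000L, 901000L),
#'   strand = "+",
#'   exons = list(
#'     cbind(start = 1000L, end = 2000L),
#'     cbind(start = 5000L, end = 6000L),
#'     cbind(start = 900000L, end = 901000L)
#'   ),
#'   is_family_member = TRUE
#' )
#' detect_tandem_repeats(genes) # g1+g2 form a repeat, g3 is too far
detect_tandem_repeats <- function(genes, config = analysis_config()) {
  config <- as_analysis_config(config)
  genes <- arrange(genes, .data$chromosome, .data$start, .data$gene_id)
  fam <- genes[genes$is_family_member, ]
  empty <- tibble(
    repeat_id = character(), chromosome = character(), gene_id = character(),
    span_start = integer(), span_end = integer(), n_members = integer()
  )
  if (nrow(fam) < 2) return(empty)

  # union-find over family genes; only same-chromosome pairs can qualify,
  # and on a sorted layout the gap test lets us stop extending early
  parent <- seq_len(nrow(fam))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  max_len <- max(fam$end - fam$start)
  for (i in seq_len(nrow(fam) - 1)) {
    for (j in (i + 1):nrow(fam)) {
      if (fam$chromosome[j] != fam$chromosome[i]) break
      # sorted by start, so once starts are too far apart no later j qualifies
      # (inner gap >= start_j - start_i - gene length)
      d_start <- fam$start[j] - fam$start[i]
      if (config$distance_mode == "anchor") {
        if (d_start > config$max_pair_distance_bp) break
      } else if (d_start > config$max_pair_distance_bp + max_len) {
        break
      }
      if (is_tandem_pair(genes, fam$gene_id[i], fam$gene_id[j], config)) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(nrow(fam)), find, integer(1))
  keep <- comp %in% comp[duplicated(comp)]
  if (!any(keep)) return(empty)
  members <- fam[keep, ]
  members$comp <- comp[keep]
  members <- members |>
    group_by(.data$comp) |>
    mutate(span_start = min(.data$start), span_end = max(.data$end)) |>
    ungroup() |>
    arrange(.data$chromosome, .data$span_start, .data$start, .data$gene_id)
  ids <- unique(members$comp)
  members$repeat_id <- sprintf(
    "TR%03d", match(members$comp, ids)
  )
  select(
    members, "repeat_id", "chromosome", "gene_id", "span_start", "span_end"
  ) |>
    group_by(.data$repeat_id) |>
    mutate(n_members = dplyr::n()) |>
    ungroup()
}
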