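#' Read gene models from a GFF3 file
#'
#' Extracts `gene` features and their `exon` children from a GFF3 annotation
#' and flags the genes belonging to the family under study. Exons are attached
#' to genes through their `Parent` attribute, following either the gene
#' directly or an intermediate mRNA feature.
#'
#' @param gff Path to a GFF3 file, or a character vector of GFF3 text lines.
#' @param family_ids Character vector of gene identifiers belonging to the
#'   gene family of interest.
#' @return A tibble with one row per gene, columns `gene_id`, `chromosome`,
#'   `start`, `end`, `strand`, `exons` (list column of two-column integer
#'   matrices, one exon per row) and `is_family_member`, sorted by
#'   (chromosome, start, gene_id). Coordinates are 1-based and inclusive.
#' @export
#' @examples
#' gff <- c(
#'   "##gff-version 3",
#'   "chr1\tsrc\tgene\t100\t500\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1",
#'   "chr1\tsrc\texon\t300\t500\t.\t+\t.\tParent=g1"
#' )
#' parse_gff_genes(gff, family_ids = "g1")
parse_gff_genes <- function(gff, family_ids = character()) {
  path <- resolve_gff_input(gff)
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  lineno <- which(body)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) >= 5) {
      s <- suppressWarnings(as.numeric(f[4]))
      e <- suppressWarnings(as.numeric(f[5]))
      if (!is.na(s) && !is.na(e) && s > e) {
        abort(sprintf(
          "malformed coordinates on line %d: start (%s) > end (%s)",
          lineno[i], f[4], f[5]
        ))
      }
    }
  }

  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_gene <- type == "gene"
  if (!any(is_gene)) abort("no gene features found in GFF3 input")

  gene_ids <- as.character(gr$ID[is_gene])
  if (anyNA(gene_ids)) abort("gene feature without an ID attribute")
  if (anyDuplicated(gene_ids)) {
    abort(sprintf(
      "duplicate gene_id in GFF3: %s",
      paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")
    ))
  }

  # map transcript-level features back to their parent gene so exons whose
  # Parent is an mRNA still resolve
  feat_id <- as.character(gr$ID)
  parent_of <- vapply(gr$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  idx_tx <- which(!is_gene & !is.na(feat_id))
  tx_to_gene <- setNames(parent_of[idx_tx], feat_id[idx_tx])

  is_exon <- type == "exon"
  exon_gene <- character(sum(is_exon))
  exon_idx <- which(is_exon)
  for (k in seq_along(exon_idx)) {
    p <- parent_of[exon_idx[k]]
    if (is.na(p)) abort("exon without a Parent attribute")
    if (p %in% gene_ids) {
      exon_gene[k] <- p
    } else if (!is.na(tx_to_gene[p]) && tx_to_gene[p] %in% gene_ids) {
      exon_gene[k] <- tx_to_gene[p]
    } else {
      abort(sprintf("exon Parent '%s' does not resolve to a gene", p))
    }
  }

  ex_start <- GenomicRanges::start(gr)[is_exon]
  ex_end <- GenomicRanges::end(gr)[is_exon]
  exons_by_gene <- split(
    data.frame(start = ex_start, end = ex_end),
    factor(exon_gene, levels = gene_ids)
  )

  genes <- tibble(
    gene_id = gene_ids,
    chromosome = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    exons = unname(lapply(exons_by_gene, function(d) {
      d <- d[order(d$start), , drop = FALSE]
      matrix(c(d$start, d$end),
        ncol = 2,
        dimnames = list(NULL, c("start", "end"))
      )
    })),
    is_family_member = gene_ids %in% family_ids
  )
  genes$strand[genes$strand == "*"] <- "."
  validate_genes(genes)
  arrange(genes, .data$chromosome, .data$start, .data$gene_id)
}

resolve_gff_input <- function(gff) {
  if (length(gff) == 1 && !grepl("\n", gff) && file.exists(gff)) return(gff)
  path <- tempfile(fileext = ".gff3")
  writeLines(unlist(strsplit(gff, "\n", fixed = TRUE)), path)
  path
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [parse_gff_genes()]: emits one `gene` feature per row plus its
#' exons, so a written table re-reads to an identical structure.
#'
#' @param genes Gene tibble as returned by [parse_gff_genes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  validate_genes(genes)
  n_ex <- vapply(genes$exons, nrow, integer(1))
  feat <- tibble(
    seqnames = c(genes$chromosome, rep(genes$chromosome, n_ex)),
    start = c(genes$start, unlist(lapply(genes$exons, function(m) m[, 1]))),
    end = c(genes$end, unlist(lapply(genes$exons, function(m) m[, 2]))),
    strand = c(genes$strand, rep(genes$strand, n_ex)),
    type = c(rep("gene", nrow(genes)), rep("exon", sum(n_ex))),
    ID = c(genes$gene_id, rep(NA_character_, sum(n_ex))),
    Parent = c(rep(NA_character_, nrow(genes)), rep(genes$gene_id, n_ex))
  )
  feat$strand[feat$strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = feat$seqnames,
    ranges = IRanges::IRanges(feat$start, feat$end),
    strand = feat$strand
  )
  gr$type <- feat$type
  gr$ID <- feat$ID
  gr$Parent <- ifelse(is.na(feat$Parent), "", feat$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

validate_genes <- function(genes) {
  stopifnot(all(c(
    "gene_id", "chromosome", "start", "end", "strand", "exons",
    "is_family_member"
  ) %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) abort("gene_id values must be unique")
  if (any(genes$start > genes$end)) abort("gene with start > end")
  if (!all(genes$strand %in% c("+", "-", "."))) abort("strand must be +, - or .")
  for (i in seq_len(nrow(genes))) {
    ex <- genes$exons[[i]]
    if (nrow(ex) == 0) next
    if (any(ex[, 1] > ex[, 2])) abort("exon with start > end")
    if (any(ex[, 1] < genes$start[i]) || any(ex[, 2] > genes$end[i])) {
      abort(sprintf("exon outside gene span for %s", genes$gene_id[i]))
    }
    if (nrow(ex) > 1) {
      if (is.unsorted(ex[, 1])) abort("exons must be sorted by start")
      if (any(ex[-1, 1] <= ex[-nrow(ex), 2])) {
        abort(sprintf("overlapping exons in %s", genes$gene_id[i]))
      }
    }
  }
  invisible(genes)
}
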