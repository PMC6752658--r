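#' Read an expression matrix (genes x stages, RPKM)
#'
#' @param path TSV path (or literal text): header row of stage labels, first
#'   column `gene_id`, numeric RPKM body.
#' @return A tibble with a `gene_id` column followed by one numeric column per
#'   stage.
#' @export
parse_expression_table <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      .default = readr::col_double(),
      gene_id = readr::col_character()
    )
  )
  names(x)[1] <- "gene_id"
  validate_expression(x)
  x
}

validate_expression <- function(x) {
  if (!is.data.frame(x) || ncol(x) < 2) abort("expression matrix needs gene_id plus >=1 stage")
  if (names(x)[1] != "gene_id") abort("first expression column must be gene_id")
  if (anyDuplicated(x$gene_id)) abort("duplicate gene_id in expression matrix")
  if (anyDuplicated(names(x))) abort("stage labels must be unique")
  vals <- as.matrix(x[, -1])
  if (!is.numeric(vals)) abort("expression values must be numeric")
  if (anyNA(vals)) abort("missing expression values are not allowed")
  if (any(vals < 0)) abort("negative RPKM value in expression matrix")
  invisible(x)
}

#' Write an expression matrix to TSV
#' @param x Expression tibble from [parse_expression_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  validate_expression(x)
  readr::write_tsv(x, path)
  invisible(path)
}

expression_values <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$gene_id
  m
}

#' Read a motif-architecture table
#'
#' One row per motif occurrence: `gene_id`, `motif_id`, `start` (offset of the
#' motif in the protein). The ordered motif list of a gene is its architecture.
#'
#' @param path TSV path.
#' @return Tibble sorted by (gene_id, start).
#' @export
read_motif_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    motif_id = readr::col_character(),
    start = readr::col_integer()
  ))
  dup <- duplicated(x[, c("gene_id", "start")])
  if (any(dup)) abort("motif offsets must be unique within a gene")
  arrange(x, .data$gene_id, .data$start)
}

#' Read a qPCR Ct table
#'
#' Expected columns: `sample_id`, `condition`, `timepoint`, `gene_id`,
#' `ct_target`, `ct_reference`, `replicate`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_qpcr_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    condition = readr::col_character(),
    timepoint = readr::col_character(),
    gene_id = readr::col_character(),
    ct_target = readr::col_double(),
    ct_reference = readr::col_double(),
    replicate = readr::col_integer()
  ))
  if (any(!is.finite(x$ct_target)) || any(!is.finite(x$ct_reference)) ||
    any(x$ct_target <= 0) || any(x$ct_reference <= 0)) {
    abort("Ct values must be positive and finite")
  }
  x
}

#' Read a FASTA file of sequences
#' @param path FASTA path.
#' @param type `"dna"` or `"protein"`.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  setNames(as.character(set), names(set))
}

#' Write named sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
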