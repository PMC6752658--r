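#' @rdname ng86_ka_ks
#' @export
ng86_sites <- function(codon) {
  tabs <- codon_tables()
  codon <- toupper(codon)
  if (!codon %in% tabs$sense) {
    if (codon %in% tabs$stops) abort(sprintf("'%s' is a stop codon", codon))
    abort(sprintf("'%s' is not a valid codon", codon))
  }
  c(syn = tabs$syn_sites[[codon]], nonsyn = 3 - tabs$syn_sites[[codon]])
}

# Lazily built lookup tables: per-codon synonymous site counts and, for every
# ordered sense-codon pair, pathway-averaged synonymous/nonsynonymous
# difference counts. Minimal mutational pathways (permutations of the
# differing positions) are weighted equally; pathways passing through a stop
# codon are dropped, and when all are dropped the pair is marked NA so callers
# can skip the codon.
codon_tables <- function() {
  if (!is.null(the$codon_tables)) return(the$codon_tables)
  code <- Biostrings::GENETIC_CODE
  all_codons <- names(code)
  stops <- all_codons[code == "*"]
  sense <- setdiff(all_codons, stops)
  nts <- c("A", "C", "G", "T")

  neighbors <- function(codon) {
    out <- character(0)
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(codon, pos, pos))) {
        x <- codon
        substr(x, pos, pos) <- nt
        out <- c(out, x)
      }
    }
    out
  }
  syn_sites <- vapply(sense, function(cd) {
    nb <- neighbors(cd)
    sum(code[nb] == code[cd] & !(nb %in% stops)) / 3
  }, numeric(1))

  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(
      c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
      c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
    )
  )
  n <- length(sense)
  sd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_mat <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      c1 <- sense[i]
      c2 <- sense[j]
      diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      tot_s <- 0
      tot_n <- 0
      n_ok <- 0L
      for (ord in perms[[as.character(length(diffpos))]]) {
        cur <- c1
        s <- 0
        ns <- 0
        ok <- TRUE
        for (pos in diffpos[ord]) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(c2, pos, pos)
          if (nxt %in% stops) {
            ok <- FALSE
            break
          }
          if (code[[cur]] == code[[nxt]]) s <- s + 1 else ns <- ns + 1
          cur <- nxt
        }
        if (ok) {
          tot_s <- tot_s + s
          tot_n <- tot_n + ns
          n_ok <- n_ok + 1L
        }
      }
      if (n_ok == 0L) {
        sd_mat[i, j] <- NA_real_
        nd_mat[i, j] <- NA_real_
      } else {
        sd_mat[i, j] <- tot_s / n_ok
        nd_mat[i, j] <- tot_n / n_ok
      }
    }
  }
  the$codon_tables <- list(
    code = code, sense = sense, stops = stops,
    syn_sites = syn_sites, sd = sd_mat, nd = nd_mat
  )
  the$codon_tables
}

translate_cds <- function(seq) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(seq),
    no.init.codon = TRUE
  ))
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) abort("sequence length is not a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Nei-Gojobori (1986) pairwise Ka/Ks
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (fractions of
#' the three possible changes at each position that are synonymous; changes to
#' stop codons count as nonsynonymous), averages them over the two sequences,
#' counts synonymous/nonsynonymous differences (Sd, Nd) per codon pair by
#' equal-weight averaging over all minimal mutational pathways (pathways
#' through stop codons excluded), and applies the Jukes-Cantor correction
#' `d = -3/4 * log(1 - 4p/3)` to the proportions `pS = Sd/S`, `pN = Nd/N`.
#' Proportions at or above 3/4 are saturated and yield `NA`. Codon columns
#' containing a gap or ambiguity character in either sequence are skipped
#' (pairwise deletion). `ka_ks` is `ka/ks` when `ks > 0`, otherwise `NA`.
#'
#' `ng86_sites()` returns the (synonymous, nonsynonymous) site counts of a
#' single codon; their sum is always exactly 3.
#'
#' @param seq1,seq2 Aligned CDS strings of equal length over `A,C,G,T,-`.
#' @param codon Single codon (3-mer), not a stop.
#' @return For `ng86_ka_ks()`, a one-row tibble with `n_codons`, `S`, `N`,
#'   `Sd`, `Nd`, `ps`, `pn`, `ks`, `ka`, `ka_ks`, `pi`.
#' @export
#' @examples
#' ng86_sites("TTT")
#' ng86_ka_ks("ATGAAACCC", "ATGAAGCCC")
ng86_ka_ks <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) abort("aligned sequences must have equal length")
  tabs <- codon_tables()
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)
  ok <- c1 %in% tabs$sense & c2 %in% tabs$sense
  c1 <- c1[ok]
  c2 <- c2[ok]
  if (length(c1) < 1) abort("no comparable codons between the two sequences")

  sdv <- ifelse(c1 == c2, 0, tabs$sd[cbind(c1, c2)])
  ndv <- ifelse(c1 == c2, 0, tabs$nd[cbind(c1, c2)])
  blocked <- is.na(sdv)
  if (any(blocked)) {
    inform(sprintf(
      "%d codon pair(s) skipped: every minimal pathway passes a stop codon",
      sum(blocked)
    ))
    c1 <- c1[!blocked]
    c2 <- c2[!blocked]
    sdv <- sdv[!blocked]
    ndv <- ndv[!blocked]
    if (length(c1) < 1) abort("no comparable codons between the two sequences")
  }

  S <- (sum(tabs$syn_sites[c1]) + sum(tabs$syn_sites[c2])) / 2
  n_codons <- length(c1)
  N <- 3 * n_codons - S
  Sd <- sum(sdv)
  Nd <- sum(ndv)
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ks <- jc(ps)
  ka <- jc(pn)
  ka_ks <- if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_
  tibble(
    n_codons = n_codons, S = S, N = N, Sd = Sd, Nd = Nd,
    ps = ps, pn = pn, ks = ks, ka = ka, ka_ks = ka_ks,
    pi = pairwise_pi(seq1, seq2)
  )
}

#' Pairwise nucleotide divergence (Pi)
#'
#' Proportion of differing nucleotide sites among sites where neither row has
#' a gap or ambiguity character.
#'
#' @param seq1,seq2 Aligned sequences of equal length.
#' @return Proportion in `[0,1]`, or `NA` when no comparable sites exist.
#' @export
#' @examples
#' pairwise_pi("ATGAAA", "ATGAAG") # 1/6
pairwise_pi <- function(seq1, seq2) {
  if (nchar(seq1) != nchar(seq2)) abort("aligned sequences must have equal length")
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  nts <- c("A", "C", "G", "T")
  comp <- a %in% nts & b %in% nts
  if (!any(comp)) return(NA_real_)
  sum(a[comp] != b[comp]) / sum(comp)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps every amino-acid column of the protein alignment to the corresponding
#' codon of the gene's CDS; protein gaps become `---`. The translated CDS must
#' equal the ungapped protein row under the standard genetic code (a terminal
#' stop codon on the CDS is stripped); any mismatch is reported with gene and
#' position.
#'
#' @param protein_alignment Named character vector of aligned protein
#'   sequences (gaps as `-`), or a tibble with columns `gene_id`, `protein`.
#' @param cds_map Named character vector: gene_id -> unaligned CDS.
#' @return Tibble of class `"codon_alignment"` with columns `gene_id`,
#'   `cds_aligned`; all rows share one length divisible by 3, gaps occur in
#'   whole-codon units.
#' @export
#' @examples
#' backtranslate_alignment(c(g1 = "M-K"), c(g1 = "ATGAAA"))
backtranslate_alignment <- function(protein_alignment, cds_map) {
  if (is.data.frame(protein_alignment)) {
    protein_alignment <- setNames(
      protein_alignment$protein, protein_alignment$gene_id
    )
  }
  ids <- names(protein_alignment)
  if (is.null(ids)) abort("protein alignment rows must be named by gene_id")
  widths <- unique(nchar(protein_alignment))
  if (length(widths) != 1) abort("protein alignment rows must have equal length")
  tabs <- codon_tables()

  rows <- vapply(ids, function(g) {
    prot <- toupper(protein_alignment[[g]])
    cds <- toupper(cds_map[[g]])
    if (is.null(cds) || is.na(cds)) abort(sprintf("no CDS provided for %s", g))
    aa <- gsub("-", "", prot, fixed = TRUE)
    if (nchar(cds) == 3 * (nchar(aa) + 1)) {
      last <- substr(cds, nchar(cds) - 2, nchar(cds))
      if (last %in% tabs$stops) cds <- substr(cds, 1, nchar(cds) - 3)
    }
    if (nchar(cds) != 3 * nchar(aa)) {
      abort(sprintf(
        "CDS length of %s (%d nt) does not match protein length (%d aa)",
        g, nchar(cds), nchar(aa)
      ))
    }
    codons <- split_codons(cds)
    if (any(codons %in% tabs$stops)) {
      abort(sprintf(
        "internal stop codon in CDS of %s at codon %d",
        g, which(codons %in% tabs$stops)[1]
      ))
    }
    trans <- unname(tabs$code[codons])
    trans[is.na(trans)] <- "X"
    aavec <- strsplit(aa, "")[[1]]
    bad <- which(trans != aavec)
    if (length(bad) > 0) {
      abort(sprintf(
        "translation mismatch for %s at protein position %d: CDS gives %s, alignment has %s",
        g, bad[1], trans[bad[1]], aavec[bad[1]]
      ))
    }
    out <- character(nchar(prot))
    k <- 0L
    pv <- strsplit(prot, "")[[1]]
    for (i in seq_along(pv)) {
      if (pv[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        out[i] <- codons[k]
      }
    }
    paste(out, collapse = "")
  }, character(1))

  structure(
    tibble(gene_id = ids, cds_aligned = unname(rows)),
    class = c("codon_alignment", class(tibble()))
  )
}

#' Pairwise divergence statistics over a set of gene pairs
#'
#' Runs [ng86_ka_ks()] (which includes [pairwise_pi()]) for each requested
#' pair of rows of a codon alignment.
#'
#' @param alignment A `"codon_alignment"` from [backtranslate_alignment()].
#' @param pairs Tibble with columns `gene1`, `gene2`.
#' @return Tibble: one row per pair with the [ng86_ka_ks()] columns.
#' @export
divergence_table <- function(alignment, pairs) {
  row_of <- setNames(alignment$cds_aligned, alignment$gene_id)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs$gene1[i]
    g2 <- pairs$gene2[i]
    if (!g1 %in% names(row_of) || !g2 %in% names(row_of)) {
      abort(sprintf("pair %s/%s not present in alignment", g1, g2))
    }
    mutate(ng86_ka_ks(row_of[[g1]], row_of[[g2]]),
      gene1 = g1, gene2 = g2, .before = 1
    )
  })
  bind_rows(out)
}
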