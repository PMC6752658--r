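# Independent oracles and fixture builders. Everything here is written from
# the definitions, not by calling the package's implementation paths.

# -- gene fixtures ----------------------------------------------------------

make_genes <- function(gene_id, chromosome, start, end,
                       is_family_member = TRUE, strand = "+",
                       exons = NULL) {
  n <- length(gene_id)
  tibble::tibble(
    gene_id = gene_id,
    chromosome = rep_len(chromosome, n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(strand, n),
    exons = if (is.null(exons)) {
      lapply(seq_len(n), function(i) {
        cbind(start = as.integer(start[i]), end = as.integer(end[i]))
      })
    } else {
      exons
    },
    is_family_member = rep_len(is_family_member, n)
  )
}

random_layout <- function(n_genes, n_chrom = 2, family_frac = 0.3,
                          span_bp = 2e6) {
  starts <- sort(sample.int(span_bp, n_genes))
  lens <- sample(300:5000, n_genes, replace = TRUE)
  make_genes(
    gene_id = sprintf("g%04d", seq_len(n_genes)),
    chromosome = sample(sprintf("chr%d", seq_len(n_chrom)), n_genes, replace = TRUE),
    start = starts, end = starts + lens,
    is_family_member = stats::runif(n_genes) < family_frac
  ) |> dplyr::arrange(chromosome, start, gene_id)
}

# -- brute-force tandem detector --------------------------------------------
# Direct transcription of the definition: test the pair rule between every
# family pair, then take connected components by repeated merging.

brute_force_repeats <- function(genes, config = analysis_config()) {
  fam <- genes[genes$is_family_member, , drop = FALSE]
  n <- nrow(fam)
  if (n < 2) return(list())
  qualifies <- function(i, j) {
    if (fam$chromosome[i] != fam$chromosome[j]) return(FALSE)
    a <- if (fam$start[i] <= fam$start[j]) i else j
    b <- if (fam$start[i] <= fam$start[j]) j else i
    gap <- if (config$distance_mode == "anchor") {
      abs(fam$start[b] - fam$start[a])
    } else {
      max(0, fam$start[b] - fam$end[a])
    }
    if (gap > config$max_pair_distance_bp) return(FALSE)
    n_between <- 0
    for (k in seq_len(nrow(genes))) {
      if (genes$chromosome[k] == fam$chromosome[a] &&
        !genes$is_family_member[k] &&
        genes$start[k] > fam$end[a] && genes$end[k] < fam$start[b]) {
        n_between <- n_between + 1
      }
    }
    n_between <= config$max_intervening
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (comp[i] != comp[j] && qualifies(i, j)) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  groups <- split(fam$gene_id, comp)
  groups <- Filter(function(g) length(g) >= 2, groups)
  unname(lapply(groups, sort))
}

repeat_membership <- function(repeats) {
  if (nrow(repeats) == 0) return(list())
  unname(lapply(split(repeats$gene_id, repeats$repeat_id), sort))
}

sort_sets <- function(sets) sets[order(vapply(sets, paste, character(1), collapse = ","))]

# -- NG86 pathway-enumeration oracle ----------------------------------------
# Recursive depth-first enumeration over orders of the differing positions;
# per-step synonymy from the genetic code; paths through stops dropped.

oracle_code <- Biostrings::GENETIC_CODE
oracle_stops <- names(oracle_code)[oracle_code == "*"]
oracle_sense <- setdiff(names(oracle_code), oracle_stops)

oracle_paths <- function(from, to) {
  f <- strsplit(from, "")[[1]]
  t <- strsplit(to, "")[[1]]
  remaining <- which(f != t)
  if (length(remaining) == 0) {
    return(list(list(syn = 0, nonsyn = 0)))
  }
  out <- list()
  for (pos in remaining) {
    nxt <- f
    nxt[pos] <- t[pos]
    nxt_codon <- paste(nxt, collapse = "")
    if (nxt_codon %in% oracle_stops) next
    step_syn <- oracle_code[[from]] == oracle_code[[nxt_codon]]
    for (rest in oracle_paths(nxt_codon, to)) {
      out[[length(out) + 1]] <- list(
        syn = rest$syn + as.integer(step_syn),
        nonsyn = rest$nonsyn + as.integer(!step_syn)
      )
    }
  }
  out
}

oracle_sd_nd <- function(c1, c2) {
  paths <- oracle_paths(c1, c2)
  if (length(paths) == 0) return(c(sd = NA_real_, nd = NA_real_))
  c(
    sd = mean(vapply(paths, function(p) p$syn, numeric(1))),
    nd = mean(vapply(paths, function(p) p$nonsyn, numeric(1)))
  )
}

oracle_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      other <- codon
      substr(other, pos, pos) <- nt
      if (!(other %in% oracle_stops) &&
        oracle_code[[other]] == oracle_code[[codon]]) {
        syn <- syn + 1
      }
    }
  }
  c(syn = syn / 3, nonsyn = 3 - syn / 3)
}

random_codon_pair <- function(n_codons, max_diff_per_codon = 2) {
  c1 <- sample(oracle_sense, n_codons, replace = TRUE)
  c2 <- vapply(c1, function(cd) {
    k <- sample(0:max_diff_per_codon, 1)
    if (k == 0) return(cd)
    pos <- sample(1:3, k)
    repeat {
      x <- cd
      for (p in pos) {
        substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"), substr(cd, p, p)), 1)
      }
      if (!(x %in% oracle_stops)) return(x)
    }
  }, character(1))
  list(seq1 = paste(c1, collapse = ""), seq2 = paste(c2, collapse = ""))
}

# -- expression fixture builder ----------------------------------------------

make_expr <- function(values, stages = NULL) {
  n <- ncol(values)
  stages <- stages %||% sprintf("s%02d", seq_len(n))
  tibble::as_tibble(cbind(
    tibble::tibble(gene_id = rownames(values)),
    stats::setNames(as.data.frame(values), stages)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- small GFF3 text fixture ------------------------------------------------

toy_gff <- function(n_genes = 10, chrom = "chr1") {
  lines <- "##gff-version 3"
  pos <- 1000
  for (i in seq_len(n_genes)) {
    id <- sprintf("gene%02d", i)
    end <- pos + 1500
    lines <- c(
      lines,
      sprintf("%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s", chrom, pos, end, id),
      sprintf(
        "%s\ttoy\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
        chrom, pos, end, id, id
      ),
      sprintf(
        "%s\ttoy\texon\t%d\t%d\t.\t+\t.\tParent=%s.t1",
        chrom, pos, pos + 600, id
      ),
      sprintf(
        "%s\ttoy\texon\t%d\t%d\t.\t+\t.\tParent=%s.t1",
        chrom, pos + 800, end, id
      )
    )
    pos <- pos + 5000
  }
  lines
}
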