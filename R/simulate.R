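#' Parameters for the two-species gene-family simulator
#'
#' The simulator emulates the inferred history of a tandem-prone
#' transcription-factor family observed in a focal genome with a single
#' outgroup: some family genes duplicated in tandem in the common ancestor
#' (ancestral tandem pairs, inherited by both species), others duplicated in
#' tandem on the focal lineage after the split (lineage-specific pairs), and a
#' few duplicated to dispersed positions. Synonymous-divergence targets are
#' NG86 Ks values; `omega` values are Ka/Ks targets.
#'
#' @param n_ancestral_genes Number of family genes in the common ancestor.
#' @param p_tandem_before_speciation Probability an ancestral gene carries a
#'   pre-speciation tandem duplicate.
#' @param p_tandem_after_speciation Probability a focal-lineage gene copy
#'   duplicates in tandem after the split.
#' @param p_dispersed_after Probability of a dispersed (non-tandem) focal
#'   duplication instead.
#' @param gene_loss_rate Probability each focal gene copy is lost.
#' @param n_chromosomes,chromosome_length_bp Genome layout of each species.
#' @param intervening_density_per_10kb Density of non-family filler genes.
#' @param codons_per_gene CDS length in codons (including the start codon).
#' @param ks_speciation Ks between orthologs of the two species.
#' @param ks_ancestral_pair Pair Ks target between members of an ancestral
#'   tandem pair; must be >= `ks_speciation`.
#' @param ks_lineage_pair Pair Ks target between members of a lineage-specific
#'   pair; must be <= `ks_speciation`.
#' @param omega_ancestral,omega_lineage Ka/Ks targets for pre-/post-split
#'   branches.
#' @param p_intron_gain Probability a descendant gene copy gains introns.
#' @param n_stages Number of expression stages (13 mirrors a full
#'   flower-plus-early-fruit developmental series).
#' @param corr_target_ancestral,corr_target_lineage Expression-correlation
#'   targets for tandem pairs of each class.
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @return A list of class `"simulation_params"`.
#' @export
simulation_params <- function(n_ancestral_genes = 30L,
                              p_tandem_before_speciation = 0.3,
                              p_tandem_after_speciation = 0.25,
                              p_dispersed_after = 0.1,
                              gene_loss_rate = 0,
                              n_chromosomes = 7L,
                              chromosome_length_bp = 3e6,
                              intervening_density_per_10kb = 1,
                              codons_per_gene = 200L,
                              ks_speciation = 0.8,
                              ks_ancestral_pair = 1.2,
                              ks_lineage_pair = 0.2,
                              omega_ancestral = 0.2,
                              omega_lineage = 0.2,
                              p_intron_gain = 0.2,
                              n_stages = 13L,
                              corr_target_ancestral = 0.5,
                              corr_target_lineage = 0.5,
                              rng_seed = 1L) {
  p <- as.list(environment())
  stopifnot(
    p$n_ancestral_genes >= 0,
    p$p_tandem_before_speciation >= 0, p$p_tandem_before_speciation <= 1,
    p$p_tandem_after_speciation >= 0, p$p_tandem_after_speciation <= 1,
    p$p_tandem_after_speciation + p$p_dispersed_after <= 1,
    p$gene_loss_rate >= 0, p$gene_loss_rate <= 1,
    p$n_chromosomes > 0, p$chromosome_length_bp > 0,
    p$codons_per_gene >= 10,
    p$ks_ancestral_pair >= p$ks_speciation,
    p$ks_lineage_pair <= p$ks_speciation,
    p$omega_ancestral >= 0, p$omega_lineage >= 0,
    p$n_stages >= 2
  )
  structure(p, class = "simulation_params")
}

#' Evolve a coding sequence to a target synonymous divergence
#'
#' Simulates a continuous-time substitution process on each codon: every
#' synonymous single-nucleotide change has rate 1, every nonsynonymous change
#' rate `omega`, and changes creating stop codons are rejected. Because each
#' codon's NG86 synonymous site count is exactly one third of its synonymous
#' single-nucleotide changes, synonymous substitutions per synonymous site
#' accrue at rate 3, so running the process for time `target_ks / 3` yields an
#' expected synonymous divergence of `target_ks` (and an expected Ka/Ks close
#' to `omega`).
#'
#' @param seq CDS string (multiple of 3, no internal stop codons).
#' @param target_ks Expected synonymous substitutions per synonymous site.
#' @param omega Relative fixation probability of nonsynonymous changes (>= 0).
#' @param seed Optional integer seed applied locally (the caller's RNG state
#'   is restored on exit).
#' @return The evolved CDS string.
#' @export
#' @examples
#' evolve_codon_sequence("ATGAAACCC", target_ks = 0, omega = 0.2)
evolve_codon_sequence <- function(seq, target_ks, omega, seed = NULL) {
  if (omega < 0) abort("omega must be >= 0")
  if (target_ks < 0) abort("target_ks must be >= 0")
  tabs <- codon_tables()
  codons <- split_codons(seq)
  if (any(codons %in% tabs$stops)) abort("internal stop codon in input CDS")
  if (!all(codons %in% tabs$sense)) abort("input CDS contains non-ACGT characters")
  if (target_ks == 0) return(seq)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  t_total <- target_ks / 3
  nb <- codon_neighbors()
  for (i in seq_along(codons)) {
    cur <- codons[i]
    t <- 0
    repeat {
      nbi <- nb[[cur]]
      rates <- ifelse(nbi$syn, 1, omega)
      total <- sum(rates)
      if (total <= 0) break
      t <- t + rexp(1, total)
      if (t >= t_total) break
      cur <- nbi$to[sample.int(length(rates), 1, prob = rates)]
    }
    codons[i] <- cur
  }
  paste(codons, collapse = "")
}

# per-codon list of non-stop single-nucleotide neighbours with synonymy flags
codon_neighbors <- function() {
  if (!is.null(the$codon_neighbors)) return(the$codon_neighbors)
  tabs <- codon_tables()
  nts <- c("A", "C", "G", "T")
  out <- lapply(tabs$sense, function(cd) {
    to <- character(0)
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(cd, pos, pos))) {
        x <- cd
        substr(x, pos, pos) <- nt
        if (!x %in% tabs$stops) to <- c(to, x)
      }
    }
    list(to = to, syn = tabs$code[to] == tabs$code[cd])
  })
  the$codon_neighbors <- setNames(out, tabs$sense)
  the$codon_neighbors
}

#' Simulate a pair of expression profiles at a target correlation
#'
#' On the log scale the second profile mixes the first profile's deviations
#' with independent noise of equal variance, weighted so the expected Pearson
#' correlation between the two profiles is approximately `target_r`. With a
#' flat (constant) baseline the target is met exactly in expectation; a
#' stage-varying baseline adds shared signal and raises the realized
#' correlation.
#'
#' @param base_profile Positive finite numeric vector (one value per stage).
#' @param target_r Target correlation in `[0, 1]`.
#' @param sd_log Standard deviation of the log-scale deviations.
#' @param seed Optional local seed.
#' @return List with `profile1` and `profile2`.
#' @export
simulate_expression_pair <- function(base_profile, target_r, sd_log = 0.2,
                                     seed = NULL) {
  if (any(!is.finite(base_profile)) || any(base_profile <= 0)) {
    abort("base profile must be positive and finite")
  }
  if (target_r < 0 || target_r > 1) abort("target_r must be in [0, 1]")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  n <- length(base_profile)
  z1 <- rnorm(n)
  z2 <- target_r * z1 + sqrt(1 - target_r^2) * rnorm(n)
  list(
    profile1 = base_profile * exp(sd_log * z1),
    profile2 = base_profile * exp(sd_log * z2)
  )
}

random_cds <- function(n_codons, sense, stops) {
  body <- sample(setdiff(sense, "ATG"), n_codons - 1, replace = TRUE)
  paste(c("ATG", body), collapse = "")
}

#' Simulate a two-species gene family with known duplication history
#'
#' Generates gene models for the focal and outgroup genomes, coding and
#' protein sequences, the true gene tree, an expression matrix, motif
#' architectures, and a ground-truth record of every planted event, so each
#' pipeline stage can be validated against a known answer. Ancestral tandem
#' duplicates sit adjacently in both genomes; lineage-specific ones duplicate
#' adjacently on the focal lineage only; dispersed duplicates go to distant
#' positions; non-family filler genes are scattered at the requested density.
#' Family loci are spaced at least 300 kb apart so unrelated loci can never be
#' chained into one repeat. Output is deterministic given `rng_seed`.
#'
#' @param params A [simulation_params()] object.
#' @return A list: `genes_focal`, `genes_outgroup` (gene tibbles), `cds`,
#'   `proteins` (named vectors over both species), `newick`, `species_map`,
#'   `tree` (parsed `gene_tree`), `expression`, `motifs`, `truth`, `params`.
#' @export
simulate_family <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  if (params$n_ancestral_genes < 1) {
    abort("parameter combination yields zero family genes")
  }
  set.seed(params$rng_seed)
  tabs <- codon_tables()

  loci <- lapply(seq_len(params$n_ancestral_genes), function(i) {
    root_cds <- random_cds(params$codons_per_gene, tabs$sense, tabs$stops)
    anc_pair <- runif(1) < params$p_tandem_before_speciation
    list(idx = i, root_cds = root_cds, anc_pair = anc_pair)
  })

  ks_sp <- params$ks_speciation
  ks_anc <- params$ks_ancestral_pair
  ks_ls <- params$ks_lineage_pair

  # one ancestral copy -> focal/outgroup descendants (with optional
  # post-speciation duplication on the focal branch)
  evolve_copy <- function(copy_cds, id_base, omega_post) {
    out_cds <- evolve_codon_sequence(copy_cds, ks_sp / 2, params$omega_ancestral)
    u <- runif(1)
    kind <- if (u < params$p_tandem_after_speciation) {
      "tandem"
    } else if (u < params$p_tandem_after_speciation + params$p_dispersed_after) {
      "dispersed"
    } else {
      "single"
    }
    if (kind == "single") {
      f_cds <- evolve_codon_sequence(copy_cds, ks_sp / 2, omega_post)
      focal <- tibble(
        gene_id = paste0("F", id_base), cds = f_cds,
        dup_kind = "single", dup_partner = NA_character_
      )
      sub <- sprintf("F%s:%.4f", id_base, ks_sp / 2)
    } else {
      pre <- evolve_codon_sequence(
        copy_cds, (ks_sp - ks_ls) / 2, omega_post
      )
      c1 <- evolve_codon_sequence(pre, ks_ls / 2, params$omega_lineage)
      c2 <- evolve_codon_sequence(pre, ks_ls / 2, params$omega_lineage)
      ids <- paste0("F", id_base, c("x", "y"))
      focal <- tibble(
        gene_id = ids, cds = c(c1, c2),
        dup_kind = kind, dup_partner = rev(ids)
      )
      sub <- sprintf(
        "(%s:%.4f,%s:%.4f):%.4f",
        ids[1], ks_ls / 2, ids[2], ks_ls / 2, (ks_sp - ks_ls) / 2
      )
    }
    list(
      focal = focal, out_id = paste0("O", id_base), out_cds = out_cds,
      newick = sprintf("(%s,O%s:%.4f)", sub, id_base, ks_sp / 2)
    )
  }

  locus_results <- lapply(loci, function(lc) {
    id <- sprintf("%03d", lc$idx)
    if (lc$anc_pair) {
      pre_len <- (ks_anc - ks_sp) / 2
      a <- evolve_codon_sequence(lc$root_cds, pre_len, params$omega_ancestral)
      b <- evolve_codon_sequence(lc$root_cds, pre_len, params$omega_ancestral)
      ra <- evolve_copy(a, paste0(id, "a"), params$omega_ancestral)
      rb <- evolve_copy(b, paste0(id, "b"), params$omega_ancestral)
      list(
        idx = lc$idx, anc_pair = TRUE, copies = list(ra, rb),
        newick = sprintf("(%s:%.4f,%s:%.4f)", ra$newick, pre_len, rb$newick, pre_len)
      )
    } else {
      ra <- evolve_copy(lc$root_cds, paste0(id, "a"), params$omega_ancestral)
      list(idx = lc$idx, anc_pair = FALSE, copies = list(ra), newick = ra$newick)
    }
  })

  # gene loss on the focal lineage
  for (k in seq_along(locus_results)) {
    for (c in seq_along(locus_results[[k]]$copies)) {
      f <- locus_results[[k]]$copies[[c]]$focal
      keep <- runif(nrow(f)) >= params$gene_loss_rate
      locus_results[[k]]$copies[[c]]$focal <- f[keep, ]
    }
  }

  all_focal <- bind_rows(lapply(locus_results, function(lr) {
    bind_rows(lapply(seq_along(lr$copies), function(ci) {
      mutate(lr$copies[[ci]]$focal, locus = lr$idx, copy = ci)
    }))
  }))
  if (nrow(all_focal) == 0) abort("all focal family genes were lost")

  # rebuild newick keeping only surviving focal tips (outgroup copies are
  # never lost)
  prune <- function(nwk, survivors) {
    tr <- ape::read.tree(text = paste0(nwk, ";"))
    keep <- tr$tip.label[!startsWith(tr$tip.label, "F") |
      tr$tip.label %in% survivors]
    if (length(keep) == 1) {
      return(sprintf("%s:%.4f", keep, ks_sp / 2))
    }
    drop <- setdiff(tr$tip.label, keep)
    if (length(drop) > 0) tr <- ape::drop.tip(tr, drop)
    sub <- ape::write.tree(tr)
    sub <- sub(";$", "", sub)
    sub
  }
  locus_newicks <- vapply(locus_results, function(lr) {
    prune(lr$newick, all_focal$gene_id)
  }, character(1))
  newick <- paste0(
    Reduce(function(a, b) sprintf("(%s:0.05,%s:0.05)", a, b), locus_newicks),
    ";"
  )

  # ---- genome layout ----------------------------------------------------
  locus_genes_focal <- lapply(locus_results, function(lr) {
    ids <- bind_rows(lapply(lr$copies, function(cp) cp$focal))$gene_id
    ids[order(ids)]
  })
  locus_genes_out <- lapply(locus_results, function(lr) {
    vapply(lr$copies, function(cp) cp$out_id, character(1))
  })
  # dispersed copies move to their own singleton locus
  dispersed <- all_focal$gene_id[all_focal$dup_kind == "dispersed" &
    endsWith(all_focal$gene_id, "y")]
  locus_genes_focal <- lapply(locus_genes_focal, function(g) setdiff(g, dispersed))
  locus_genes_focal <- c(locus_genes_focal, as.list(dispersed))

  layout_genome <- function(locus_list, cds_len_of, prefix) {
    locus_list <- locus_list[vapply(locus_list, length, integer(1)) > 0]
    n_loci <- length(locus_list)
    per_chrom <- ceiling(n_loci / params$n_chromosomes)
    if (50000 + per_chrom * 300000 > params$chromosome_length_bp) {
      abort("chromosomes too short for the requested number of loci")
    }
    rows <- list()
    fillers <- list()
    fid <- 0L
    for (k in seq_len(n_loci)) {
      chrom <- sprintf("%schr%d", prefix, ((k - 1) %% params$n_chromosomes) + 1)
      slot <- (k - 1) %/% params$n_chromosomes
      pos <- 50000 + slot * 300000 + floor(runif(1, 0, 40000))
      for (g in locus_list[[k]]) {
        cds_len <- cds_len_of(g)
        n_intr <- if (runif(1) < params$p_intron_gain) sample(1:3, 1) else 0L
        glen <- cds_len + n_intr * 200L
        ex <- exon_layout(pos, cds_len, n_intr)
        rows[[length(rows) + 1]] <- tibble(
          gene_id = g, chromosome = chrom,
          start = as.integer(pos), end = as.integer(pos + glen - 1),
          strand = sample(c("+", "-"), 1), exons = list(ex),
          is_family_member = TRUE
        )
        gap <- floor(runif(1, 200, 20000))
        n_fill <- sample(0:3, 1)
        n_fill <- min(n_fill, max(0, floor((gap - 100) / 500)))
        if (n_fill > 0) {
          at <- pos + glen + floor(seq(100, gap - 400, length.out = n_fill))
          for (a in at) {
            fid <- fid + 1L
            fillers[[length(fillers) + 1]] <- tibble(
              gene_id = sprintf("%sfill%05d", prefix, fid),
              chromosome = chrom, start = as.integer(a),
              end = as.integer(a + 300), strand = "+",
              exons = list(cbind(start = as.integer(a), end = as.integer(a + 300))),
              is_family_member = FALSE
            )
          }
        }
        pos <- pos + glen + gap
      }
    }
    genes <- bind_rows(rows)
    # genome-wide fillers outside family loci
    spans <- genes |>
      group_by(.data$chromosome) |>
      summarise(lo = min(.data$start) - 1000, hi = max(.data$end) + 1000)
    n_global <- stats::rpois(
      1,
      params$intervening_density_per_10kb *
        params$n_chromosomes * params$chromosome_length_bp / 10000
    )
    if (n_global > 0) {
      gchrom <- sprintf(
        "%schr%d", prefix, sample.int(params$n_chromosomes, n_global, replace = TRUE)
      )
      gpos <- floor(runif(n_global, 1, params$chromosome_length_bp - 400))
      ok <- rep(TRUE, n_global)
      for (i in seq_len(nrow(spans))) {
        ok <- ok & !(gchrom == spans$chromosome[i] &
          gpos + 300 >= spans$lo[i] & gpos <= spans$hi[i])
      }
      if (any(ok)) {
        idx <- which(ok)
        fillers[[length(fillers) + 1]] <- tibble(
          gene_id = sprintf("%sbg%06d", prefix, seq_along(idx)),
          chromosome = gchrom[idx], start = as.integer(gpos[idx]),
          end = as.integer(gpos[idx] + 300), strand = "+",
          exons = lapply(idx, function(i) {
            cbind(start = as.integer(gpos[i]), end = as.integer(gpos[i] + 300))
          }),
          is_family_member = FALSE
        )
      }
    }
    arrange(
      bind_rows(genes, bind_rows(fillers)),
      .data$chromosome, .data$start, .data$gene_id
    )
  }

  cds_all <- c(
    setNames(all_focal$cds, all_focal$gene_id),
    unlist(lapply(locus_results, function(lr) {
      setNames(
        lapply(lr$copies, function(cp) cp$out_cds),
        vapply(lr$copies, function(cp) cp$out_id, character(1))
      )
    }))
  )
  cds_len_of <- function(g) nchar(cds_all[[g]])
  genes_focal <- layout_genome(locus_genes_focal, cds_len_of, "F")
  genes_outgroup <- layout_genome(locus_genes_out, cds_len_of, "O")

  proteins <- vapply(cds_all, translate_cds, character(1))

  species_map <- tibble(
    gene_id = c(
      all_focal$gene_id,
      unlist(locus_genes_out, use.names = FALSE)
    ),
    species = c(
      rep("focal", nrow(all_focal)),
      rep("outgroup", length(unlist(locus_genes_out)))
    )
  )
  tree <- parse_gene_tree(newick, species_map)

  # ---- expression -------------------------------------------------------
  # correlated pairs are generated against a flat per-locus baseline so the
  # realized correlation tracks the class target; remaining genes get
  # independent profiles
  stages <- sprintf("stage%02d", seq_len(params$n_stages))
  focal_ids <- all_focal$gene_id
  expr_rows <- list()
  pair_targets <- list()
  assign_pair <- function(g1, g2, target) {
    base <- rep(exp(rnorm(1, log(8), 1.2)), params$n_stages)
    pr <- simulate_expression_pair(base, target)
    expr_rows[[g1]] <<- pr$profile1
    expr_rows[[g2]] <<- pr$profile2
    pair_targets[[length(pair_targets) + 1]] <<- tibble(
      gene1 = g1, gene2 = g2, target_r = target
    )
  }
  # lineage-specific cherries with both members surviving
  for (i in seq_len(nrow(all_focal))) {
    g <- all_focal$gene_id[i]
    p <- all_focal$dup_partner[i]
    if (all_focal$dup_kind[i] == "tandem" && !is.na(p) && g < p &&
      p %in% focal_ids) {
      assign_pair(g, p, params$corr_target_lineage)
    }
  }
  # ancestral pairs: correlate surviving lead copies not already assigned
  for (lr in locus_results) {
    if (!lr$anc_pair) next
    ga <- setdiff(lr$copies[[1]]$focal$gene_id, names(expr_rows))
    gb <- setdiff(lr$copies[[2]]$focal$gene_id, names(expr_rows))
    if (length(ga) > 0 && length(gb) > 0) {
      assign_pair(ga[1], gb[1], params$corr_target_ancestral)
    }
  }
  for (g in setdiff(focal_ids, names(expr_rows))) {
    base <- exp(rnorm(1, log(8), 1.2))
    expr_rows[[g]] <- base * exp(0.2 * rnorm(params$n_stages))
  }
  expr_rows <- expr_rows[focal_ids]
  expression <- bind_rows(lapply(focal_ids, function(g) {
    as_tibble(setNames(
      c(list(g), as.list(unname(expr_rows[[g]]))), c("gene_id", stages)
    ))
  }))

  # ---- motifs -----------------------------------------------------------
  motif_universe <- sprintf("m%d", 1:15)
  locus_root_sets <- lapply(seq_len(params$n_ancestral_genes), function(i) {
    c("m1", "m2", "m3", "m4", sample(motif_universe[5:15], sample(2:4, 1)))
  })
  motifs <- bind_rows(lapply(seq_len(nrow(all_focal)), function(i) {
    g <- all_focal$gene_id[i]
    lr <- locus_results[[all_focal$locus[i]]]
    rate <- if (lr$anc_pair) 1.5 else 0.5
    k <- stats::rpois(1, rate)
    arch <- locus_root_sets[[all_focal$locus[i]]]
    for (j in seq_len(k)) {
      if (runif(1) < 0.5 && length(arch) > 3) {
        arch <- arch[-sample.int(length(arch), 1)]
      } else {
        arch <- c(arch, sample(motif_universe, 1))
      }
    }
    tibble(
      gene_id = g, motif_id = arch,
      start = as.integer(seq(1, by = 25, length.out = length(arch)))
    )
  }))

  truth <- build_truth(locus_results, locus_genes_focal, all_focal, params)
  truth$pair_targets <- bind_rows(pair_targets)

  list(
    genes_focal = genes_focal, genes_outgroup = genes_outgroup,
    cds = cds_all, proteins = proteins, newick = newick,
    species_map = species_map, tree = tree, expression = expression,
    motifs = motifs, truth = truth, params = params
  )
}

exon_layout <- function(pos, cds_len, n_introns) {
  if (n_introns == 0) {
    return(cbind(start = as.integer(pos), end = as.integer(pos + cds_len - 1)))
  }
  cuts <- floor(seq(0, cds_len, length.out = n_introns + 2))
  sizes <- diff(cuts)
  starts <- integer(n_introns + 1)
  ends <- integer(n_introns + 1)
  at <- pos
  for (i in seq_len(n_introns + 1)) {
    starts[i] <- at
    ends[i] <- at + sizes[i] - 1
    at <- at + sizes[i] + 200 # 200 bp introns
  }
  cbind(start = as.integer(starts), end = as.integer(ends))
}

# ground-truth labels implied by the planted events, mirroring the definitions
# the classifier is supposed to recover
build_truth <- function(locus_results, locus_genes_focal, all_focal, params) {
  cherry_of <- setNames(rep(NA_character_, nrow(all_focal)), all_focal$gene_id)
  for (i in seq_len(nrow(all_focal))) {
    g <- all_focal$gene_id[i]
    p <- all_focal$dup_partner[i]
    if (all_focal$dup_kind[i] != "single" && !is.na(p) &&
      p %in% all_focal$gene_id) {
      cherry_of[g] <- paste(sort(c(g, p)), collapse = "|")
    }
  }
  gene_type <- ifelse(is.na(cherry_of), "II", "I")

  tandem_class <- setNames(rep("none", nrow(all_focal)), all_focal$gene_id)
  arrays <- list()
  for (k in seq_along(locus_genes_focal)) {
    members <- locus_genes_focal[[k]]
    members <- intersect(members, all_focal$gene_id)
    if (length(members) >= 2) arrays[[length(arrays) + 1]] <- members
    if (length(members) < 2) next
    for (g in members) {
      partners <- setdiff(members, g)
      same_cherry <- !is.na(cherry_of[g]) &
        vapply(partners, function(h) {
          identical(unname(cherry_of[h]), unname(cherry_of[g]))
        }, logical(1))
      ls <- any(same_cherry)
      anc <- is.na(cherry_of[g]) || any(!same_cherry)
      tandem_class[g] <- if (ls && anc) {
        "both"
      } else if (ls) {
        "lineage_specific"
      } else {
        "ancestral"
      }
    }
  }
  pair_ks <- bind_rows(lapply(seq_len(nrow(all_focal)), function(i) {
    g <- all_focal$gene_id[i]
    p <- all_focal$dup_partner[i]
    if (is.na(p) || !p %in% all_focal$gene_id || g > p) {
      return(NULL)
    }
    tibble(
      gene1 = g, gene2 = p,
      true_ks = params$ks_lineage_pair,
      true_omega = params$omega_lineage,
      pair_class = "lineage_specific"
    )
  }))
  list(
    labels = tibble(
      gene_id = all_focal$gene_id,
      gene_type = unname(gene_type),
      tandem_class = unname(tandem_class[all_focal$gene_id])
    ),
    arrays = arrays,
    pair_ks = pair_ks
  )
}
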