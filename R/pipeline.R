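#' Direct tandem pairs within detected repeats
#'
#' Enumerates the gene pairs inside each repeat that satisfy the pair rule
#' directly (not merely through chaining) and, when clusters are supplied,
#' assigns each pair a duplicate class: `lineage_specific` when the two genes
#' share a focal cluster, `ancestral` otherwise.
#'
#' @param repeats Output of [detect_tandem_repeats()].
#' @param genes Gene tibble.
#' @param config [analysis_config()].
#' @param clusters Optional output of [find_focal_clusters()].
#' @return Tibble: `repeat_id`, `gene1`, `gene2`, and `pair_class` when
#'   clusters are given.
#' @export
tandem_pairs <- function(repeats, genes, config = analysis_config(),
                         clusters = NULL) {
  out <- list()
  for (rid in unique(repeats$repeat_id)) {
    members <- repeats$gene_id[repeats$repeat_id == rid]
    if (length(members) < 2) next
    cmb <- utils::combn(members, 2)
    for (k in seq_len(ncol(cmb))) {
      if (is_tandem_pair(genes, cmb[1, k], cmb[2, k], config)) {
        out[[length(out) + 1]] <- tibble(
          repeat_id = rid, gene1 = cmb[1, k], gene2 = cmb[2, k]
        )
      }
    }
  }
  pairs <- bind_rows(out)
  if (nrow(pairs) == 0) {
    pairs <- tibble(
      repeat_id = character(), gene1 = character(), gene2 = character()
    )
  }
  if (!is.null(clusters) && nrow(pairs) > 0) {
    cl <- setNames(clusters$cluster_id, clusters$gene_id)
    pairs$pair_class <- ifelse(
      !is.na(cl[pairs$gene1]) & !is.na(cl[pairs$gene2]) &
        cl[pairs$gene1] == cl[pairs$gene2],
      "lineage_specific", "ancestral"
    )
  }
  pairs
}

pipeline_inputs <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  required <- c("gff_focal", "family_ids", "tree", "species_map", "expression")
  missing <- required[!required %in% names(config)]
  if (length(missing) > 0) {
    abort(sprintf(
      "missing required pipeline inputs: %s",
      paste(missing, collapse = ", ")
    ))
  }
  config
}

read_or_pass <- function(x, reader) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) reader(x) else x
}

#' Run the full divergence pipeline
#'
#' Executes the stages in dependency order — tandem detection, duplicate
#' classification, sequence/structural/expression divergence, class summary —
#' and returns a consolidated report plus a run manifest. Inputs are given as
#' a config list (or YAML file path) whose entries may be file paths or
#' in-memory objects: `gff_focal`, `family_ids`, `tree`, `species_map`,
#' `expression` (required); `gff_outgroup`, `motifs`, `protein_alignment`,
#' `cds`, `qpcr`, `control_condition`, `analysis` (threshold overrides)
#' (optional). Re-running with identical inputs reproduces identical outputs.
#'
#' @param config Config list or path to a YAML config file.
#' @return A list of class `"tandemdiv_report"`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_inputs(config)
  cfg <- as_analysis_config(config$analysis)
  manifest <- list(
    config = config[!vapply(config, is.object, logical(1))],
    version = as.character(utils::packageVersion("tandemdiv")),
    rng_seed = cfg$rng_seed,
    checksums = input_checksums(config),
    stages = list()
  )
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  family_ids <- config$family_ids
  if (is.character(family_ids) && length(family_ids) == 1 &&
    file.exists(family_ids)) {
    family_ids <- readLines(family_ids, warn = FALSE)
  }
  ingest <- stage("ingest", {
    genes <- read_or_pass(config$gff_focal, function(p) {
      parse_gff_genes(p, family_ids)
    })
    species_map <- read_or_pass(config$species_map, read_species_map)
    tree <- if (inherits(config$tree, "gene_tree")) {
      config$tree
    } else {
      parse_gene_tree(config$tree, species_map)
    }
    expr <- read_or_pass(config$expression, parse_expression_table)
    list(
      genes = genes, tree = tree, expr = expr,
      genes_out = if (!is.null(config$gff_outgroup)) {
        read_or_pass(config$gff_outgroup, function(p) {
          parse_gff_genes(p, species_map$gene_id)
        })
      },
      motifs = if (!is.null(config$motifs)) {
        read_or_pass(config$motifs, read_motif_table)
      },
      cds = if (!is.null(config$cds)) {
        read_or_pass(config$cds, read_fasta_seqs)
      },
      protein_alignment = if (!is.null(config$protein_alignment)) {
        read_or_pass(config$protein_alignment, function(p) {
          read_fasta_seqs(p, type = "protein")
        })
      },
      qpcr = if (!is.null(config$qpcr)) {
        read_or_pass(config$qpcr, read_qpcr_table)
      }
    )
  })

  repeats <- stage("detect", detect_tandem_repeats(ingest$genes, cfg))
  classification <- stage("classify", {
    clusters <- find_focal_clusters(ingest$tree)
    types <- assign_gene_types(ingest$tree, clusters)
    pairs <- tandem_pairs(repeats, ingest$genes, cfg, clusters)
    evidence <- NULL
    if (!is.null(ingest$genes_out) && nrow(pairs) > 0) {
      omap <- build_ortholog_map(ingest$tree)
      evidence <- mutate(pairs, outgroup_tandem = vapply(
        seq_len(nrow(pairs)),
        function(i) {
          suppressMessages(outgroup_tandem_evidence(
            c(pairs$gene1[i], pairs$gene2[i]), omap, ingest$genes_out, cfg
          ))
        },
        logical(1)
      ))
    }
    labels <- classify_tandem_genes(
      repeats, clusters, types, ingest$genes, cfg, evidence
    )
    list(
      clusters = clusters, types = types, labels = labels,
      pairs = pairs, evidence = evidence
    )
  })

  divergence <- stage("seqdiv", {
    pairs <- classification$pairs
    if (nrow(pairs) == 0 || is.null(ingest$cds)) {
      NULL
    } else {
      aln <- if (!is.null(ingest$protein_alignment)) {
        backtranslate_alignment(ingest$protein_alignment, ingest$cds)
      } else {
        prots <- vapply(ingest$cds, translate_cds, character(1))
        if (length(unique(nchar(prots))) != 1) {
          abort("CDS of unequal length require a protein alignment")
        }
        backtranslate_alignment(prots, ingest$cds)
      }
      left_join(
        divergence_table(aln, pairs), pairs,
        by = c("gene1", "gene2")
      )
    }
  })

  structure_div <- stage("structdiv", {
    if (nrow(classification$pairs) == 0) {
      NULL
    } else {
      left_join(
        structural_divergence_table(
          ingest$genes, classification$pairs, ingest$motifs
        ),
        classification$pairs,
        by = c("gene1", "gene2")
      )
    }
  })

  exprdiv <- stage("exprdiv", {
    calls <- call_expression(ingest$expr, cfg)
    correlations <- if (nrow(classification$pairs) > 0) {
      left_join(
        all_pair_correlations(ingest$expr, classification$pairs, cfg),
        classification$pairs,
        by = c("gene1", "gene2")
      )
    }
    qpcr <- if (!is.null(ingest$qpcr)) {
      ddct_fold_change(
        ingest$qpcr, config$control_condition %||% "control"
      )
    }
    list(calls = calls, correlations = correlations, qpcr = qpcr)
  })

  summary <- stage("summarize", {
    list(
      classes = summarize_duplicate_labels(classification$labels, repeats),
      expression = summarize_class_statistics(
        classification$labels, exprdiv$calls, exprdiv$correlations
      ),
      divergence_by_class = if (!is.null(divergence) && "pair_class" %in% names(divergence)) {
        divergence |>
          group_by(.data$pair_class) |>
          summarise(
            n_pairs = dplyr::n(),
            mean_pi = mean(.data$pi, na.rm = TRUE),
            mean_ka = mean(.data$ka, na.rm = TRUE),
            mean_ks = mean(.data$ks, na.rm = TRUE),
            mean_ka_ks = mean(.data$ka_ks, na.rm = TRUE),
            .groups = "drop"
          )
      }
    )
  })

  structure(
    list(
      manifest = manifest, config = cfg,
      genes = ingest$genes, repeats = repeats,
      clusters = classification$clusters, types = classification$types,
      labels = classification$labels, pairs = classification$pairs,
      evidence = classification$evidence,
      divergence = divergence, structure = structure_div,
      calls = exprdiv$calls, correlations = exprdiv$correlations,
      qpcr = exprdiv$qpcr, expression = ingest$expr,
      summary = summary
    ),
    class = "tandemdiv_report"
  )
}

input_checksums <- function(config) {
  paths <- Filter(
    function(x) is.character(x) && length(x) == 1 && file.exists(x),
    config
  )
  if (length(paths) == 0) return(list())
  as.list(tools::md5sum(unlist(paths)))
}

#' Render a pipeline report as text tables and machine-readable JSON
#'
#' Percentages are printed at one decimal; the JSON keeps the exact fractions
#' (numerator, denominator) alongside the rounded value.
#'
#' @param report A `"tandemdiv_report"` from [run_pipeline()].
#' @return List with `text` (character lines) and `json` (nested list, ready
#'   for [jsonlite::toJSON()]).
#' @export
render_summary <- function(report) {
  cs <- report$summary$classes
  es <- report$summary$expression
  text <- c(
    sprintf(
      "family genes: %d; tandem: %d (%s) in %d repeats (mean size %.2f)",
      cs$n_focal_genes, cs$n_tandem_genes,
      format_percent(cs$n_tandem_genes, cs$n_focal_genes),
      cs$n_repeats, cs$mean_repeat_size
    ),
    sprintf(
      "type I: %d in %d clusters (%s of family); type II: %d",
      cs$n_type_I, cs$n_clusters,
      format_percent(cs$n_type_I, cs$n_focal_genes), cs$n_type_II
    ),
    sprintf(
      "lineage-specific: %d; ancestral: %d; both: %d (inclusion-exclusion: %d)",
      cs$n_lineage_specific, cs$n_ancestral, cs$n_both,
      cs$n_lineage_specific + cs$n_ancestral - cs$n_both
    ),
    vapply(seq_len(nrow(es$groups)), function(i) {
      sprintf(
        "low expression [%s]: %d/%d (%s)",
        es$groups$group[i], es$groups$n_low[i], es$groups$n[i],
        format_percent(es$groups$n_low[i], es$groups$n[i])
      )
    }, character(1)),
    sprintf(
      "low-expression fold (tandem/clustered vs other): %s",
      ifelse(is.na(es$fold_low_expression), "NA", format(es$fold_low_expression))
    )
  )
  json <- list(
    n_family_genes = cs$n_focal_genes,
    tandem = list(
      n = cs$n_tandem_genes, of = cs$n_focal_genes,
      pct = percent(cs$n_tandem_genes, cs$n_focal_genes)
    ),
    type_I = list(
      n = cs$n_type_I, clusters = cs$n_clusters,
      pct = percent(cs$n_type_I, cs$n_focal_genes)
    ),
    classes = list(
      lineage_specific = cs$n_lineage_specific,
      ancestral = cs$n_ancestral, both = cs$n_both
    ),
    repeats = list(n = cs$n_repeats, mean_size = cs$mean_repeat_size),
    low_expression = lapply(seq_len(nrow(es$groups)), function(i) {
      list(
        group = es$groups$group[i],
        n = es$groups$n_low[i], of = es$groups$n[i],
        pct = percent(es$groups$n_low[i], es$groups$n[i])
      )
    }),
    fold_low_expression = es$fold_low_expression
  )
  if (!is.null(report$summary$divergence_by_class)) {
    d <- report$summary$divergence_by_class
    text <- c(text, vapply(seq_len(nrow(d)), function(i) {
      sprintf(
        "divergence [%s]: n=%d, Pi=%.4f, Ka=%.4f, Ks=%.4f, Ka/Ks=%.3f",
        d$pair_class[i], d$n_pairs[i], d$mean_pi[i], d$mean_ka[i],
        d$mean_ks[i], d$mean_ka_ks[i]
      )
    }, character(1)))
    json$divergence_by_class <- d
  }
  if (!is.null(es$correlated_fraction)) {
    cf <- es$correlated_fraction
    text <- c(text, vapply(seq_len(nrow(cf)), function(i) {
      sprintf(
        "correlated pairs [%s]: %d/%d (%s)",
        cf$pair_class[i], cf$n_correlated[i], cf$n_pairs[i],
        format_percent(cf$n_correlated[i], cf$n_pairs[i])
      )
    }, character(1)))
    json$correlated_pairs <- cf
  }
  list(text = text, json = json)
}

#' @export
print.tandemdiv_report <- function(x, ...) {
  cat("<tandemdiv_report>\n")
  cat(paste0("  ", render_summary(x)$text, "\n"), sep = "")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `"tandemdiv_report"`.
#' @param ... Unused.
#' @method tidy tandemdiv_report
#' @export
tidy.tandemdiv_report <- function(x, ...) {
  out <- left_join(x$labels, as_tibble(x$calls), by = "gene_id")
  out$evidence <- vapply(out$evidence, paste, character(1), collapse = ";")
  out
}

#' @rdname run_pipeline
#' @method glance tandemdiv_report
#' @export
glance.tandemdiv_report <- function(x, ...) {
  cs <- x$summary$classes
  tibble(
    n_family_genes = cs$n_focal_genes,
    n_tandem = cs$n_tandem_genes,
    pct_tandem = percent(cs$n_tandem_genes, cs$n_focal_genes),
    n_repeats = cs$n_repeats,
    mean_repeat_size = cs$mean_repeat_size,
    n_type_I = cs$n_type_I,
    n_clusters = cs$n_clusters,
    n_lineage_specific = cs$n_lineage_specific,
    n_ancestral = cs$n_ancestral,
    n_both = cs$n_both
  )
}
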