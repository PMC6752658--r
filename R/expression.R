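#' Call expression status of genes from an RPKM matrix
#'
#' A gene is *detected* in a stage when its RPKM is at or above
#' `detection_threshold` (values lower than the threshold count as not
#' expressed); *expressed* when detected in at least `min_expressed_stages`
#' stages; *lowly expressed* when its RPKM stays below `low_expr_threshold` in
#' at least `ceiling(low_expr_fraction * n_stages)` stages.
#'
#' @param expr Expression tibble ([parse_expression_table()]): `gene_id`
#'   column plus one numeric column per stage.
#' @param config [analysis_config()].
#' @return Tibble of class `"expression_calls"`: `gene_id`, `n_detected`,
#'   `expressed`, `low_expression`, plus a `detected` attribute holding the
#'   per-stage logical detection matrix.
#' @export
#' @examples
#' expr <- tibble::tibble(
#'   gene_id = c("g1", "g2"),
#'   s1 = c(0.5, 0.1), s2 = c(0.6, 0.1), s3 = c(0, 0.1)
#' )
#' call_expression(expr)
call_expression <- function(expr, config = analysis_config()) {
  config <- as_analysis_config(config)
  validate_expression(expr)
  vals <- expression_values(expr)
  if (nrow(vals) == 0 || ncol(vals) == 0) abort("empty expression matrix")
  detected <- vals >= config$detection_threshold
  n_low_needed <- ceiling(config$low_expr_fraction * ncol(vals))
  out <- tibble(
    gene_id = expr$gene_id,
    n_detected = as.integer(rowSums(detected)),
    expressed = rowSums(detected) >= config$min_expressed_stages,
    low_expression = rowSums(vals < config$low_expr_threshold) >= n_low_needed
  )
  attr(out, "detected") <- detected
  class(out) <- c("expression_calls", class(tibble()))
  out
}

#' Expression correlation of a duplicate gene pair
#'
#' Correlation is computed over the stages in which *both* genes are detected
#' (RPKM at or above the detection threshold); undetected values carry no
#' signal and are excluded. When fewer than `min_shared_stages` stages remain
#' the correlation is undefined (`NA`) and the pair is not flagged as
#' correlated. The correlated flag requires `r > corr_threshold` strictly.
#'
#' @param expr Expression tibble.
#' @param gene1,gene2 gene_ids of the pair.
#' @param config [analysis_config()].
#' @return One-row tibble: `gene1`, `gene2`, `shared_stages`, `r`,
#'   `correlated`.
#' @export
pair_correlation <- function(expr, gene1, gene2, config = analysis_config()) {
  config <- as_analysis_config(config)
  vals <- expression_values(expr)
  for (g in c(gene1, gene2)) {
    if (!g %in% rownames(vals)) abort(sprintf("gene '%s' not in expression matrix", g))
  }
  v1 <- vals[gene1, ]
  v2 <- vals[gene2, ]
  shared <- v1 >= config$detection_threshold & v2 >= config$detection_threshold
  n_shared <- sum(shared)
  if (n_shared < config$min_shared_stages) {
    r <- NA_real_
  } else {
    r <- suppressWarnings(
      cor(v1[shared], v2[shared], method = config$cor_method)
    )
  }
  tibble(
    gene1 = gene1, gene2 = gene2, shared_stages = as.integer(n_shared),
    r = r, correlated = !is.na(r) && r > config$corr_threshold
  )
}

#' @rdname pair_correlation
#' @param pairs Tibble `gene1`, `gene2`.
#' @return `all_pair_correlations()`: one row per pair.
#' @export
all_pair_correlations <- function(expr, pairs, config = analysis_config()) {
  bind_rows(lapply(
    seq_len(nrow(pairs)),
    function(i) pair_correlation(expr, pairs$gene1[i], pairs$gene2[i], config)
  ))
}

#' Two-group comparison (Welch t-test)
#'
#' Two-sided Welch t-test between two groups of values. When both groups have
#' zero variance and equal means the statistic is degenerate: the function
#' returns `p = 1` with a warning rather than failing.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @return One-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' group_comparison(c(1, 2, 3), c(11, 12, 13))
group_comparison <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs at least 2 values")
  }
  va <- stats::var(values_a)
  vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    if (mean(values_a) == mean(values_b)) {
      warn("both groups are constant and equal; p = 1")
      return(tibble(
        t = 0, df = NA_real_, p_value = 1,
        mean_a = mean(values_a), mean_b = mean(values_b)
      ))
    }
    warn("both groups are constant with different means; p = 0")
    return(tibble(
      t = Inf, df = NA_real_, p_value = 0,
      mean_a = mean(values_a), mean_b = mean(values_b)
    ))
  }
  tt <- t.test(values_a, values_b, var.equal = FALSE)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, mean_a = mean(values_a), mean_b = mean(values_b)
  )
}

#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; per gene and condition,
#' `ddCt = mean dCt(condition) - mean dCt(control)` and the fold change is
#' `2^(-ddCt)`. Significance against the control condition is assessed with
#' [group_comparison()] on the replicate-level dCt values.
#'
#' @param records qPCR tibble ([read_qpcr_table()]).
#' @param control_condition Name of the control/calibrator condition.
#' @return Tibble: `gene_id`, `condition`, `n_replicates`, `mean_dct`,
#'   `ddct`, `fold_change`, `p_value`, `dct` (list column of replicate dCt).
#' @export
ddct_fold_change <- function(records, control_condition) {
  if (!control_condition %in% records$condition) {
    abort(sprintf("control condition '%s' absent from records", control_condition))
  }
  records <- mutate(records, dct = .data$ct_target - .data$ct_reference)
  per <- records |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(
      n_replicates = dplyr::n(),
      mean_dct = mean(.data$dct),
      dct = list(.data$dct),
      .groups = "drop"
    )
  out <- lapply(unique(per$gene_id), function(g) {
    sub <- per[per$gene_id == g, ]
    ctrl <- sub[sub$condition == control_condition, ]
    if (nrow(ctrl) == 0) {
      abort(sprintf("gene %s has no records for control '%s'", g, control_condition))
    }
    mutate(sub,
      ddct = .data$mean_dct - ctrl$mean_dct,
      fold_change = 2^(-(.data$mean_dct - ctrl$mean_dct)),
      p_value = vapply(seq_len(nrow(sub)), function(i) {
        if (sub$condition[i] == control_condition) {
          return(NA_real_)
        }
        if (length(sub$dct[[i]]) < 2 || length(ctrl$dct[[1]]) < 2) {
          return(NA_real_)
        }
        suppressWarnings(
          group_comparison(sub$dct[[i]], ctrl$dct[[1]])$p_value
        )
      }, numeric(1))
    )
  })
  bind_rows(out) |>
    select(
      "gene_id", "condition", "n_replicates", "mean_dct", "ddct",
      "fold_change", "p_value", "dct"
    )
}

#' Class-level summary of expression and duplication statistics
#'
#' Aggregates duplicate labels, expression calls and pair correlations into
#' the class-level comparison: tandem/clustered versus other genes, and
#' ancestral versus lineage-specific tandem genes. Percentages are reported to
#' one decimal together with the exact fractions; fold ratios between class
#' percentages to one decimal. Empty classes yield `NA` percentages.
#'
#' @param labels Output of [classify_tandem_genes()].
#' @param calls Output of [call_expression()].
#' @param pair_results Output of [all_pair_correlations()], optionally with a
#'   `pair_class` column naming the duplicate class of each pair.
#' @return A list of class `"expression_class_summary"` with components
#'   `groups` (tibble of per-group counts and low-expression percentages),
#'   `fold_low_expression` (tandem/clustered vs other), and
#'   `correlated_fraction` (per pair class).
#' @export
summarize_class_statistics <- function(labels, calls, pair_results = NULL) {
  x <- left_join(labels, as_tibble(calls), by = "gene_id")
  x$tandem_or_clustered <- x$tandem_class != "none" | x$gene_type == "I"
  grp <- function(mask, name) {
    n <- sum(mask)
    n_low <- sum(x$low_expression[mask], na.rm = TRUE)
    tibble(
      group = name, n = n, n_low = n_low,
      pct_low = percent(n_low, n)
    )
  }
  groups <- bind_rows(
    grp(x$tandem_or_clustered, "tandem_or_clustered"),
    grp(!x$tandem_or_clustered, "other"),
    grp(x$tandem_class %in% c("lineage_specific", "both"), "lineage_specific_tandem"),
    grp(x$tandem_class %in% c("ancestral", "both"), "ancestral_tandem")
  )
  fold <- fold_ratio(
    groups$pct_low[groups$group == "tandem_or_clustered"],
    groups$pct_low[groups$group == "other"]
  )
  corr <- NULL
  if (!is.null(pair_results) && nrow(pair_results) > 0) {
    pr <- pair_results
    if (!"pair_class" %in% names(pr)) pr$pair_class <- "all"
    corr <- pr |>
      group_by(.data$pair_class) |>
      summarise(
        n_pairs = dplyr::n(),
        n_correlated = sum(.data$correlated, na.rm = TRUE),
        fraction_correlated = mean(.data$correlated, na.rm = TRUE),
        .groups = "drop"
      )
  }
  structure(
    list(
      groups = groups, fold_low_expression = fold,
      correlated_fraction = corr
    ),
    class = "expression_class_summary"
  )
}

#' @export
print.expression_class_summary <- function(x, ...) {
  cat("Expression by duplicate class (low-expression calls)\n")
  for (i in seq_len(nrow(x$groups))) {
    cat(sprintf(
      "  %-24s %d/%d (%s)\n", x$groups$group[i],
      x$groups$n_low[i], x$groups$n[i],
      format_percent(x$groups$n_low[i], x$groups$n[i])
    ))
  }
  cat(sprintf(
    "  fold (tandem/clustered vs other): %s\n",
    ifelse(is.na(x$fold_low_expression), "NA", format(x$fold_low_expression))
  ))
  if (!is.null(x$correlated_fraction)) {
    for (i in seq_len(nrow(x$correlated_fraction))) {
      cat(sprintf(
        "  correlated pairs [%s]: %d/%d\n",
        x$correlated_fraction$pair_class[i],
        x$correlated_fraction$n_correlated[i],
        x$correlated_fraction$n_pairs[i]
      ))
    }
  }
  invisible(x)
}
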