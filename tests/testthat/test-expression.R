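test_that("expression calls follow the detection and low-expression rules", {
  vals <- rbind(
    g1 = c(0.5, 0.5, rep(0, 11)), # detected twice, all below 1
    g2 = rep(0.1, 13), # never detected
    g3 = rep(5, 13), # strongly expressed
    g4 = c(rep(2, 5), rep(0.5, 8)) # 8 of 13 low: below the 9-stage cutoff
  )
  calls <- call_expression(make_expr(vals))
  got <- setNames(
    paste(calls$expressed, calls$low_expression),
    calls$gene_id
  )
  expect_equal(unname(got["g1"]), "TRUE TRUE")
  expect_equal(unname(got["g2"]), "FALSE TRUE")
  expect_equal(unname(got["g3"]), "TRUE FALSE")
  expect_equal(unname(got["g4"]), "TRUE FALSE")
  # boundary: exactly 0.3 is detected ("lower than 0.3" is not expressed)
  b <- call_expression(make_expr(rbind(g = c(0.3, 0.3, 0))))
  expect_true(b$expressed)
  expect_error(call_expression(make_expr(matrix(0, 0, 0))), "gene_id")
})

test_that("raising an RPKM value never turns expressed into unexpressed", {
  set.seed(5)
  for (rep in 1:20) {
    vals <- matrix(stats::rexp(26, 2), 2, 13)
    rownames(vals) <- c("a", "b")
    before <- call_expression(make_expr(vals))$expressed
    i <- sample(1:2, 1)
    j <- sample(1:13, 1)
    vals[i, j] <- vals[i, j] + stats::rexp(1, 1)
    after <- call_expression(make_expr(vals))$expressed
    expect_true(all(after >= before))
  }
})

test_that("pair correlation uses shared detected stages only", {
  prof <- seq(1, 13)
  vals <- rbind(g1 = prof, g2 = prof)
  pc <- pair_correlation(make_expr(vals), "g1", "g2")
  expect_equal(pc$shared_stages, 13L)
  expect_equal(pc$r, 1)
  expect_true(pc$correlated)

  # two shared stages: below min_shared_stages, undefined
  vals2 <- rbind(
    g1 = c(1, 2, rep(0, 11)), # detected in stages 1-2 only
    g2 = seq(1, 13)
  )
  pc2 <- pair_correlation(make_expr(vals2), "g1", "g2")
  expect_true(is.na(pc2$r))
  expect_false(pc2$correlated)
  expect_error(
    pair_correlation(make_expr(vals), "g1", "zz"),
    "zz"
  )
})

test_that("values in undetected stages cannot influence the correlation", {
  set.seed(6)
  for (rep in 1:20) {
    v1 <- stats::runif(13, 0.5, 10)
    v2 <- stats::runif(13, 0.5, 10)
    mask <- sample(1:13, 4)
    v1[mask] <- 0 # undetected for gene 1
    base <- pair_correlation(make_expr(rbind(a = v1, b = v2)), "a", "b")
    v2_mod <- v2
    v2_mod[mask] <- stats::runif(4, 0, 100) # arbitrary garbage where masked
    mod <- pair_correlation(make_expr(rbind(a = v1, b = v2_mod)), "a", "b")
    expect_equal(mod$r, base$r)
    expect_equal(mod$correlated, base$correlated)
  }
})

test_that("group comparison is a two-sided Welch t-test with degenerate guards", {
  same <- group_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  apart <- group_comparison(c(1, 2, 3), c(11, 12, 13))
  expect_lt(apart$p_value, 0.01)
  expect_warning(
    const <- group_comparison(c(2, 2, 2), c(2, 2, 2)),
    "p = 1"
  )
  expect_equal(const$p_value, 1)
  expect_error(group_comparison(1, c(1, 2)), "at least 2")
  # agreement with stats::t.test on ordinary data
  set.seed(7)
  a <- rnorm(10)
  b <- rnorm(12, 0.5)
  expect_equal(
    group_comparison(a, b)$p_value,
    t.test(a, b)$p.value
  )
})

test_that("ddCt fold changes follow the closed form and hand computation", {
  rec <- tibble::tibble(
    sample_id = sprintf("s%d", 1:12),
    condition = rep(c("control", "treated"), each = 6),
    timepoint = "t1",
    gene_id = "g1",
    ct_target = c(24, 24.2, 23.8, 23, 23.1, 22.9, 22, 22.2, 21.8, 21, 21.1, 20.9),
    ct_reference = rep(18, 12),
    replicate = rep(1:6, 2)
  )
  out <- ddct_fold_change(rec, "control")
  ctrl <- out[out$condition == "control", ]
  trt <- out[out$condition == "treated", ]
  expect_equal(ctrl$fold_change, 1)
  # hand computation: mean dCt control = 5.5, treated = 3.5, ddCt = -2, fold 4
  expect_equal(ctrl$mean_dct, 5.5)
  expect_equal(trt$mean_dct, 3.5)
  expect_equal(trt$ddct, -2)
  expect_equal(trt$fold_change, 4)
  expect_lt(trt$p_value, 0.01)
  expect_error(ddct_fold_change(rec, "mock"), "mock")
})

test_that("ddCt of -1 doubles expression", {
  rec <- tibble::tibble(
    sample_id = sprintf("s%d", 1:4),
    condition = rep(c("control", "treated"), each = 2),
    timepoint = "t1", gene_id = "g",
    ct_target = c(25, 25, 24, 24),
    ct_reference = rep(20, 4),
    replicate = rep(1:2, 2)
  )
  out <- ddct_fold_change(rec, "control")
  expect_equal(out$fold_change[out$condition == "treated"], 2)
})

test_that("class summary uses the stated denominators and fold ratio", {
  labels <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    gene_type = c(rep("I", 3), rep("II", 7)),
    tandem_class = c(
      "lineage_specific", "lineage_specific", "both",
      "ancestral", "ancestral", rep("none", 5)
    ),
    evidence = replicate(10, character(0), simplify = FALSE)
  )
  vals <- matrix(5, 10, 13)
  vals[c(1, 2, 3, 10), ] <- 0.5 # low expression for 3 tandem + 1 other
  rownames(vals) <- labels$gene_id
  calls <- call_expression(make_expr(vals))
  s <- summarize_class_statistics(labels, calls)
  g <- s$groups
  expect_equal(g$n[g$group == "tandem_or_clustered"], 5)
  expect_equal(g$pct_low[g$group == "tandem_or_clustered"], 60)
  expect_equal(g$n[g$group == "other"], 5)
  expect_equal(g$pct_low[g$group == "other"], 20)
  expect_equal(s$fold_low_expression, 3)
  expect_equal(g$n[g$group == "lineage_specific_tandem"], 3)
  expect_equal(g$n[g$group == "ancestral_tandem"], 3)
})
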