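cfg <- analysis_config()

test_that("count_intervening counts only non-family genes strictly between", {
  genes <- make_genes(
    gene_id = c("f1", "n1", "n2", "n3", "m1", "f2"),
    chromosome = "chr1",
    start = c(1000, 3000, 4000, 5000, 6000, 8000),
    end = c(2000, 3200, 4200, 5200, 6200, 9000),
    is_family_member = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  expect_equal(count_intervening(genes, "f1", "f2"), 3)
  adjacent <- make_genes(
    gene_id = c("a", "b"), chromosome = "chr1",
    start = c(100, 300), end = c(200, 400)
  )
  expect_equal(count_intervening(adjacent, "a", "b"), 0)
  two_chrom <- make_genes(
    gene_id = c("a", "b"), chromosome = c("chr1", "chr2"),
    start = c(100, 300), end = c(200, 400)
  )
  expect_error(count_intervening(two_chrom, "a", "b"), "same chromosome")
})

test_that("count_intervening matches an exhaustive scan on random layouts", {
  set.seed(11)
  for (rep in 1:10) {
    genes <- random_layout(50, n_chrom = 1, span_bp = 5e5)
    fam <- genes$gene_id[genes$is_family_member]
    if (length(fam) < 2) next
    pair <- sample(fam, 2)
    g1 <- genes[genes$gene_id == pair[1], ]
    g2 <- genes[genes$gene_id == pair[2], ]
    if (g1$start > g2$start) {
      tmp <- g1
      g1 <- g2
      g2 <- tmp
    }
    naive <- 0
    for (k in seq_len(nrow(genes))) {
      if (!genes$is_family_member[k] &&
        genes$start[k] > g1$end && genes$end[k] < g2$start) {
        naive <- naive + 1
      }
    }
    expect_equal(count_intervening(genes, pair[1], pair[2]), naive)
  }
})

test_that("the pair rule respects both the distance and intervening bounds", {
  # gap 99,000 with 2 intervening: qualifies
  genes <- make_genes(
    gene_id = c("f1", "n1", "n2", "f2"),
    chromosome = "chr1",
    start = c(1000, 10000, 20000, 101000),
    end = c(2000, 10500, 20500, 102000),
    is_family_member = c(TRUE, FALSE, FALSE, TRUE)
  )
  expect_true(is_tandem_pair(genes, "f1", "f2", cfg))

  # gap 100,001: one bp beyond the limit
  far <- make_genes(
    gene_id = c("f1", "f2"), chromosome = "chr1",
    start = c(1000, 102001), end = c(2000, 103000)
  )
  expect_equal(far$start[2] - far$end[1], 100001)
  expect_false(is_tandem_pair(far, "f1", "f2", cfg))

  # 11 intervening non-family genes at 5 kb gap: fails
  mids <- seq(3000, 6000, length.out = 11)
  crowded <- make_genes(
    gene_id = c("f1", sprintf("n%02d", 1:11), "f2"),
    chromosome = "chr1",
    start = c(1000, mids, 7000),
    end = c(2000, mids + 100, 8000),
    is_family_member = c(TRUE, rep(FALSE, 11), TRUE)
  )
  expect_false(is_tandem_pair(crowded, "f1", "f2", cfg))
  # dropping one intervening gene brings it back under the bound
  expect_true(is_tandem_pair(
    crowded[crowded$gene_id != "n01", ], "f1", "f2", cfg
  ))

  expect_error(
    is_tandem_pair(crowded, "f1", "n01", cfg),
    "family members"
  )
})

test_that("strand plays no role in the pair rule", {
  genes <- make_genes(
    gene_id = c("a", "b"), chromosome = "chr1",
    start = c(1000, 5000), end = c(2000, 6000),
    strand = c("+", "-")
  )
  expect_true(is_tandem_pair(genes, "a", "b", cfg))
})

test_that("six qualifying genes in a row chain into a single repeat", {
  starts <- seq(1000, by = 15000, length.out = 6)
  genes <- make_genes(
    gene_id = sprintf("f%d", 1:6), chromosome = "chr2",
    start = starts, end = starts + 2000
  )
  rep6 <- detect_tandem_repeats(genes, cfg)
  expect_equal(length(unique(rep6$repeat_id)), 1)
  expect_equal(nrow(rep6), 6)
  expect_equal(rep6$n_members, rep(6L, 6))
})

test_that("distant family genes form no repeat", {
  genes <- make_genes(
    gene_id = c("a", "b"), chromosome = "chr1",
    start = c(1000, 501000), end = c(2000, 502000)
  )
  expect_equal(nrow(detect_tandem_repeats(genes, cfg)), 0)
})

test_that("detection equals the brute-force oracle on random layouts", {
  set.seed(42)
  for (rep in 1:50) {
    genes <- random_layout(sample(20:200, 1))
    got <- sort_sets(repeat_membership(detect_tandem_repeats(genes, cfg)))
    want <- sort_sets(brute_force_repeats(genes, cfg))
    expect_equal(got, want)
  }
})

test_that("output is invariant to input ordering and bounded by family size", {
  set.seed(7)
  genes <- random_layout(120)
  ref <- detect_tandem_repeats(genes, cfg)
  shuffled <- genes[sample.int(nrow(genes)), ]
  expect_equal(detect_tandem_repeats(shuffled, cfg), ref)
  expect_lte(nrow(ref), sum(genes$is_family_member))
})

test_that("anchor distance mode measures start-to-start", {
  cfg_anchor <- analysis_config(distance_mode = "anchor")
  genes <- make_genes(
    gene_id = c("a", "b"), chromosome = "chr1",
    start = c(1000, 99000), end = c(95000, 100000)
  )
  # inner gap is 4 kb but anchors are 98 kb apart; both within 100 kb
  expect_true(is_tandem_pair(genes, "a", "b", cfg))
  expect_true(is_tandem_pair(genes, "a", "b", cfg_anchor))
  wide <- make_genes(
    gene_id = c("a", "b"), chromosome = "chr1",
    start = c(1000, 111000), end = c(105000, 112000)
  )
  # inner gap 6 kb qualifies, anchor distance 110 kb does not
  expect_true(is_tandem_pair(wide, "a", "b", cfg))
  expect_false(is_tandem_pair(wide, "a", "b", cfg_anchor))
})
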