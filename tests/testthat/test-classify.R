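species4 <- tibble::tibble(
  gene_id = c("A1", "A2", "O1", "O2"),
  species = c("focal", "focal", "outgroup", "outgroup")
)

test_that("a focal cherry sister to outgroup tips is one cluster", {
  tr <- parse_gene_tree("((A1,A2),(O1,O2));", species4)
  cl <- find_focal_clusters(tr)
  expect_equal(length(unique(cl$cluster_id)), 1)
  expect_equal(sort(cl$gene_id), c("A1", "A2"))
  types <- assign_gene_types(tr, cl)
  expect_equal(types$gene_type[types$gene_id %in% c("A1", "A2")], c("I", "I"))
})

test_that("interleaved focal/outgroup tips yield no clusters, all type II", {
  tr <- parse_gene_tree("((A1,O1),(A2,O2));", species4)
  cl <- find_focal_clusters(tr)
  expect_equal(nrow(cl), 0)
  types <- assign_gene_types(tr, cl)
  expect_equal(types$gene_type, c("II", "II"))
})

test_that("a polytomy mixing species is not a focal cluster", {
  sm <- tibble::tibble(
    gene_id = c("A1", "A2", "O1", "O2"),
    species = c("focal", "focal", "outgroup", "outgroup")
  )
  tr <- parse_gene_tree("((A1,A2,O1),O2);", sm)
  expect_equal(nrow(find_focal_clusters(tr)), 0)
})

test_that("cluster detection needs both species and is ladderization-invariant", {
  focal_only <- tibble::tibble(
    gene_id = c("A1", "A2"), species = c("focal", "focal")
  )
  expect_error(
    find_focal_clusters(parse_gene_tree("(A1,A2);", focal_only)),
    "outgroup"
  )
  out_only <- tibble::tibble(
    gene_id = c("O1", "O2"), species = c("outgroup", "outgroup")
  )
  expect_error(
    find_focal_clusters(parse_gene_tree("(O1,O2);", out_only)),
    "focal"
  )

  sm <- tibble::tibble(
    gene_id = c("A1", "A2", "A3", "O1", "O2"),
    species = c("focal", "focal", "focal", "outgroup", "outgroup")
  )
  t1 <- parse_gene_tree("(((A1,A2),A3),(O1,O2));", sm)
  t2 <- parse_gene_tree("((O2,O1),(A3,(A2,A1)));", sm)
  c1 <- find_focal_clusters(t1)
  c2 <- find_focal_clusters(t2)
  expect_equal(c1$gene_id, c2$gene_id)
  expect_equal(c1$cluster_id, c2$cluster_id)
})

test_that("simulated post-speciation clades are recovered exactly", {
  sim <- simulate_family(simulation_params(
    n_ancestral_genes = 15, p_tandem_after_speciation = 0.4,
    gene_loss_rate = 0, rng_seed = 5
  ))
  cl <- find_focal_clusters(sim$tree)
  got <- sort(unname(vapply(
    split(cl$gene_id, cl$cluster_id),
    function(g) paste(sort(g), collapse = "|"), character(1)
  )))
  truth_cherries <- sim$truth$labels$gene_id[sim$truth$labels$gene_type == "I"]
  # cherry members share an id prefix and differ in the x/y suffix
  want <- sort(unname(vapply(
    split(truth_cherries, sub("[xy]$", "", truth_cherries)),
    function(g) paste(sort(g), collapse = "|"), character(1)
  )))
  expect_equal(got, want)
  types <- assign_gene_types(sim$tree, cl)
  cmp <- dplyr::left_join(sim$truth$labels, types, by = "gene_id")
  expect_equal(cmp$gene_type.x, cmp$gene_type.y)
})

test_that("ortholog map returns the nearest outgroup tips", {
  sm <- tibble::tibble(
    gene_id = c("A1", "A2", "O1", "O2"),
    species = c("focal", "focal", "outgroup", "outgroup")
  )
  tr <- parse_gene_tree("(((A1,A2),O1),O2);", sm)
  omap <- build_ortholog_map(tr)
  expect_equal(omap[["A1"]], "O1")
  expect_equal(omap[["A2"]], "O1")
})

test_that("outgroup tandem evidence follows the pair rule in the outgroup", {
  out_genes <- make_genes(
    gene_id = c("O1", "O2", "O3"),
    chromosome = c("oc1", "oc1", "oc2"),
    start = c(1000, 5000, 1000), end = c(2000, 6000, 2000)
  )
  omap <- list(A1 = "O1", A2 = "O2", A3 = "O3")
  expect_true(outgroup_tandem_evidence(c("A1", "A2"), omap, out_genes))
  expect_false(outgroup_tandem_evidence(c("A1", "A3"), omap, out_genes))
  expect_message(
    res <- outgroup_tandem_evidence(
      c("A1", "A2"), list(A1 = character(0), A2 = "O2"), out_genes
    ),
    "no outgroup orthologs"
  )
  expect_false(res)
})

test_that("small repeats classify by cluster membership and gene type", {
  # two genes in a repeat, both in one cluster -> lineage specific
  sm <- tibble::tibble(
    gene_id = c("g1", "g2", "O1"),
    species = c("focal", "focal", "outgroup")
  )
  tr <- parse_gene_tree("((g1,g2),O1);", sm)
  genes <- make_genes(
    gene_id = c("g1", "g2"), chromosome = "chr1",
    start = c(1000, 5000), end = c(2000, 6000)
  )
  repeats <- detect_tandem_repeats(genes)
  cl <- find_focal_clusters(tr)
  types <- assign_gene_types(tr, cl)
  lab <- classify_tandem_genes(repeats, cl, types, genes)
  expect_equal(lab$tandem_class, c("lineage_specific", "lineage_specific"))

  # both type II -> ancestral
  tr2 <- parse_gene_tree("((g1,O1),(g2,O2));", tibble::tibble(
    gene_id = c("g1", "g2", "O1", "O2"),
    species = c("focal", "focal", "outgroup", "outgroup")
  ))
  cl2 <- find_focal_clusters(tr2)
  types2 <- assign_gene_types(tr2, cl2)
  lab2 <- classify_tandem_genes(repeats, cl2, types2, genes)
  expect_equal(lab2$tandem_class, c("ancestral", "ancestral"))
})

test_that("a six-gene repeat mixes lineage-specific, both, and ancestral", {
  # five cluster genes (two cherries) plus one type II gene; the type II gene
  # is within pair range only of its nearest cluster neighbours
  sm <- tibble::tibble(
    gene_id = c(sprintf("g%d", 1:6), "O1", "O2"),
    species = c(rep("focal", 6), "outgroup", "outgroup")
  )
  tr <- parse_gene_tree(
    "((((g1,g2),(g3,(g4,g5))),(g6,O1)),O2);", sm
  )
  starts <- c(10000, 13000, 16000, 19000, 22000, 123000)
  genes <- make_genes(
    gene_id = sprintf("g%d", 1:6), chromosome = "chr2",
    start = starts, end = starts + 2000
  )
  repeats <- detect_tandem_repeats(genes)
  expect_equal(length(unique(repeats$repeat_id)), 1)
  expect_equal(nrow(repeats), 6)

  cl <- find_focal_clusters(tr)
  types <- assign_gene_types(tr, cl)
  expect_equal(types$gene_type[types$gene_id == "g6"], "II")
  lab <- classify_tandem_genes(repeats, cl, types, genes)
  got <- setNames(lab$tandem_class, lab$gene_id)
  expect_equal(unname(got[c("g1", "g2", "g3", "g4")]), rep("lineage_specific", 4))
  expect_equal(unname(got["g5"]), "both") # in range of g6, outside its cluster
  expect_equal(unname(got["g6"]), "ancestral")
})

test_that("a tandem gene missing from the tree is an error", {
  genes <- make_genes(
    gene_id = c("g1", "g2"), chromosome = "chr1",
    start = c(1000, 5000), end = c(2000, 6000)
  )
  repeats <- detect_tandem_repeats(genes)
  tr <- parse_gene_tree("((g1,gX),O1);", tibble::tibble(
    gene_id = c("g1", "gX", "O1"),
    species = c("focal", "focal", "outgroup")
  ))
  cl <- find_focal_clusters(tr)
  types <- assign_gene_types(tr, cl)
  expect_error(
    classify_tandem_genes(repeats, cl, types, genes),
    "absent from the gene tree"
  )
})

test_that("gene-level tallies obey inclusion-exclusion on simulations", {
  for (seed in c(3, 17)) {
    sim <- simulate_family(simulation_params(
      n_ancestral_genes = 20, rng_seed = seed
    ))
    repeats <- detect_tandem_repeats(sim$genes_focal)
    cl <- find_focal_clusters(sim$tree)
    types <- assign_gene_types(sim$tree, cl)
    lab <- classify_tandem_genes(repeats, cl, types, sim$genes_focal)
    s <- summarize_duplicate_labels(lab, repeats)
    expect_equal(
      s$n_lineage_specific + s$n_ancestral - s$n_both,
      s$n_tandem_genes
    )
    expect_equal(s$n_tandem_genes, sum(lab$tandem_class != "none"))
  }
})
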