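test_that("without birth, death or WGD the gene tree mirrors the species tree", {
  sp <- toy_species_tree()
  gt <- simulate_gene_tree(sp, bd_params(0, 0), seed = 1)
  expect_equal(length(gt$tip.label), 4)
  expect_setequal(sub("\\|.*", "", gt$tip.label), sp$tip.label)
  stripped <- gt
  stripped$tip.label <- sub("\\|.*", "", gt$tip.label)
  expect_true(ape::all.equal.phylo(stripped, sp, use.edge.length = TRUE))
})

test_that("forced WGDs double tips per species along the root path", {
  sp <- toy_species_tree()
  gt <- simulate_gene_tree(sp, bd_params(0, 0),
                           list(wgd_event(c("A", "B"), 1)), seed = 2)
  counts <- table(sub("\\|.*", "", gt$tip.label))
  expect_equal(as.vector(counts[c("A", "B")]), c(2L, 2L))
  expect_equal(as.vector(counts[c("C", "D")]), c(1L, 1L))
  # stacked events: one above {A,B}, one above A only -> A has 2^2 tips
  gt2 <- simulate_gene_tree(sp, bd_params(0, 0),
                            list(wgd_event(c("A", "B"), 1),
                                 wgd_event("A", 1)), seed = 2)
  counts2 <- table(sub("\\|.*", "", gt2$tip.label))
  expect_equal(as.vector(counts2[c("A", "B", "C", "D")]), c(4L, 2L, 1L, 1L))
})

test_that("pure-birth tip counts match the Yule expectation e^(lambda*T)", {
  sp1 <- read_newick("(A:100);", rooted_required = FALSE)
  counts <- simulate_gene_counts(sp1, bd_params(0.002, 0), 2000, seed = 11)
  m <- mean(counts$A)
  se <- stats::sd(counts$A) / sqrt(nrow(counts))
  expect_lt(abs(m - exp(0.002 * 100)), 3 * se)
})

test_that("generated gene trees are time-ultrametric and seed-reproducible", {
  sp <- toy_ladder_tree()
  trees <- simulate_tree_set(sp, bd_params(0.004, 0.002), n = 40,
                             require_full_coverage = TRUE, seed = 5)
  expect_length(trees, 40)
  for (tr in trees) {
    depth <- ape::node.depth.edgelength(tr)
    expect_lt(diff(range(depth[seq_along(tr$tip.label)])), 1e-9)
    expect_true(all(sp$tip.label %in% sub("\\|.*", "", tr$tip.label)))
  }
  expect_gt(attr(trees, "acceptance_rate"), 0)
  again <- simulate_tree_set(sp, bd_params(0.004, 0.002), n = 40,
                             require_full_coverage = TRUE, seed = 5)
  expect_identical(vapply(trees, write_newick, character(1)),
                   vapply(again, write_newick, character(1)))
})

test_that("five identical species-tree copies come back when rates are zero", {
  sp <- toy_species_tree()
  trees <- simulate_tree_set(sp, bd_params(0, 0), n = 5, seed = 3)
  nwk <- vapply(trees, function(t) {
    t$tip.label <- sub("\\|.*", "", t$tip.label)
    write_newick(t)
  }, character(1))
  expect_equal(length(unique(nwk)), 1L)
})

test_that("clock Ks is an exact affine function of MRCA age without noise", {
  gt <- read_newick("(A|g1:54,B|g2:54);", rooted_required = FALSE)
  kt <- assign_pairwise_ks(gt, clock_params(0.01, 0))
  expect_equal(kt$ks, 1.08)
  # zero-age MRCA
  gt0 <- read_newick("((A|g1:0,A|g2:0):10,B|g3:10);", rooted_required = FALSE)
  kt0 <- assign_pairwise_ks(gt0, clock_params(0.01, 0))
  expect_equal(min(kt0$ks), 0)
  expect_equal(sort(unique(kt0$ks)), c(0, 0.2))
})

test_that("multiplicative gamma noise keeps the clock unbiased", {
  gt <- star_gene_tree(100, 50) # 4950 pairs, all MRCA age 50
  kt <- assign_pairwise_ks(gt, clock_params(0.01, 0.2), seed = 9)
  expect_lt(abs(mean(kt$ks) - 1) / 1, 0.02)
  expect_equal(unique(kt$node_id), "n101")
})

test_that("polyploid genome simulation duplicates, fractionates and re-ranks", {
  base <- simulate_base_genome(2, 100)
  expect_identical(simulate_polyploid_genome(base, 0, seed = 1), base)

  nofrac <- simulate_polyploid_genome(
    base, 1, fractionation_params(0, 0), seed = 1)
  expect_equal(nrow(nofrac), 2 * nrow(base))
  expect_equal(length(unique(nofrac$chrom)), 4)

  tri <- simulate_polyploid_genome(
    base, 1, fractionation_params(0, 0), multiplier = 3, seed = 1)
  expect_equal(nrow(tri), 3 * nrow(base))

  big <- simulate_base_genome(5, 400)
  frac <- simulate_polyploid_genome(
    big, 1, fractionation_params(0.3, 0), seed = 4)
  survivors <- nrow(frac) - nrow(big)
  expect_lt(abs(survivors - 2000 * 0.7), 3 * sqrt(2000 * 0.3 * 0.7))
  # still a valid genome after inversions
  inv <- simulate_polyploid_genome(
    big, 1, fractionation_params(0.3, 3), seed = 4)
  expect_s3_class(validate_gene_order(inv), "tbl_df")
  expect_error(simulate_polyploid_genome(big[0, ], 1), "empty")
})

test_that("gene counts are all 1 at zero rates and grow at rate lambda - mu", {
  sp <- toy_species_tree()
  cnt0 <- simulate_gene_counts(sp, bd_params(0, 0), 20, seed = 1)
  expect_true(all(as.matrix(cnt0[, sp$tip.label]) == 1L))

  sp1 <- read_newick("(A:100);", rooted_required = FALSE)
  cnt <- simulate_gene_counts(sp1, bd_params(0.003, 0.001), 3000, seed = 2)
  m <- mean(cnt$A)
  se <- stats::sd(cnt$A) / sqrt(nrow(cnt))
  expect_lt(abs(m - exp(0.002 * 100)), 3 * se)
  expect_identical(
    cnt, simulate_gene_counts(sp1, bd_params(0.003, 0.001), 3000, seed = 2))
})
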