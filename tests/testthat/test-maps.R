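test_that("textbook LCA duplication cases map correctly", {
  ladder <- ladder_spec(c("B", "C"), "A")
  # ((B1,C1),(B2,C2)) rooted by A1: one duplication shared by B and C
  gt <- read_newick("(((B|1:1,C|1:1):1,(B|2:1,C|2:1):1):1,A|1:3);",
                    rooted_required = FALSE)
  md <- map_duplications(gt, ladder)
  expect_equal(md$subtrees, 1L)
  expect_equal(md$duplicated, 1L)
  # ((B1,B2),C1): duplication within species B only
  gt2 <- read_newick("(((B|1:1,B|2:1):1,C|1:2):1,A|1:3);",
                     rooted_required = FALSE)
  md2 <- map_duplications(gt2, ladder)
  expect_equal(md2$subtrees, 1L)
  expect_equal(md2$duplicated, 0L)
  # no outgroup tip -> unusable
  gt3 <- read_newick("(B|1:1,C|1:1);", rooted_required = FALSE)
  expect_error(map_duplications(gt3, ladder), "no outgroup")
})

test_that("a forced WGD at N2 lights up N2 and nothing else", {
  ladder <- toy_ladder()
  sp <- toy_ladder_tree()
  trees <- simulate_tree_set(sp, bd_params(0, 0),
                             list(wgd_event(c("t1", "t2", "t3"), 1)),
                             n = 30, seed = 8)
  for (tr in trees) {
    md <- map_duplications(tr, ladder)
    expect_equal(md$duplicated[md$node == "N2"], 1L)
    expect_equal(sum(md$duplicated), 1L)
  }
  mt <- maps_table(trees, ladder)
  expect_equal(mt$pct[mt$node == "N2"], 100)
  expect_equal(mt$pct[mt$node != "N2"], c(0, 0, 0))
  # the retained copy contributes a second N1 subtree
  expect_equal(mt$subtree_total[mt$node == "N1"], 60)
})

test_that("partial retention shows up as the retention percentage", {
  ladder <- toy_ladder()
  sp <- toy_ladder_tree()
  trees <- simulate_tree_set(sp, bd_params(0, 0),
                             list(wgd_event(c("t1", "t2", "t3"), 0.3)),
                             n = 500, seed = 9)
  mt <- maps_table(trees, ladder)
  pct <- mt$pct[mt$node == "N2"]
  sigma <- 100 * sqrt(0.3 * 0.7 / 500)
  expect_lt(abs(pct - 30), 3 * sigma)
})

test_that("the null run is empty at zero rates and reproducible by seed", {
  ladder <- toy_ladder()
  sp <- toy_ladder_tree()
  null0 <- run_null(sp, ladder, bd_params(0, 0), n_trees = 50, seed = 10)
  expect_equal(null0$pct, rep(0, 4))
  n1 <- run_null(sp, ladder, bd_params(0.003, 0.001), n_trees = 100, seed = 11)
  n2 <- run_null(sp, ladder, bd_params(0.003, 0.001), n_trees = 100, seed = 11)
  expect_equal(as.data.frame(n1), as.data.frame(n2))
})

test_that("null duplication percentages increase with the birth rate", {
  ladder <- toy_ladder()
  sp <- toy_ladder_tree()
  lo <- run_null(sp, ladder, bd_params(0.001, 0.001), n_trees = 1200, seed = 12)
  hi <- run_null(sp, ladder, bd_params(0.004, 0.001), n_trees = 1200, seed = 12)
  expect_gt(sum(hi$shared_dups), sum(lo$shared_dups))
  expect_gt(mean(hi$pct), mean(lo$pct))
})

test_that("positive runs dominate the null at the WGD node and warn below 20% retention", {
  ladder <- toy_ladder()
  sp <- toy_ladder_tree()
  bd <- bd_params(0.002, 0.002)
  null <- run_null(sp, ladder, bd, n_trees = 600, seed = 13)
  pos <- run_positive(sp, ladder, bd, "N2", retention = 1, n_trees = 600,
                      seed = 14)
  expect_gte(pos$pct[pos$node == "N2"], null$pct[null$node == "N2"])
  expect_warning(
    run_positive(sp, ladder, bd_params(0, 0), "N2", retention = 0.1,
                 n_trees = 5, seed = 1),
    "retention below 0.2")
  expect_error(run_positive(sp, ladder, bd, "N9", n_trees = 5, seed = 1),
               "unknown ladder node")
})

test_that("resampling collapses to zero width on a pool of exactly `size` trees", {
  ladder <- toy_ladder()
  sp <- toy_ladder_tree()
  trees <- simulate_tree_set(sp, bd_params(0.002, 0.002),
                             list(wgd_event(c("t1", "t2", "t3"), 0.3)),
                             n = 60, seed = 15)
  ci <- resample_percentages(trees, ladder, size = 60, reps = 20, seed = 1)
  expect_equal(ci$pct_lo, ci$pct_hi)
  expect_error(
    resample_percentages(trees, ladder, size = 100, reps = 10, seed = 1),
    "smaller size")
})

test_that("resampling intervals cover the full-pool percentage", {
  ladder <- toy_ladder()
  sp <- toy_ladder_tree()
  trees <- simulate_tree_set(sp, bd_params(0.002, 0.002),
                             list(wgd_event(c("t1", "t2", "t3"), 0.3)),
                             n = 600, seed = 16)
  full <- maps_table(trees, ladder)
  covered <- 0L
  for (s in 1:20) {
    ci <- resample_percentages(trees, ladder, size = 300, reps = 60, seed = s)
    if (all(ci$pct_lo <= full$pct & full$pct <= ci$pct_hi)) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered, 18L)
})

test_that("fisher_compare matches the hypergeometric tail oracle", {
  obs <- structure(
    tibble::tibble(node = "N1", subtree_total = 100L, shared_dups = 30L,
                   pct = 30),
    class = c("maps_result", "tbl_df", "tbl", "data.frame"))
  null <- structure(
    tibble::tibble(node = "N1", subtree_total = 100L, shared_dups = 10L,
                   pct = 10),
    class = c("maps_result", "tbl_df", "tbl", "data.frame"))
  got <- fisher_compare(obs, null)
  expect_equal(got$p_value, oracle_fisher_greater(30, 70, 10, 90),
               tolerance = 1e-12)
  # equal counts carry no enrichment evidence
  same <- fisher_compare(obs, obs)
  expect_gte(same$p_value, 0.5)
  # zero totals fall back to p = 1 with a warning
  zero <- structure(
    tibble::tibble(node = "N1", subtree_total = 0L, shared_dups = 0L, pct = 0),
    class = c("maps_result", "tbl_df", "tbl", "data.frame"))
  expect_warning(z <- fisher_compare(zero, null), "zero subtree total")
  expect_equal(z$p_value, 1)
})

test_that("consistency flags combine Fisher significance with the positive band", {
  fisher <- tibble::tibble(node = c("N1", "N2"), obs_pct = c(5, 35),
                           null_pct = c(5, 8), p_value = c(0.8, 1e-10),
                           significant = c(FALSE, TRUE))
  pos_ci <- tibble::tibble(node = c("N1", "N2"), pct_lo = c(20, 25),
                           pct_hi = c(30, 40))
  obs <- tibble::tibble(node = c("N1", "N2"), pct = c(5, 35))
  out <- consistent_with_positive(obs, fisher, pos_ci)
  expect_equal(out$consistent_with_positive, c(FALSE, TRUE))
})

test_that("birth-death rates are recovered from simulated gene counts", {
  sp <- toy_ladder_tree()
  cnt <- simulate_gene_counts(sp, bd_params(0.002, 0.002), 1500, seed = 17)
  est <- estimate_bd_rates(cnt, sp)
  expect_lt(abs(est$birth_rate - 0.002) / 0.002, 0.2)
  expect_lt(abs(est$death_rate - 0.002) / 0.002, 0.2)
  # likelihood ordering: the truth beats doubled rates
  expect_gt(bd_loglik(cnt, sp, 0.002, 0.002),
            bd_loglik(cnt, sp, 0.004, 0.004))
})

test_that("all-singleton counts push the birth rate to the boundary", {
  sp <- toy_species_tree()
  cnt <- simulate_gene_counts(sp, bd_params(0, 0), 200, seed = 18)
  expect_warning(est <- estimate_bd_rates(cnt, sp), "boundary")
  expect_lt(est$birth_rate, 1e-5)
})

test_that("ladder trees are strictly ladderized and correctly aged", {
  ladder <- toy_ladder()
  sp <- toy_ladder_tree()
  expect_true(is_ladder_tree(sp))
  expect_true(is_ultrametric_tree(sp))
  expect_equal(max(node_ages(sp)), 190)
  expect_false(is_ladder_tree(toy_species_tree()))
})
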