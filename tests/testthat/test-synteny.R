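mini_genome <- function(fams, chrom = "c1", prefix = "x") {
  tibble::tibble(
    chrom = chrom, rank = seq_along(fams) - 1L,
    gene_id = sprintf("%s%03d", prefix, seq_along(fams)),
    family_id = fams
  )
}

diag_anchors <- function(ra, rb = ra) {
  tibble::tibble(
    family_id = sprintf("f%03d", seq_along(ra)),
    chrom_a = "c1", rank_a = as.integer(ra),
    gene_a = sprintf("a%03d", seq_along(ra)),
    chrom_b = "c1", rank_b = as.integer(rb),
    gene_b = sprintf("b%03d", seq_along(ra))
  )
}

test_that("anchors come from shared families, with the tandem-array cap", {
  a <- mini_genome(sprintf("f%d", 1:5), prefix = "a")
  b <- mini_genome(sprintf("f%d", 1:5), prefix = "b")
  expect_equal(nrow(find_anchors(a, b)), 5)

  a2 <- mini_genome(c("f1", "f1"), prefix = "a")
  b2 <- mini_genome(c("f1", "f1", "f1"), prefix = "b")
  expect_equal(nrow(find_anchors(a2, b2)), 6) # 2 x 3

  a3 <- mini_genome(rep("f1", 11), prefix = "a")
  b3 <- mini_genome(c("f1", "f2"), prefix = "b")
  expect_warning(anc <- find_anchors(a3, b3), "no shared families")
  expect_equal(nrow(anc), 0)
})

test_that("the five-pair and ten-gene thresholds gate blocks exactly", {
  expect_equal(nrow(chain_anchors(diag_anchors(0:4))), 1)
  expect_equal(chain_anchors(diag_anchors(0:4))$n_anchors, 5)
  expect_equal(nrow(chain_anchors(diag_anchors(0:3))), 0)
  # gap of 11 intervening genes splits; both halves reach min_pairs
  split <- chain_anchors(diag_anchors(c(0:4, 16:20)))
  expect_equal(nrow(split), 2)
  # gap of exactly 10 intervening genes chains through
  merged <- chain_anchors(diag_anchors(c(0:4, 15:19)))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_anchors, 10)
})

test_that("inverted blocks are chained with descending partner ranks", {
  inv <- chain_anchors(diag_anchors(0:5, 5:0))
  expect_equal(nrow(inv), 1)
  expect_equal(inv$orientation, "inverted")
  expect_equal(inv$n_anchors, 6)
})

test_that("chaining is invariant to anchor order and validates block invariants", {
  withr::with_seed(51, {
    anc <- diag_anchors(sample(0:30, 18), sample(0:30, 18))
  })
  shuffled <- anc[sample(nrow(anc)), ]
  b1 <- chain_anchors(anc, max_gap = 10, min_pairs = 2)
  b2 <- chain_anchors(shuffled, max_gap = 10, min_pairs = 2)
  expect_equal(dplyr::select(b1, -"anchors"), dplyr::select(b2, -"anchors"))
  for (i in seq_len(nrow(b1))) {
    m <- b1$anchors[[i]]
    expect_gte(nrow(m), 2)
    expect_true(all(diff(m$rank_a) > 0))
    rb <- if (b1$orientation[i] == "inverted") -m$rank_b else m$rank_b
    expect_true(all(diff(rb) > 0))
    expect_true(all(diff(m$rank_a) <= 11) && all(abs(diff(m$rank_b)) <= 11))
  }
})

test_that("DP chaining matches exhaustive enumeration on random instances", {
  withr::with_seed(52, {
    for (i in 1:100) {
      n <- sample(4:12, 1)
      ra <- sample(0:14, n)
      rb <- sample(0:14, n)
      gap <- sample(c(2L, 5L, 10L), 1)
      got <- chain_anchors(diag_anchors(ra, rb), max_gap = gap, min_pairs = 1)
      oracle <- oracle_best_chain_size(ra, rb, gap)
      expect_equal(max(got$n_anchors), oracle,
                   info = paste("instance", i))
    }
  })
})

test_that("depth profiles count covering spans and conserve total coverage", {
  g <- simulate_base_genome(1, 20)
  blocks <- tibble::tibble(
    block_id = 1:2, chrom_a = "chr01", chrom_b = "chr01",
    orientation = "same", n_anchors = 5L,
    span_a_lo = c(0L, 0L), span_a_hi = c(5L, 5L),
    span_b_lo = c(10L, 2L), span_b_hi = c(15L, 8L),
    anchors = list(NULL, NULL)
  )
  pr <- depth_profiles(blocks, g, g)
  expect_equal(sum(pr$a$depth == 2), 5) # two identical spans on A
  expect_equal(sum(pr$a$depth), 10)
  expect_equal(sum(pr$b$depth == 1), 11) # disjoint spans [10,15) and [2,8)
  # conservation over random block sets
  withr::with_seed(53, {
    for (r in 1:50) {
      lo <- sample(0:15, 4)
      hi <- pmin(lo + sample(1:5, 4, replace = TRUE), 20L)
      bl <- tibble::tibble(
        block_id = 1:4, chrom_a = "chr01", chrom_b = "chr01",
        orientation = "same", n_anchors = 5L,
        span_a_lo = lo, span_a_hi = hi,
        span_b_lo = lo, span_b_hi = hi, anchors = vector("list", 4)
      )
      p <- depth_profiles(bl, g, g)
      expect_equal(sum(p$a$depth), sum(hi - lo))
    }
  })
})

test_that("modal depth ratios read one-to-two for a one-round polyploid", {
  base <- simulate_base_genome(2, 150)
  poly <- simulate_polyploid_genome(base, 1, fractionation_params(0.2, 1),
                                    seed = 6)
  blocks <- chain_anchors(find_anchors(base, poly))
  pr <- depth_profiles(blocks, base, poly)
  dr <- depth_ratio(pr)
  expect_equal(dr$mult_a, 1)
  expect_equal(dr$mult_b, 2)
  expect_equal(dr$ratio, "1:2")
  expect_equal(dr$label, "one-to-two")
  expect_true(all(c("depth", "n") %in% names(dr$hist_a[[1]])))
})

test_that("all-zero profiles are refused", {
  g <- simulate_base_genome(1, 10)
  pr <- list(
    a = tibble::tibble(chrom = "chr01", rank = 0:9,
                       gene_id = g$gene_id, depth = 0L),
    b = tibble::tibble(chrom = "chr01", rank = 0:9,
                       gene_id = g$gene_id, depth = 0L)
  )
  expect_error(depth_ratio(pr), "all-zero")
})
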