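#' Derive cross-genome anchor pairs from shared family membership
#'
#' Every pair of genes from the two genomes sharing a `family_id` becomes an
#' anchor, except that families with more than `max_family_size` members in
#' either genome are skipped entirely (a guard against tandem arrays blowing
#' up the anchor list).
#'
#' @param genome_a,genome_b Gene-order tibbles with a shared family namespace.
#' @param max_family_size Family-size cap (default 10).
#' @return A tibble of anchors: `family_id`, `chrom_a`, `rank_a`, `gene_a`,
#'   `chrom_b`, `rank_b`, `gene_b`.
#' @export
find_anchors <- function(genome_a, genome_b, max_family_size = 10L) {
  ga <- validate_gene_order(genome_a)
  gb <- validate_gene_order(genome_b)
  size_a <- table(ga$family_id)
  size_b <- table(gb$family_id)
  ok_fams <- intersect(
    names(size_a)[size_a <= max_family_size],
    names(size_b)[size_b <= max_family_size]
  )
  a <- ga %>%
    filter(.data$family_id %in% ok_fams) %>%
    select(family_id = "family_id", chrom_a = "chrom",
           rank_a = "rank", gene_a = "gene_id")
  b <- gb %>%
    filter(.data$family_id %in% ok_fams) %>%
    select(family_id = "family_id", chrom_b = "chrom",
           rank_b = "rank", gene_b = "gene_id")
  anchors <- dplyr::inner_join(a, b, by = "family_id",
                               relationship = "many-to-many") %>%
    arrange(.data$chrom_a, .data$chrom_b, .data$rank_a, .data$rank_b)
  if (nrow(anchors) == 0L) warn("no shared families: empty anchor list")
  anchors
}

# Maximum-cardinality collinear chain among anchors of one chromosome pair
# and one orientation. ra must be the A-rank, rb the (possibly negated)
# B-rank. Gap = number of intervening genes, must be <= max_gap on BOTH
# genomes. Returns integer indices of the chain (in input order) or NULL.
best_chain_dp <- function(ra, rb, max_gap) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]
  rb <- rb[ord]
  dp <- rep(1L, n)
  pred <- rep(0L, n)
  for (j in seq_len(n)[-1]) {
    i <- seq_len(j - 1L)
    valid <- ra[i] < ra[j] & rb[i] < rb[j] &
      (ra[j] - ra[i]) <= max_gap + 1L & (rb[j] - rb[i]) <= max_gap + 1L
    if (any(valid)) {
      cand <- i[valid]
      best <- cand[which.max(dp[cand])]
      dp[j] <- dp[best] + 1L
      pred[j] <- best
    }
  }
  end <- which.max(dp)
  chain <- integer(dp[end])
  k <- dp[end]
  while (end > 0L) {
    chain[k] <- end
    k <- k - 1L
    end <- pred[end]
  }
  ord[chain]
}

#' Chain anchors into collinear synteny blocks
#'
#' Within each chromosome pair, maximal-cardinality collinear chains are
#' found by longest-increasing-chain dynamic programming, separately for the
#' two orientations, requiring at most `max_gap` intervening genes between
#' consecutive anchors on both genomes. Chains are extracted best-first with
#' anchors consumed (ties: longer total span, then `same` orientation before
#' `inverted`); chains with fewer than `min_pairs` anchors are discarded.
#'
#' @param anchors Anchor tibble from [find_anchors()].
#' @param max_gap Maximum number of intervening genes between consecutive
#'   anchors (default 10, the classic MCScan-style distance cut-off).
#' @param min_pairs Minimum anchor pairs per block (default 5).
#' @return A tibble of blocks with `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `n_anchors`, half-open rank spans `span_a_lo/hi`,
#'   `span_b_lo/hi`, and a list-column `anchors` of the member anchor rows.
#' @export
chain_anchors <- function(anchors, max_gap = 10L, min_pairs = 5L) {
  stopifnot(max_gap >= 0, min_pairs >= 1)
  need <- c("family_id", "chrom_a", "rank_a", "gene_a",
            "chrom_b", "rank_b", "gene_b")
  stopifnot(all(need %in% names(anchors)))
  anchors <- arrange(as_tibble(anchors), .data$chrom_a, .data$chrom_b,
                     .data$rank_a, .data$rank_b)
  groups <- split(anchors,
                  paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"),
                  drop = TRUE)
  blocks <- list()
  for (grp in groups) {
    remaining <- grp
    repeat {
      if (nrow(remaining) < min_pairs) break
      ch_same <- best_chain_dp(remaining$rank_a, remaining$rank_b, max_gap)
      ch_inv <- best_chain_dp(remaining$rank_a, -remaining$rank_b, max_gap)
      span_of <- function(idx) {
        diff(range(remaining$rank_a[idx])) + diff(range(remaining$rank_b[idx]))
      }
      pick_inv <- length(ch_inv) > length(ch_same) ||
        (length(ch_inv) == length(ch_same) &&
           span_of(ch_inv) > span_of(ch_same))
      idx <- if (pick_inv) ch_inv else ch_same
      if (length(idx) < min_pairs) break
      memb <- remaining[idx, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- tibble(
        chrom_a = memb$chrom_a[1L], chrom_b = memb$chrom_b[1L],
        orientation = if (pick_inv) "inverted" else "same",
        n_anchors = nrow(memb),
        span_a_lo = min(memb$rank_a), span_a_hi = max(memb$rank_a) + 1L,
        span_b_lo = min(memb$rank_b), span_b_hi = max(memb$rank_b) + 1L,
        anchors = list(memb)
      )
      remaining <- remaining[-idx, , drop = FALSE]
    }
  }
  if (length(blocks) == 0L) {
    return(tibble(
      block_id = integer(), chrom_a = character(), chrom_b = character(),
      orientation = character(), n_anchors = integer(),
      span_a_lo = integer(), span_a_hi = integer(),
      span_b_lo = integer(), span_b_hi = integer(), anchors = list()
    ))
  }
  out <- bind_rows(blocks) %>%
    arrange(dplyr::desc(.data$n_anchors), .data$chrom_a, .data$chrom_b,
            .data$span_a_lo)
  out$block_id <- seq_len(nrow(out))
  out[c("block_id", setdiff(names(out), "block_id"))]
}

#' Per-gene syntenic depth profiles
#'
#' For every gene of each genome, counts how many synteny-block spans from
#' the comparison cover its rank. Genes with zero coverage are retained (bin
#' 0 of the histogram).
#'
#' @param blocks Block tibble from [chain_anchors()].
#' @param genome_a,genome_b The two gene-order tibbles the blocks refer to.
#' @return A list with tibbles `a` and `b` (`chrom`, `rank`, `gene_id`,
#'   `depth`).
#' @export
depth_profiles <- function(blocks, genome_a, genome_b) {
  ga <- validate_gene_order(genome_a)
  gb <- validate_gene_order(genome_b)
  profile_one <- function(genome, chrom_col, lo_col, hi_col) {
    depth <- integer(nrow(genome))
    for (cm in unique(blocks[[chrom_col]])) {
      rows <- which(genome$chrom == cm)
      if (length(rows) == 0L) {
        abort(paste0("blocks reference unknown chromosome ", cm))
      }
      nr <- length(rows)
      cover <- integer(nr + 1L)
      bl <- blocks[blocks[[chrom_col]] == cm, ]
      for (i in seq_len(nrow(bl))) {
        lo <- max(0L, bl[[lo_col]][i]) + 1L
        hi <- min(nr, bl[[hi_col]][i])
        if (hi >= lo) {
          cover[lo] <- cover[lo] + 1L
          cover[hi + 1L] <- cover[hi + 1L] - 1L
        }
      }
      depth[rows] <- cumsum(cover)[seq_len(nr)]
    }
    tibble(chrom = genome$chrom, rank = genome$rank,
           gene_id = genome$gene_id, depth = depth)
  }
  list(
    a = profile_one(ga, "chrom_a", "span_a_lo", "span_a_hi"),
    b = profile_one(gb, "chrom_b", "span_b_lo", "span_b_hi")
  )
}

ratio_word <- function(m) {
  words <- c("one", "two", "three", "four", "five", "six", "seven",
             "eight", "nine", "ten")
  if (m >= 1 && m <= 10) words[m] else as.character(m)
}

#' Syntenic depth ratio between two genomes
#'
#' The multiplicity of genome A is the modal nonzero depth with which
#' A-anchored block spans cover genome B's genes, and vice versa; the ratio
#' is reported unreduced (a two-round polyploid against a one-round polyploid
#' is `2-to-4`, not `1-to-2`). Zero-depth genes are excluded from the mode
#' but kept in the histograms.
#'
#' @param profiles Depth profiles from [depth_profiles()].
#' @return A one-row tibble with `mult_a`, `mult_b`, `ratio` (e.g. `"1:2"`),
#'   `label` (e.g. `"one-to-two"`), and list-columns `hist_a`, `hist_b`
#'   holding the depth histograms.
#' @export
depth_ratio <- function(profiles) {
  stopifnot(is.list(profiles), all(c("a", "b") %in% names(profiles)))
  modal <- function(depth) {
    nz <- depth[depth > 0]
    if (length(nz) == 0L) abort("all-zero depth profile: no blocks cover any gene")
    which.max(tabulate(nz))
  }
  hist_tab <- function(depth) count(tibble(depth = depth), .data$depth)
  # multiplicity of A = how many A regions align to a typical B gene
  mult_a <- modal(profiles$b$depth)
  mult_b <- modal(profiles$a$depth)
  tibble(
    mult_a = mult_a, mult_b = mult_b,
    ratio = paste0(mult_a, ":", mult_b),
    label = paste0(ratio_word(mult_a), "-to-", ratio_word(mult_b)),
    hist_a = list(hist_tab(profiles$a$depth)),
    hist_b = list(hist_tab(profiles$b$depth))
  )
}
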