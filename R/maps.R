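#' Ladder specification for a MAPS analysis
#'
#' MAPS works on a strictly ladderized (caterpillar) species tree: the
#' ingroup taxa are listed tip-to-root, so taxa 1 and 2 join at node `N1`,
#' taxon 3 joins at `N2`, and so on; outgroup taxa attach below the ingroup
#' root and are used to root the gene trees.
#'
#' @param ingroup Character vector of ingroup taxa, ordered tip-to-root
#'   (at least 2).
#' @param outgroup Character vector of outgroup taxa (at least 1).
#' @return A list of class `ladder_spec` with derived node labels
#'   `N1..N(k-1)`.
#' @export
ladder_spec <- function(ingroup, outgroup) {
  stopifnot(length(ingroup) >= 2, length(outgroup) >= 1,
            !anyDuplicated(c(ingroup, outgroup)))
  structure(list(
    ingroup = ingroup, outgroup = outgroup,
    nodes = paste0("N", seq_len(length(ingroup) - 1L))
  ), class = "ladder_spec")
}

#' Build the ultrametric ladder species tree of a MAPS analysis
#'
#' @param ladder A [ladder_spec()].
#' @param ages Node ages (time-units before present), one per ladder node
#'   `N1..N(k-1)` followed by one per outgroup join, strictly increasing.
#' @return An ultrametric `phylo` tree.
#' @export
ladder_species_tree <- function(ladder, ages) {
  taxa <- c(ladder$ingroup, ladder$outgroup)
  stopifnot(length(ages) == length(taxa) - 1L, !is.unsorted(ages, strictly = TRUE))
  s <- taxa[1L]
  cur <- 0
  for (i in seq_along(ages)) {
    s <- sprintf("(%s:%.10g,%s:%.10g)",
                 s, ages[i] - cur, taxa[i + 1L], ages[i])
    cur <- ages[i]
  }
  read_newick(paste0(s, ";"))
}

#' Test whether a rooted tree is strictly ladderized
#'
#' @param tree A `phylo` object.
#' @return `TRUE` when every internal node has at most one non-leaf child.
#' @export
is_ladder_tree <- function(tree) {
  internal <- tree$edge[, 2L] > length(tree$tip.label)
  parents <- tree$edge[internal, 1L]
  !anyDuplicated(parents)
}

# The species-tree clade collapsing at ladder node Nj (ingroup taxa 1..j+1).
ladder_clade <- function(ladder, node) {
  j <- match(node, ladder$nodes)
  if (is.na(j)) abort(paste0("unknown ladder node: ", node))
  ladder$ingroup[seq_len(j + 1L)]
}

tip_species <- function(tree) sub("\\|.*$", "", tree$tip.label)

# Map one gene tree onto the ladder. Returns NULL (with a reason attribute)
# for unusable trees, otherwise a list of logical vectors `present` and
# `duplicated`, one entry per ladder node.
map_one_tree <- function(tree, ladder) {
  k <- length(ladder$ingroup)
  spp <- tip_species(tree)
  out_tips <- which(spp %in% ladder$outgroup)
  if (length(out_tips) == 0L) {
    return(list(skip = "no outgroup tip"))
  }
  root_tip <- out_tips[order(tree$tip.label[out_tips])][1L]
  tree <- tryCatch(
    ape::root(tree, outgroup = root_tip, resolve.root = TRUE),
    error = function(e) NULL
  )
  if (is.null(tree)) return(list(skip = "unrootable"))
  spp <- tip_species(tree)
  ing_idx <- match(spp, ladder$ingroup)
  all_idx <- match(spp, c(ladder$ingroup, ladder$outgroup))
  ntip <- length(spp)
  nnode <- ntip + tree$Nnode
  mask_in <- integer(nnode) # bitmask over ingroup species
  mask_all <- numeric(nnode) # bitmask over all species (double: up to 2^52)
  is_dup <- logical(nnode)
  for (t in seq_len(ntip)) {
    if (!is.na(ing_idx[t])) mask_in[t] <- bitwShiftL(1L, ing_idx[t] - 1L)
    mask_all[t] <- 2^(all_idx[t] - 1L)
  }
  parent_of <- integer(nnode)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) { # children are complete before use
    p <- edges[e, 1L]
    ch <- edges[e, 2L]
    parent_of[ch] <- p
    if (bit_and_dbl(mask_all[p], mask_all[ch]) > 0) is_dup[p] <- TRUE
    mask_in[p] <- bitwOr(mask_in[p], mask_in[ch])
    mask_all[p] <- mask_all[p] + mask_all[ch] -
      bit_and_dbl(mask_all[p], mask_all[ch])
  }
  # a gene-tree node maps to ladder node Nj iff its leaf-species set holds
  # >= 2 ingroup species, none of them outgroup, with max ladder index j+1;
  # the subtree counted at Nj is the MAXIMAL such node (its parent maps
  # elsewhere), so one retained WGD copy contributes one extra subtree, not
  # an inflated duplication percentage
  maps_to <- function(v) {
    m_in <- mask_in[v]
    if (mask_all[v] < 2^k && m_in > 0L && bitwAnd(m_in, m_in - 1L) != 0L) {
      floor(log2(m_in))
    } else 0L
  }
  total <- integer(k - 1L)
  dup <- integer(k - 1L)
  for (v in (ntip + 1L):nnode) {
    node_j <- maps_to(v)
    if (node_j > 0L &&
        (parent_of[v] == 0L || maps_to(parent_of[v]) != node_j)) {
      total[node_j] <- total[node_j] + 1L
      if (is_dup[v]) dup[node_j] <- dup[node_j] + 1L
    }
  }
  list(total = total, dup = dup)
}

# bitwise AND for species masks stored as doubles (> 31 species safe-guard)
bit_and_dbl <- function(a, b) {
  if (a < .Machine$integer.max && b < .Machine$integer.max) {
    return(bitwAnd(as.integer(a), as.integer(b)))
  }
  r <- 0
  bit <- 1
  while (a > 0 && b > 0) {
    if (a %% 2 >= 1 && b %% 2 >= 1) r <- r + bit
    a <- a %/% 2
    b <- b %/% 2
    bit <- bit * 2
  }
  r
}

# Per-tree subtree/duplication counts for a set of gene trees: integer
# matrices trees x ladder nodes, plus skip bookkeeping.
maps_flags <- function(gene_trees, ladder) {
  k <- length(ladder$ingroup)
  species <- c(ladder$ingroup, ladder$outgroup)
  usable <- logical(length(gene_trees))
  reasons <- character(0)
  total <- matrix(0L, length(gene_trees), k - 1L)
  dup <- matrix(0L, length(gene_trees), k - 1L)
  for (i in seq_along(gene_trees)) {
    tr <- gene_trees[[i]]
    if (is.null(tr)) {
      reasons <- c(reasons, "empty tree")
      next
    }
    if (!all(species %in% tip_species(tr))) {
      reasons <- c(reasons, "missing species coverage")
      next
    }
    m <- map_one_tree(tr, ladder)
    if (!is.null(m$skip)) {
      reasons <- c(reasons, m$skip)
      next
    }
    usable[i] <- TRUE
    total[i, ] <- m$total
    dup[i, ] <- m$dup
  }
  list(total = total[usable, , drop = FALSE],
       dup = dup[usable, , drop = FALSE],
       n_usable = sum(usable), skipped = reasons)
}

#' Map the duplications of one gene tree onto ladder nodes
#'
#' Roots the gene tree at its first outgroup tip, maps every internal node to
#' the species-tree node that is the LCA of its leaf-species set, and flags
#' nodes whose child leaf-species sets intersect as duplications. Counted
#' subtrees are the maximal nodes mapping to each ladder node.
#'
#' @param gene_tree A `phylo` gene tree with `SPECIES|gene` tip labels.
#' @param ladder A [ladder_spec()].
#' @return A tibble `node`, `subtrees`, `duplicated`; errors when the tree
#'   carries no outgroup tip.
#' @export
map_duplications <- function(gene_tree, ladder) {
  m <- map_one_tree(gene_tree, ladder)
  if (!is.null(m$skip)) abort(paste0("gene tree unusable: ", m$skip))
  tibble(node = ladder$nodes, subtrees = m$total, duplicated = m$dup)
}

#' Count shared gene duplications at each ladder node
#'
#' For every gene tree (rooted by its outgroup) each internal node is mapped
#' to the species-tree node that is the LCA of its leaf-species set; a node
#' is a duplication when its child leaf-species sets intersect. Per ladder
#' node the subtree total counts the maximal gene-tree nodes mapping there,
#' and the shared-duplication count those that are duplications. Trees
#' missing a species or lacking an outgroup tip are skipped and recorded.
#'
#' @param gene_trees List of `phylo` gene trees with `SPECIES|gene` tips.
#' @param ladder A [ladder_spec()].
#' @return A tibble of class `maps_result`: `node`, `subtree_total`,
#'   `shared_dups`, `pct`, with attributes `n_trees` and `skipped`.
#' @export
maps_table <- function(gene_trees, ladder) {
  fl <- maps_flags(gene_trees, ladder)
  if (fl$n_usable == 0L) abort("no usable gene trees (coverage/outgroup filters)")
  tot <- colSums(fl$total)
  shr <- colSums(fl$dup)
  out <- tibble(
    node = ladder$nodes,
    subtree_total = tot,
    shared_dups = shr,
    pct = ifelse(tot > 0, 100 * shr / tot, 0)
  )
  structure(out, class = c("maps_result", class(out)),
            n_trees = fl$n_usable, skipped = fl$skipped)
}

#' Simulate the birth-death null for a MAPS analysis
#'
#' Simulates `n_trees` coverage-filtered gene trees under the fitted
#' birth-death rates (no WGD) and tabulates shared duplications.
#'
#' @param species_tree Ultrametric `phylo` tree matching the ladder (see
#'   [ladder_species_tree()]).
#' @param ladder A [ladder_spec()].
#' @param bd A [bd_params()] object.
#' @param n_trees Number of simulated gene trees (default 3000).
#' @param seed Optional integer seed.
#' @return A `maps_result` tibble.
#' @export
run_null <- function(species_tree, ladder, bd, n_trees = 3000L, seed = NULL) {
  trees <- simulate_tree_set(species_tree, bd, list(), n = n_trees,
                             require_full_coverage = TRUE, seed = seed)
  res <- maps_table(trees, ladder)
  attr(res, "gene_trees") <- trees
  res
}

#' Simulate a WGD-positive comparison for a MAPS analysis
#'
#' As [run_null()] plus one whole-genome duplication placed on the branch
#' subtending the given ladder node. Retention below 0.2 is allowed but
#' warned about, since positive simulations are normally run with at least
#' 20% retention.
#'
#' @inheritParams run_null
#' @param wgd_node Ladder node label (e.g. `"N2"`) carrying the WGD.
#' @param retention Per-lineage retention probability of WGD copies.
#' @return A `maps_result` tibble.
#' @export
run_positive <- function(species_tree, ladder, bd, wgd_node, retention = 0.2,
                         n_trees = 3000L, seed = NULL) {
  if (retention < 0.2) {
    warn("retention below 0.2: positive simulations normally retain >= 20%")
  }
  ev <- wgd_event(ladder_clade(ladder, wgd_node), retention = retention)
  trees <- simulate_tree_set(species_tree, bd, list(ev), n = n_trees,
                             require_full_coverage = TRUE, seed = seed)
  res <- maps_table(trees, ladder)
  attr(res, "gene_trees") <- trees
  res
}

#' Resampling uncertainty for per-node duplication percentages
#'
#' Resamples `size` trees without replacement `reps` times and reports the
#' 2.5-97.5 percentile interval of the per-node percentages.
#'
#' @param gene_trees List of `phylo` gene trees.
#' @param ladder A [ladder_spec()].
#' @param size Trees per resample (default 1000).
#' @param reps Number of resamples (default 100).
#' @param seed Optional integer seed.
#' @return A tibble `node`, `pct_lo`, `pct_hi` with the resampled
#'   percentages as attribute `resamples` (reps x nodes matrix).
#' @export
resample_percentages <- function(gene_trees, ladder, size = 1000L,
                                 reps = 100L, seed = NULL) {
  fl <- maps_flags(gene_trees, ladder)
  if (fl$n_usable < size) {
    abort(sprintf(
      "pool of %d usable trees is smaller than the resample size %d; choose a smaller size",
      fl$n_usable, size))
  }
  run <- function() {
    pcts <- matrix(NA_real_, reps, length(ladder$nodes))
    for (r in seq_len(reps)) {
      idx <- sample.int(fl$n_usable, size, replace = FALSE)
      tot <- colSums(fl$total[idx, , drop = FALSE])
      shr <- colSums(fl$dup[idx, , drop = FALSE])
      pcts[r, ] <- ifelse(tot > 0, 100 * shr / tot, 0)
    }
    out <- tibble(
      node = ladder$nodes,
      pct_lo = apply(pcts, 2L, quantile, probs = 0.025, names = FALSE),
      pct_hi = apply(pcts, 2L, quantile, probs = 0.975, names = FALSE)
    )
    attr(out, "resamples") <- pcts
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Fisher's exact comparison of observed vs null shared duplications
#'
#' Per ladder node, a one-sided (greater) Fisher's exact test on the 2x2
#' table of (duplicated, not duplicated) subtrees in the observed vs the
#' null collection. No correction is applied across nodes.
#'
#' @param observed,null `maps_result` tibbles sharing the same ladder nodes.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A tibble `node`, `obs_pct`, `null_pct`, `p_value`, `significant`.
#' @export
fisher_compare <- function(observed, null, alpha = 0.05) {
  stopifnot(identical(observed$node, null$node))
  p <- vapply(seq_len(nrow(observed)), function(i) {
    o_t <- observed$subtree_total[i]
    n_t <- null$subtree_total[i]
    if (o_t == 0 || n_t == 0) {
      warn(sprintf("zero subtree total at node %s; p set to 1", observed$node[i]))
      return(1)
    }
    m <- matrix(c(observed$shared_dups[i], o_t - observed$shared_dups[i],
                  null$shared_dups[i], n_t - null$shared_dups[i]), 2L)
    fisher.test(m, alternative = "greater")$p.value
  }, numeric(1))
  tibble(
    node = observed$node,
    obs_pct = observed$pct, null_pct = null$pct,
    p_value = p, significant = p < alpha
  )
}

#' Flag nodes consistent with a positive WGD simulation
#'
#' A node is consistent with the positive simulation when its observed
#' percentage reaches at least the lower resampling bound of the positive
#' simulation and its Fisher test against the null is significant.
#'
#' @param observed A `maps_result` for the observed gene trees.
#' @param fisher Output of [fisher_compare()] (observed vs null).
#' @param positive_ci Output of [resample_percentages()] on the positive
#'   simulation's gene trees.
#' @return `fisher` with columns `positive_lo` and `consistent_with_positive`.
#' @export
consistent_with_positive <- function(observed, fisher, positive_ci) {
  stopifnot(identical(fisher$node, positive_ci$node))
  mutate(fisher,
         positive_lo = positive_ci$pct_lo,
         consistent_with_positive =
           .data$significant & observed$pct >= positive_ci$pct_lo)
}
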