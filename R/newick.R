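#' Read a rooted tree from a newick string
#'
#' Thin, strict wrapper around [ape::read.tree()]. The input must be a single
#' newick statement terminated by `";"`. Leaf labels must be unique and branch
#' lengths, when present, non-negative. Polytomies are preserved.
#'
#' @param text A single newick string (one tree, terminated by `";"`).
#' @param rooted_required If `TRUE` (default), refuse unrooted trees.
#' @return An object of class `phylo`.
#' @seealso [write_newick()]
#' @export
#' @examples
#' tr <- read_newick("(A:1,(B:0.5,C:0.5):0.5);")
#' write_newick(tr)
read_newick <- function(text, rooted_required = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || !grepl(";\\s*$", text)) {
    abort("newick parse error: input must be a single statement ending in ';'")
  }
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort(sprintf(
      "newick parse error: unbalanced parentheses (%d '(' vs %d ')')",
      n_open, n_close
    ))
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort("newick parse error: malformed tree statement")
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("newick parse error: duplicate leaf label(s): ",
                 paste(dup, collapse = ", ")))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1L]
    abort(sprintf(
      "newick parse error: negative branch length %g on edge to node %d",
      tree$edge.length[bad], tree$edge[bad, 2L]
    ))
  }
  if (rooted_required && !ape::is.rooted(tree)) {
    abort("tree is unrooted but a rooted tree is required")
  }
  tree
}

#' Write a tree as a canonical newick string
#'
#' Children of every node are ordered by their smallest descendant tip label,
#' so the output is invariant under child-order permutation of the input.
#' Branch lengths are printed with 10 significant digits; trees without
#' branch lengths yield a topology-only string.
#'
#' @param tree A `phylo` object.
#' @return A single newick string terminated by `";"`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- tree$edge.length
  edge_of <- integer(max(tree$edge))
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))

  min_lab <- character(ntip + tree$Nnode)
  fill_min <- function(node) {
    if (node <= ntip) {
      min_lab[node] <<- tree$tip.label[node]
    } else {
      for (k in kids[[as.character(node)]]) fill_min(k)
      min_lab[node] <<- min(min_lab[kids[[as.character(node)]]])
    }
  }
  fill_min(root)

  fmt <- function(node) {
    ch <- kids[[as.character(node)]]
    lab <- if (node <= ntip) tree$tip.label[node] else ""
    s <- if (is.null(ch)) {
      lab
    } else {
      ch <- ch[order(min_lab[ch])]
      paste0("(", paste(vapply(ch, fmt, character(1)), collapse = ","), ")", lab)
    }
    if (!is.null(elen) && node != root) {
      s <- paste0(s, ":", sprintf("%.10g", elen[edge_of[node]]))
    }
    s
  }
  paste0(fmt(root), ";")
}

#' Node ages of an ultrametric tree
#'
#' Ages are measured backwards from the tips (all tips at age 0).
#'
#' @param tree A `phylo` object with branch lengths.
#' @param tol Maximum allowed root-to-tip spread before the tree is declared
#'   non-ultrametric.
#' @return Numeric vector of ages indexed by node number (tips first).
#' @export
node_ages <- function(tree, tol = 1e-8) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  h <- depth[seq_len(ntip)]
  if (diff(range(h)) > tol) {
    abort(sprintf("tree is not ultrametric (root-to-tip spread %g)",
                  diff(range(h))))
  }
  max(depth) - depth
}

#' Test whether a tree is ultrametric in time
#'
#' @inheritParams node_ages
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-8) {
  if (is.null(tree$edge.length)) return(FALSE)
  depth <- ape::node.depth.edgelength(tree)
  diff(range(depth[seq_len(length(tree$tip.label))])) <= tol
}
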