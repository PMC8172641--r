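# Gene-count likelihood under a linear birth-death process on a species tree
# (the WGDgc-style model used to parameterise MAPS null simulations).

# Transition probabilities of a linear BDP from one lineage over time t:
# P(0) = alpha, P(j) = (1 - alpha)(1 - beta) beta^(j-1).
bd_p1 <- function(lambda, mu, t, n_max) {
  if (abs(lambda - mu) < 1e-12) {
    a <- if (lambda == 0) 0 else lambda * t / (1 + lambda * t)
    b <- a
  } else {
    E <- exp((lambda - mu) * t)
    a <- mu * (E - 1) / (lambda * E - mu)
    b <- lambda * (E - 1) / (lambda * E - mu)
  }
  j <- seq_len(n_max)
  c(a, (1 - a) * (1 - b) * b^(j - 1))
}

# Full transition matrix over counts 0..n_max: row i+1 is the i-fold
# convolution of the one-lineage distribution (lineages are independent).
bd_trans_matrix <- function(lambda, mu, t, n_max) {
  p1 <- bd_p1(lambda, mu, t, n_max)
  M <- matrix(0, n_max + 1L, n_max + 1L)
  M[1L, 1L] <- 1
  M[2L, ] <- p1
  if (n_max >= 2L) {
    for (i in 3L:(n_max + 1L)) {
      conv <- stats::convolve(M[i - 1L, ], rev(p1), type = "open")
      M[i, ] <- pmax(conv[seq_len(n_max + 1L)], 0)
    }
  }
  M
}

#' Log-likelihood of gene counts under a linear birth-death process
#'
#' Felsenstein-style pruning over gene counts truncated at `n_max`, with one
#' gene at the root and conditioning on at least one surviving gene in the
#' family. All-zero families are excluded.
#'
#' @param gene_counts Tibble from [simulate_gene_counts()] (or any table with
#'   `family_id` plus one count column per species-tree tip).
#' @param species_tree Ultrametric `phylo` tree whose tip labels match the
#'   count columns.
#' @param lambda,mu Birth and death rates per gene per time-unit.
#' @param n_max Count-space truncation (default 100).
#' @return Total log-likelihood (scalar).
#' @export
bd_loglik <- function(gene_counts, species_tree, lambda, mu, n_max = 100L) {
  tips <- species_tree$tip.label
  stopifnot(all(tips %in% names(gene_counts)))
  counts <- as.matrix(gene_counts[, tips, drop = FALSE])
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(counts) == 0L) abort("no families with at least one surviving gene")
  n_max <- max(2L, min(n_max, 3L * max(counts) + 10L))
  if (max(counts) > n_max) abort("gene counts exceed the truncation bound")
  nf <- nrow(counts)
  ntip <- length(tips)
  nnode <- ntip + species_tree$Nnode
  elen <- numeric(nnode)
  elen[species_tree$edge[, 2L]] <- species_tree$edge.length
  edges <- ape::reorder.phylo(species_tree, "postorder")$edge
  # conditional likelihood matrices (n_max+1) x (families + 1); the extra
  # column tracks the all-extinct family for the conditioning constant
  L <- vector("list", nnode)
  for (t in seq_len(ntip)) {
    m <- matrix(0, n_max + 1L, nf + 1L)
    m[cbind(counts[, tips[t]] + 1L, seq_len(nf))] <- 1
    m[1L, nf + 1L] <- 1
    L[[t]] <- m
  }
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]
    ch <- edges[e, 2L]
    Tm <- bd_trans_matrix(lambda, mu, elen[ch], n_max)
    msg <- Tm %*% L[[ch]]
    L[[p]] <- if (is.null(L[[p]])) msg else L[[p]] * msg
  }
  root <- L[[ntip + 1L]][2L, ] # one gene enters the root
  p_ext <- root[nf + 1L]
  lik <- pmax(root[seq_len(nf)], 1e-300) / max(1 - p_ext, 1e-12)
  sum(log(lik))
}

#' Estimate birth and death rates from gene counts
#'
#' Maximum-likelihood estimation of a single global (lambda, mu) for a linear
#' birth-death process of gene family evolution along the species tree, by
#' numerical optimisation of [bd_loglik()] on the log-rate scale.
#'
#' @inheritParams bd_loglik
#' @param init Starting rates (defaults to 0.002 events/gene/time-unit each).
#' @return A [bd_params()] object with attributes `loglik` and `convergence`.
#'   A warning is issued when an estimate sits at the lower boundary (e.g.
#'   all counts equal 1 pushes the birth rate to 0).
#' @export
estimate_bd_rates <- function(gene_counts, species_tree, n_max = 100L,
                              init = c(0.002, 0.002)) {
  nll <- function(par) {
    -bd_loglik(gene_counts, species_tree, exp(par[1]), exp(par[2]),
               n_max = n_max)
  }
  opt <- optim(log(init), nll, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-9))
  lambda <- exp(opt$par[1])
  mu <- exp(opt$par[2])
  if (lambda < 1e-6 || mu < 1e-6) {
    warn("rate estimate at the boundary (~0); data carry little birth/death signal")
  }
  out <- bd_params(lambda, mu)
  attr(out, "loglik") <- -opt$value
  attr(out, "convergence") <- opt$convergence
  out
}
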