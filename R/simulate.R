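#' Birth-death rate parameters for gene-family evolution
#'
#' Rates are per gene lineage per time-unit (the time-unit is whatever the
#' species-tree branch lengths are in, typically million years).
#'
#' @param birth_rate Duplication rate lambda (>= 0).
#' @param death_rate Loss rate mu (>= 0).
#' @return A list of class `bd_params`.
#' @export
bd_params <- function(birth_rate, death_rate) {
  stopifnot(is.numeric(birth_rate), is.numeric(death_rate),
            birth_rate >= 0, death_rate >= 0)
  structure(list(birth_rate = birth_rate, death_rate = death_rate),
            class = "bd_params")
}

#' An episodic whole-genome duplication event on a species-tree branch
#'
#' The event sits on the branch subtending the most recent common ancestor of
#' `clade`, at `time_on_branch` time-units below the parent node. At the
#' event every gene lineage alive on that branch duplicates; each new copy is
#' retained with probability `retention`, independently per lineage.
#'
#' @param clade Character vector of tip labels; the event is placed on the
#'   edge above their MRCA (a single label places it on a terminal branch).
#' @param retention Per-lineage retention probability of the new copy,
#'   in (0, 1].
#' @param time_on_branch Time from the parent node to the event; defaults to
#'   the branch midpoint when `NULL`.
#' @return A list of class `wgd_event`.
#' @export
wgd_event <- function(clade, retention, time_on_branch = NULL) {
  stopifnot(is.character(clade), length(clade) >= 1,
            retention > 0, retention <= 1)
  structure(list(clade = clade, retention = retention,
                 time_on_branch = time_on_branch),
            class = "wgd_event")
}

#' Molecular-clock parameters mapping node ages to Ks
#'
#' A duplicate pair whose most recent common ancestor has age `a` receives
#' `ks = 2 * ks_rate * a`, times multiplicative gamma noise with mean 1 and
#' coefficient of variation `noise_cv`.
#'
#' @param ks_rate Synonymous substitutions per site per time-unit (> 0).
#' @param noise_cv Coefficient of variation of the gamma noise (>= 0);
#'   default 0.15 gives peak widths typical of empirical Ks distributions.
#' @return A list of class `clock_params`.
#' @export
clock_params <- function(ks_rate, noise_cv = 0.15) {
  stopifnot(ks_rate > 0, noise_cv >= 0)
  structure(list(ks_rate = ks_rate, noise_cv = noise_cv),
            class = "clock_params")
}

#' Post-polyploidy fractionation parameters
#'
#' @param loss_prob Probability that a gene on a newly created duplicate
#'   chromosome copy is deleted, in [0, 1).
#' @param n_inversions Number of random rank-interval inversions applied to
#'   every chromosome after duplication and loss (>= 0).
#' @return A list of class `fractionation_params`.
#' @export
fractionation_params <- function(loss_prob = 0.3, n_inversions = 2L) {
  stopifnot(loss_prob >= 0, loss_prob < 1, n_inversions >= 0)
  structure(list(loss_prob = loss_prob, n_inversions = as.integer(n_inversions)),
            class = "fractionation_params")
}

# Resolve WGD events to (child-node id, time-from-parent, retention) against a
# species tree; errors on unknown labels or out-of-range times.
resolve_wgds <- function(species_tree, wgds) {
  if (inherits(wgds, "wgd_event")) wgds <- list(wgds)
  ntip <- length(species_tree$tip.label)
  elen <- numeric(ntip + species_tree$Nnode)
  elen[species_tree$edge[, 2L]] <- species_tree$edge.length
  out <- vector("list", ntip + species_tree$Nnode)
  for (w in wgds) {
    idx <- match(w$clade, species_tree$tip.label)
    if (anyNA(idx)) {
      abort(paste0("WGD clade label(s) not in species tree: ",
                   paste(w$clade[is.na(idx)], collapse = ", ")))
    }
    node <- if (length(idx) == 1L) idx else ape::getMRCA(species_tree, idx)
    if (node == ntip + 1L) abort("cannot place a WGD above the root node")
    t_on <- if (is.null(w$time_on_branch)) elen[node] / 2 else w$time_on_branch
    if (t_on < 0 || t_on > elen[node]) {
      abort(sprintf("WGD time_on_branch %g outside branch length %g",
                    t_on, elen[node]))
    }
    out[[node]] <- rbind(out[[node]], c(t_on, w$retention))
  }
  lapply(out, function(m) {
    if (is.null(m)) return(NULL)
    m[order(m[, 1L]), , drop = FALSE]
  })
}

# Core lineage simulator. Returns a nested-list gene tree
# (list(len, children | tip species index)) or NULL if no descendants survive.
sim_gene_struct <- function(species_tree, bd, wgds = list()) {
  ntip <- length(species_tree$tip.label)
  node_ages(species_tree) # errors when not ultrametric
  kids <- vector("list", ntip + species_tree$Nnode)
  for (i in seq_len(nrow(species_tree$edge))) {
    p <- species_tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], species_tree$edge[i, 2L])
  }
  elen <- numeric(ntip + species_tree$Nnode)
  elen[species_tree$edge[, 2L]] <- species_tree$edge.length
  wgd_at <- resolve_wgds(species_tree, wgds)
  lambda <- bd$birth_rate
  mu <- bd$death_rate
  rate <- lambda + mu

  join <- function(parts, base_len) {
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) {
      parts[[1L]]$len <- parts[[1L]]$len + base_len
      return(parts[[1L]])
    }
    list(len = base_len, children = parts)
  }

  evolve <- function(sp, t0) {
    L <- elen[sp]
    t_bd <- if (rate > 0) t0 + rexp(1L, rate) else Inf
    t_w <- Inf
    ret <- NA_real_
    wm <- wgd_at[[sp]]
    if (!is.null(wm)) {
      i <- which(wm[, 1L] > t0 + 1e-12)
      if (length(i) > 0L) {
        t_w <- wm[i[1L], 1L]
        ret <- wm[i[1L], 2L]
      }
    }
    if (L <= t_bd && L <= t_w) { # reach the species node
      if (is.null(kids[[sp]])) return(list(len = L - t0, tip = sp))
      return(join(lapply(kids[[sp]], evolve, t0 = 0), L - t0))
    }
    if (t_w <= t_bd) { # whole-genome duplication
      keep_copy <- runif(1L) < ret
      a <- evolve(sp, t_w)
      b <- if (keep_copy) evolve(sp, t_w) else NULL
      return(join(list(a, b), t_w - t0))
    }
    if (runif(1L) < lambda / rate) { # gene duplication
      join(list(evolve(sp, t_bd), evolve(sp, t_bd)), t_bd - t0)
    } else { # gene loss
      NULL
    }
  }

  root <- ntip + 1L
  res <- join(lapply(kids[[root]], evolve, t0 = 0), 0)
  if (!is.null(res)) res$len <- 0
  res
}

# Tip count per species (named integer vector over all species labels).
census_struct <- function(struct, species_labels) {
  counts <- integer(length(species_labels))
  walk <- function(nd) {
    if (!is.null(nd$tip)) {
      counts[nd$tip] <<- counts[nd$tip] + 1L
    } else {
      for (ch in nd$children) walk(ch)
    }
  }
  if (!is.null(struct)) walk(struct)
  setNames(counts, species_labels)
}

# Deterministic newick rendering with SPECIES|gene tip labels.
struct_to_newick <- function(struct, species_labels) {
  counter <- 0L
  fmt <- function(nd) {
    if (!is.null(nd$tip)) {
      counter <<- counter + 1L
      paste0(species_labels[nd$tip], "|g", counter, ":", sprintf("%.12g", nd$len))
    } else {
      paste0("(", paste(vapply(nd$children, fmt, character(1)), collapse = ","),
             "):", sprintf("%.12g", nd$len))
    }
  }
  if (is.null(struct)) return(NULL)
  paste0(fmt(struct), ";")
}

struct_ntips <- function(struct) {
  if (is.null(struct)) return(0L)
  if (!is.null(struct$tip)) return(1L)
  sum(vapply(struct$children, struct_ntips, integer(1)))
}

#' Simulate one gene tree inside a species tree
#'
#' One gene lineage enters the root. Along every branch each extant lineage
#' duplicates at rate `lambda` and is lost at rate `mu` (a linear
#' birth-death process); at each [wgd_event()] on the branch every extant
#' lineage duplicates and the new copy is kept with the event's retention
#' probability. Extinct subtrees are pruned, so the returned tree is
#' time-ultrametric with tips labelled `SPECIES|gene`.
#'
#' @param species_tree Ultrametric `phylo` species tree (branch lengths in
#'   time-units).
#' @param bd A [bd_params()] object.
#' @param wgds List of [wgd_event()] objects (possibly empty).
#' @param seed Optional integer seed for reproducibility.
#' @return A `phylo` gene tree, or `NULL` when fewer than two gene copies
#'   survive to the present.
#' @export
#' @examples
#' sp <- read_newick("((A:10,B:10):10,C:20);")
#' gt <- simulate_gene_tree(sp, bd_params(0, 0))
#' gt$tip.label
simulate_gene_tree <- function(species_tree, bd, wgds = list(), seed = NULL) {
  run <- function() {
    struct <- sim_gene_struct(species_tree, bd, wgds)
    if (struct_ntips(struct) < 2L) return(NULL)
    ape::read.tree(text = struct_to_newick(struct, species_tree$tip.label))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a set of gene trees, optionally filtered for species coverage
#'
#' With `require_full_coverage = TRUE` (the default) trees are
#' rejection-sampled until each retained tree carries at least one tip per
#' species; the realised acceptance rate is attached as an attribute.
#'
#' @inheritParams simulate_gene_tree
#' @param n Number of trees to return.
#' @param require_full_coverage Keep only trees with >= 1 tip per species.
#' @param seed Optional integer seed.
#' @return A list of `phylo` gene trees with attribute `acceptance_rate`.
#' @export
simulate_tree_set <- function(species_tree, bd, wgds = list(), n,
                              require_full_coverage = TRUE, seed = NULL) {
  stopifnot(n >= 1)
  labels <- species_tree$tip.label
  run <- function() {
    trees <- vector("list", n)
    accepted <- 0L
    attempts <- 0L
    while (accepted < n) {
      attempts <- attempts + 1L
      if (attempts >= 1e6L && accepted / attempts < 1e-3) {
        abort(paste0(
          "coverage acceptance rate below 1e-3 after 1e6 attempts; ",
          "birth/death rates are incompatible with full species coverage"))
      }
      struct <- sim_gene_struct(species_tree, bd, wgds)
      if (require_full_coverage &&
          any(census_struct(struct, labels) == 0L)) next
      if (struct_ntips(struct) < 2L) next
      accepted <- accepted + 1L
      trees[[accepted]] <-
        ape::read.tree(text = struct_to_newick(struct, labels))
    }
    attr(trees, "acceptance_rate") <- accepted / attempts
    trees
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Assign clock Ks values to every leaf pair of a gene tree
#'
#' Each pair receives `ks = 2 * ks_rate * age(MRCA)` multiplied by gamma
#' noise with mean 1 and CV `noise_cv`; the `node_id` column records which
#' internal node (duplication or speciation) generated the pair.
#'
#' @param gene_tree Ultrametric `phylo` gene tree.
#' @param clock A [clock_params()] object.
#' @param seed Optional integer seed.
#' @return A validated Ks tibble (`gene_a`, `gene_b`, `ks`, `family_id`,
#'   `node_id`).
#' @export
assign_pairwise_ks <- function(gene_tree, clock, seed = NULL) {
  stopifnot(inherits(gene_tree, "phylo"))
  run <- function() {
    ages <- node_ages(gene_tree)
    ntip <- length(gene_tree$tip.label)
    prs <- utils::combn(ntip, 2L)
    mr <- ape::mrca(gene_tree)
    anc <- mr[cbind(prs[1L, ], prs[2L, ])]
    ks0 <- 2 * clock$ks_rate * ages[anc]
    noise <- if (clock$noise_cv > 0) {
      shp <- 1 / clock$noise_cv^2
      rgamma(length(ks0), shape = shp, rate = shp)
    } else 1
    validate_ks_table(tibble(
      gene_a = gene_tree$tip.label[prs[1L, ]],
      gene_b = gene_tree$tip.label[prs[2L, ]],
      ks = ks0 * noise,
      node_id = paste0("n", anc)
    ))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate gene counts per family and species
#'
#' Tip census of independent [simulate_gene_tree()] runs, without any
#' coverage filter; families that go extinct everywhere yield all-zero rows.
#'
#' @inheritParams simulate_gene_tree
#' @param n_families Number of families to simulate.
#' @return A tibble with `family_id` and one integer count column per species.
#' @export
simulate_gene_counts <- function(species_tree, bd, n_families, seed = NULL) {
  stopifnot(n_families >= 1)
  labels <- species_tree$tip.label
  run <- function() {
    rows <- lapply(seq_len(n_families), function(i) {
      census_struct(sim_gene_struct(species_tree, bd), labels)
    })
    counts <- do.call(rbind, rows)
    out <- as_tibble(as.data.frame(counts))
    out$family_id <- sprintf("fam%05d", seq_len(n_families))
    out[c("family_id", labels)]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a simple single-copy base genome
#'
#' Fixture generator: `n_chrom` chromosomes of `genes_per_chrom` genes, each
#' gene its own family, so two genomes derived from the same base share a
#' family namespace and anchor cleanly.
#'
#' @param n_chrom Number of chromosomes.
#' @param genes_per_chrom Genes per chromosome.
#' @param prefix Prefix for gene/family identifiers.
#' @return A gene-order tibble.
#' @export
simulate_base_genome <- function(n_chrom = 5L, genes_per_chrom = 400L,
                                 prefix = "g") {
  stopifnot(n_chrom >= 1, genes_per_chrom >= 1)
  n <- n_chrom * genes_per_chrom
  validate_gene_order(tibble(
    chrom = rep(sprintf("chr%02d", seq_len(n_chrom)), each = genes_per_chrom),
    rank = rep(seq_len(genes_per_chrom) - 1L, times = n_chrom),
    gene_id = sprintf("%s%06d", prefix, seq_len(n)),
    family_id = sprintf("f%06d", seq_len(n)),
    strand = "+"
  ))
}

#' Simulate a polyploid genome by rounds of duplication and fractionation
#'
#' Each round multiplies every chromosome by `multiplier` (2 = WGD,
#' 3 = whole-genome triplication). Genes on the newly created copies are then
#' deleted independently with probability `loss_prob`, and every chromosome
#' receives `n_inversions` random rank-interval inversions. Family labels are
#' preserved so anchors against the base genome (or another derived polyploid)
#' still exist.
#'
#' @param base A gene-order tibble (see [validate_gene_order()]).
#' @param rounds Number of polyploidy rounds (>= 0; 0 returns the base).
#' @param fract A [fractionation_params()] object.
#' @param multiplier Copies of each chromosome made per round (default 2).
#' @param seed Optional integer seed.
#' @return A gene-order tibble.
#' @export
simulate_polyploid_genome <- function(base, rounds,
                                      fract = fractionation_params(),
                                      multiplier = 2L, seed = NULL) {
  base <- validate_gene_order(base)
  if (nrow(base) == 0L) abort("base genome is empty")
  stopifnot(rounds >= 0, multiplier >= 2)
  run <- function() {
    g <- base
    for (r in seq_len(rounds)) {
      copies <- lapply(seq_len(multiplier - 1L), function(j) {
        cp <- g
        cp$chrom <- paste0(g$chrom, ".", r, ".", j)
        cp$gene_id <- paste0(g$gene_id, ".", r, ".", j)
        cp[runif(nrow(cp)) >= fract$loss_prob, , drop = FALSE]
      })
      g <- bind_rows(c(list(g), copies))
    }
    # re-rank gapless, then apply inversions chromosome by chromosome
    g <- g %>%
      group_by(.data$chrom) %>%
      arrange(.data$rank, .by_group = TRUE) %>%
      mutate(rank = row_number() - 1L) %>%
      ungroup()
    if (fract$n_inversions > 0L && rounds > 0L) {
      g <- g %>%
        group_by(.data$chrom) %>%
        arrange(.data$rank, .by_group = TRUE) %>%
        group_by(.data$chrom) %>%
        dplyr::group_modify(function(df, key) {
          nr <- nrow(df)
          for (k in seq_len(fract$n_inversions)) {
            if (nr < 2L) break
            ij <- sort(sample.int(nr, 2L))
            seg <- ij[1L]:ij[2L]
            df[seg, ] <- df[rev(seg), ]
            df$strand[seg] <- ifelse(df$strand[seg] == "+", "-",
                                     ifelse(df$strand[seg] == "-", "+", "unknown"))
          }
          df$rank <- seq_len(nr) - 1L
          df
        }) %>%
        ungroup()
    }
    validate_gene_order(g)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
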