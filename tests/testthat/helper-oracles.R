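# Independent oracles and small fixture builders used across the suite.

# --- genetic-code oracle (independent loops over seqinr's code) -------------

oracle_bases <- c("A", "C", "G", "T")

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

# Synonymous-site fraction of one codon by direct enumeration of all nine
# single-base mutations (stop targets count as nonsynonymous).
oracle_syn_sites <- function(codon) {
  aa0 <- oracle_translate(codon)
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in oracle_bases) {
      if (b == ch[pos]) next
      mut <- ch
      mut[pos] <- b
      if (oracle_translate(paste(mut, collapse = "")) == aa0) s <- s + 1 / 3
    }
  }
  s
}

# Pathway-averaged (sd, nd) between two codons by recursive path enumeration,
# skipping paths through stops. Returns c(NA, NA) when no path is stop-free.
oracle_pair_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  walk <- function(cur, remaining) {
    if (length(remaining) == 0L) {
      return(list(c(0, 0)))
    }
    out <- list()
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- b[p]
      aa_new <- oracle_translate(paste(nxt, collapse = ""))
      if (aa_new == "*") next
      syn <- aa_new == oracle_translate(paste(cur, collapse = ""))
      for (tailpath in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1L]] <- tailpath + c(syn, !syn)
      }
    }
    out
  }
  paths <- walk(a, which(a != b))
  if (length(paths) == 0L) {
    return(c(NA_real_, NA_real_))
  }
  Reduce(`+`, paths) / length(paths)
}

all_sense_codons <- function() {
  cods <- as.vector(outer(outer(oracle_bases, oracle_bases, paste0),
                          oracle_bases, paste0))
  cods[vapply(cods, oracle_translate, character(1)) != "*"]
}

# --- chaining oracle: exhaustive max-cardinality collinear chain ------------

# anchors: data frame with rank_a, rank_b (one chromosome pair). Returns the
# size of the largest subset that forms a valid chain in either orientation.
oracle_best_chain_size <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0L
  chain_ok <- function(idx, rb_use) {
    o <- order(ra[idx])
    ra_s <- ra[idx][o]
    rb_s <- rb_use[idx][o]
    all(diff(ra_s) > 0) && all(diff(rb_s) > 0) &&
      all(diff(ra_s) <= max_gap + 1) && all(diff(rb_s) <= max_gap + 1)
  }
  for (code in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
    if (length(idx) <= best) next
    if (chain_ok(idx, rb) || chain_ok(idx, -rb)) best <- length(idx)
  }
  best
}

# --- Fisher oracle: one-sided hypergeometric tail ---------------------------

oracle_fisher_greater <- function(x11, x12, x21, x22) {
  m <- x11 + x21 # column 1 total ("duplicated")
  n <- x12 + x22
  k <- x11 + x12 # row 1 total (observed)
  sum(stats::dhyper(x11:min(m, k), m, n, k))
}

# --- fixtures ---------------------------------------------------------------

toy_species_tree <- function() {
  read_newick("((A:10,B:10):10,(C:15,D:15):5);")
}

toy_ladder <- function() ladder_spec(paste0("t", 1:5), "OUT")

toy_ladder_tree <- function() {
  ladder_species_tree(toy_ladder(), c(77.6, 117.3, 125, 150, 190))
}

make_ks_table <- function(ks, node_id = NA_character_) {
  tibble::tibble(
    gene_a = sprintf("ga%05d", seq_along(ks)),
    gene_b = sprintf("gb%05d", seq_along(ks)),
    ks = ks,
    node_id = node_id
  )
}

# star gene tree: n tips, all pairs coalescing at `age`
star_gene_tree <- function(n, age, species = "S") {
  labs <- sprintf("%s|g%d:%.10g", species, seq_len(n), age)
  read_newick(paste0("(", paste(labs, collapse = ","), ");"),
              rooted_required = FALSE)
}
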