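# Codon machinery for the Nei-Gojobori (1986) estimator. The genetic code
# comes from seqinr; synonymous site fractions and pathway-averaged
# difference counts are computed per codon (pair) and memoised.

ng86_env <- new.env(parent = emptyenv())

ng86_code <- function() {
  if (is.null(ng86_env$aa)) {
    bases <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    aa <- vapply(codons, function(cd) {
      seqinr::translate(strsplit(cd, "")[[1]])
    }, character(1))
    ng86_env$aa <- setNames(aa, codons)
    ng86_env$bases <- bases
    ng86_env$site_cache <- new.env(parent = emptyenv())
    ng86_env$pair_cache <- new.env(parent = emptyenv())
  }
  ng86_env
}

# Fraction of synonymous sites in one codon: per position, the share of the
# three single-base changes that preserve the amino acid. Changes to stop
# codons count as nonsynonymous.
ng86_syn_sites <- function(codon) {
  env <- ng86_code()
  hit <- env$site_cache[[codon]]
  if (!is.null(hit)) return(hit)
  aa0 <- env$aa[[codon]]
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(env$bases, chars[pos])) {
      mut <- chars
      mut[pos] <- b
      if (env$aa[[paste(mut, collapse = "")]] == aa0) s <- s + 1 / 3
    }
  }
  env$site_cache[[codon]] <- s
  s
}

# Pathway-averaged synonymous / nonsynonymous difference counts between two
# codons. Paths passing through a stop codon are excluded; NA when every
# path does.
ng86_pair_diffs <- function(c1, c2) {
  env <- ng86_code()
  key <- paste0(c1, c2)
  hit <- env$pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  d <- length(pos)
  out <- if (d == 0L) {
    c(sd = 0, nd = 0)
  } else {
    perms <- list(
      list(1L), list(c(1L, 2L), c(2L, 1L)),
      list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
    )[[d]]
    sd_tot <- 0
    nd_tot <- 0
    n_valid <- 0L
    for (ord in perms) {
      cur <- a
      aa_cur <- env$aa[[c1]]
      sd_p <- 0
      nd_p <- 0
      ok <- TRUE
      for (p in pos[ord]) {
        cur[p] <- b[p]
        aa_new <- env$aa[[paste(cur, collapse = "")]]
        if (aa_new == "*") {
          ok <- FALSE
          break
        }
        if (aa_new == aa_cur) sd_p <- sd_p + 1 else nd_p <- nd_p + 1
        aa_cur <- aa_new
      }
      if (ok) {
        sd_tot <- sd_tot + sd_p
        nd_tot <- nd_tot + nd_p
        n_valid <- n_valid + 1L
      }
    }
    if (n_valid == 0L) {
      c(sd = NA_real_, nd = NA_real_)
    } else {
      c(sd = sd_tot / n_valid, nd = nd_tot / n_valid)
    }
  }
  env$pair_cache[[key]] <- out
  out
}

#' Read aligned coding sequences from a FASTA file
#'
#' Convenience reader for paired in-frame coding sequences destined for
#' [ng86_ks()]; wraps [seqinr::read.fasta()].
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A named character vector of uppercase sequences.
#' @export
read_codon_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- toupper(vapply(seqs, as.character, character(1)))
  setNames(out, names(seqs))
}

#' Synonymous and nonsynonymous divergence by Nei-Gojobori (1986) counting
#'
#' Counts synonymous site fractions per codon (averaged over both sequences),
#' averages synonymous/nonsynonymous difference counts over all mutational
#' pathways that avoid stop codons, and applies the Jukes-Cantor correction
#' `ks = -(3/4) * log(1 - (4/3) * ps)`. Codons containing gaps or ambiguous
#' bases are dropped pairwise. The estimator is symmetric in its arguments.
#' Note it systematically underestimates divergence relative to
#' codon-model maximum likelihood at high Ks.
#'
#' @param seq_a,seq_b In-frame coding sequences (single strings, equal length,
#'   a multiple of 3, no stop codons).
#' @return A one-row tibble with `ks`, `ka`, `syn_sites`, `nonsyn_sites`.
#' @export
#' @examples
#' ng86_ks("TTTGGGAAA", "TTCGGGAAA")
ng86_ks <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  seq_a <- toupper(gsub("U", "T", seq_a, fixed = TRUE))
  seq_b <- toupper(gsub("U", "T", seq_b, fixed = TRUE))
  if (nchar(seq_a) != nchar(seq_b)) abort("sequences differ in length")
  if (nchar(seq_a) %% 3 != 0) abort("sequence length is not a multiple of 3")
  env <- ng86_code()
  split_codons <- function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]
  cb <- cb[clean]
  if (length(ca) == 0L) abort("no ungapped codons left to compare")
  if (any(env$aa[ca] == "*") || any(env$aa[cb] == "*")) {
    abort("stop codon encountered in coding sequence")
  }
  s_a <- sum(vapply(ca, ng86_syn_sites, numeric(1)))
  s_b <- sum(vapply(cb, ng86_syn_sites, numeric(1)))
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i) ng86_pair_diffs(ca[i], cb[i]),
                  numeric(2))
  if (anyNA(diffs)) {
    drop <- is.na(diffs[1L, ])
    warn(sprintf("%d codon pair(s) dropped: all mutational paths hit a stop",
                 sum(drop)))
    diffs <- diffs[, !drop, drop = FALSE]
    if (ncol(diffs) == 0L) abort("no codon pairs with a stop-free path")
  }
  Sd <- sum(diffs[1L, ])
  Nd <- sum(diffs[2L, ])
  ps <- Sd / S
  pn <- Nd / N
  if (ps >= 3 / 4) {
    abort(sprintf("synonymous sites saturated (ps = %.3f >= 0.75)", ps))
  }
  ka <- if (pn >= 3 / 4) {
    warn("nonsynonymous sites saturated; ka set to NA")
    NA_real_
  } else {
    -3 / 4 * log(1 - 4 / 3 * pn)
  }
  tibble(
    ks = -3 / 4 * log(1 - 4 / 3 * ps),
    ka = ka,
    syn_sites = S,
    nonsyn_sites = N
  )
}
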