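#' Median ortholog divergence between two genomes
#'
#' Selects cross-genome ortholog pairs by reciprocal best pairing (minimum Ks
#' as the similarity proxy: a pair is kept when each gene is the other's
#' lowest-Ks cross-genome partner) and summarises their divergence as the
#' median Ks with a bootstrap percentile confidence interval.
#'
#' @param genome_a,genome_b Gene-order tibbles (only `gene_id` is used).
#' @param ks_table A Ks tibble containing cross-genome pairs.
#' @param n_boot Bootstrap replicates for the CI (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return A one-row tibble with `median`, `ci_lo`, `ci_hi`, `n_pairs`.
#' @export
ortholog_divergence_ks <- function(genome_a, genome_b, ks_table,
                                   n_boot = 1000L, conf = 0.95, seed = NULL) {
  tab <- validate_ks_table(ks_table)
  ids_a <- unique(validate_gene_order(genome_a)$gene_id)
  ids_b <- unique(validate_gene_order(genome_b)$gene_id)
  a_in_a <- tab$gene_a %in% ids_a
  a_in_b <- tab$gene_a %in% ids_b
  b_in_a <- tab$gene_b %in% ids_a
  b_in_b <- tab$gene_b %in% ids_b
  cross <- (a_in_a & b_in_b) | (a_in_b & b_in_a)
  tab <- tab[cross, , drop = FALSE]
  if (nrow(tab) == 0L) abort("no cross-genome gene pairs in the Ks table")
  # orient pairs as (A gene, B gene)
  flip <- tab$gene_a %in% ids_b
  ga <- ifelse(flip, tab$gene_b, tab$gene_a)
  gb <- ifelse(flip, tab$gene_a, tab$gene_b)
  pairs <- tibble(ga = ga, gb = gb, ks = tab$ks) %>%
    arrange(.data$ks, .data$ga, .data$gb)
  best_a <- pairs[!duplicated(pairs$ga), ]
  best_b <- pairs[!duplicated(pairs$gb), ]
  rbh <- dplyr::inner_join(best_a, best_b, by = c("ga", "gb", "ks"))
  if (nrow(rbh) == 0L) abort("no reciprocal best pairs found")
  run <- function() {
    med <- median(rbh$ks)
    reps <- vapply(seq_len(n_boot), function(i) {
      median(sample(rbh$ks, nrow(rbh), replace = TRUE))
    }, numeric(1))
    qs <- quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    tibble(median = med, ci_lo = qs[1], ci_hi = qs[2], n_pairs = nrow(rbh))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Place a Ks peak relative to an ortholog divergence
#'
#' A duplication peak whose confidence interval lies wholly above the
#' ortholog-divergence interval is older than the speciation and therefore
#' called `shared-ancestral`; wholly below is `lineage-specific`; overlapping
#' intervals are `ambiguous`.
#'
#' @param fit A `ks_mixture` object (see [fit_ks_mixture()]).
#' @param component Which mixture component is the designated WGD peak.
#' @param ortholog A one-row tibble from [ortholog_divergence_ks()] (columns
#'   `median`, `ci_lo`, `ci_hi`).
#' @return A one-row tibble with the call and both medians/intervals.
#' @export
classify_placement <- function(fit, component, ortholog) {
  stopifnot(inherits(fit, "ks_mixture"),
            component >= 1, component <= fit$k,
            all(c("median", "ci_lo", "ci_hi") %in% names(ortholog)))
  pk <- fit$components[component, ]
  call <- if (pk$median_lo > ortholog$ci_hi) {
    "shared-ancestral"
  } else if (pk$median_hi < ortholog$ci_lo) {
    "lineage-specific"
  } else {
    "ambiguous"
  }
  tibble(
    call = call,
    peak_median = pk$median, peak_lo = pk$median_lo, peak_hi = pk$median_hi,
    ortholog_median = ortholog$median,
    ortholog_lo = ortholog$ci_lo, ortholog_hi = ortholog$ci_hi
  )
}
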