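# Closed-form assembly/report arithmetic: LTR ages, heterozygosity spacing,
# fractions, gene density, flow-cytometry genome-size conversion.

#' LTR insertion time from terminal-repeat divergence
#'
#' `t = K / (2 r)`, where `K` is the nucleotide divergence between the two
#' terminal repeats of an intact element and `r` the substitution rate per
#' site per year (default 1e-8).
#'
#' @param K Substitutions per site between the LTR pair (>= 0).
#' @param r Substitution rate per site per year (> 0).
#' @return Insertion time in years.
#' @export
#' @examples
#' ltr_insertion_time(0.03) # 1.5 Myr
ltr_insertion_time <- function(K, r = 1e-8) {
  stopifnot(r > 0)
  if (any(K < 0)) abort("K must be non-negative")
  K / (2 * r)
}

#' Heterozygous-site spacing and percentage
#'
#' @param het_sites Number of heterozygous sites (>= 0).
#' @param length_bp Sequence length in bp (> 0).
#' @return A one-row tibble: `bp_per_site` (rounded to integer; `NA` when
#'   there are no sites) and `pct` (2 decimals).
#' @export
het_spacing <- function(het_sites, length_bp) {
  stopifnot(length_bp > 0, het_sites >= 0)
  tibble(
    bp_per_site = if (het_sites == 0) NA_real_ else round(length_bp / het_sites),
    pct = round(100 * het_sites / length_bp, 2)
  )
}

#' Percentage of a part in a whole
#'
#' @param part,whole Non-negative scalars with `part <= whole`, `whole > 0`.
#' @param digits Rounding digits (default 1).
#' @return Percentage, rounded.
#' @export
fraction_pct <- function(part, whole, digits = 1) {
  stopifnot(whole > 0, part >= 0)
  if (part > whole) abort("part exceeds whole")
  round(100 * part / whole, digits)
}

#' Average gene density in kb per gene
#'
#' @param total_len_bp Assembly length in bp.
#' @param n_genes Number of genes (> 0).
#' @return kb per gene, rounded to 1 decimal.
#' @export
gene_density_kb <- function(total_len_bp, n_genes) {
  stopifnot(n_genes > 0)
  round(total_len_bp / n_genes / 1000, 1)
}

#' Convert a 2C flow-cytometry DNA amount to a 1C genome size
#'
#' Uses 1 pg = 0.978 Gb.
#'
#' @param dna_pg_2c DNA amount in picograms per 2C nucleus (> 0).
#' @return Genome size in Gb per 1C, rounded to 2 decimals.
#' @export
#' @examples
#' pg_to_gb(2.36) # 1.15 Gb
pg_to_gb <- function(dna_pg_2c) {
  if (any(dna_pg_2c <= 0)) abort("DNA amount must be positive")
  round(dna_pg_2c / 2 * 0.978, 2)
}

#' Summarise an assembly report
#'
#' Convenience wrapper computing the standard derived quantities from raw
#' assembly numbers.
#'
#' @param total_len_bp,anchored_len_bp Assembly and chromosome-anchored
#'   lengths in bp.
#' @param n_genes,n_anchored_genes Gene counts (total / anchored).
#' @param repeat_len_bp Repeat-masked length in bp.
#' @param het_sites Heterozygous site count over `anchored_len_bp`.
#' @return A one-row tibble of derived percentages, spacing and density.
#' @export
assembly_summary <- function(total_len_bp, anchored_len_bp, n_genes,
                             n_anchored_genes, repeat_len_bp, het_sites) {
  stopifnot(anchored_len_bp <= total_len_bp, n_anchored_genes <= n_genes,
            repeat_len_bp <= total_len_bp)
  het <- het_spacing(het_sites, anchored_len_bp)
  tibble(
    anchored_pct = fraction_pct(anchored_len_bp, total_len_bp),
    repeat_pct = fraction_pct(repeat_len_bp, total_len_bp),
    anchored_gene_pct = fraction_pct(n_anchored_genes, n_genes),
    gene_density_kb = gene_density_kb(total_len_bp, n_genes),
    het_bp_per_site = het$bp_per_site,
    het_pct = het$pct
  )
}
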