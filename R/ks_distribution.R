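#' Build a node-weighted duplicate-age (Ks) distribution
#'
#' Each duplication node contributes total weight 1, split equally among its
#' descendant gene pairs, so large subfamilies do not dominate the age
#' distribution. Values outside the window are dropped before weights are
#' computed. Rows without a `node_id` tag are treated as their own node
#' (weight 1).
#'
#' @param ks_table A Ks tibble (see [validate_ks_table()]).
#' @param window Numeric `(low, high)` window on the Ks axis; the default
#'   `[0.01, 3]` excludes near-zero allelic/tandem noise and saturated values
#'   while covering all peaks of interest.
#' @param node_weighted Set `FALSE` for a raw per-pair histogram (all
#'   weights 1) regardless of node tags.
#' @return A tibble of class `ks_distribution` with columns
#'   `ks`, `weight`, `node_id` and attribute `window`.
#' @export
node_weighted_distribution <- function(ks_table, window = c(0.01, 3),
                                       node_weighted = TRUE) {
  stopifnot(length(window) == 2L, window[1] >= 0, window[2] > window[1])
  tab <- validate_ks_table(ks_table)
  tab <- filter(tab, .data$ks >= window[1], .data$ks <= window[2])
  if (nrow(tab) == 0L) abort("no Ks values left inside the window")
  untagged <- is.na(tab$node_id)
  tab$node_id[untagged] <- paste0("pair", which(untagged))
  out <- tab %>%
    group_by(.data$node_id) %>%
    mutate(weight = if (node_weighted) 1 / n() else 1) %>%
    ungroup() %>%
    select("ks", "weight", "node_id") %>%
    arrange(.data$ks)
  structure(out, class = c("ks_distribution", class(out)), window = window)
}
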