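# ggplot2 views of the main result types.

#' @rdname fit_ks_mixture
#' @param object A `ks_mixture` object.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ks_mixture <- function(object, bins = 60, ...) {
  dat <- object$data
  comps <- object$components
  window <- attr(dat, "window") %||% range(dat$ks)
  grid <- tibble(ks = seq(max(min(dat$ks), 1e-4), max(dat$ks), length.out = 400))
  dens <- purrr::map_dfr(seq_len(nrow(comps)), function(j) {
    tibble(
      ks = grid$ks, component = factor(j),
      density = comps$weight[j] *
        stats::dlnorm(grid$ks, comps$meanlog[j], comps$sdlog[j])
    )
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ks)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density), weight = .data$weight),
      bins = bins, fill = "grey80", colour = "grey50", linewidth = 0.2
    ) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(y = .data$density, colour = .data$component),
      linewidth = 0.8
    ) +
    ggplot2::geom_vline(xintercept = comps$median, linetype = 2,
                        colour = "grey30") +
    ggplot2::labs(x = "Ks (synonymous substitutions/site)",
                  y = "weighted density",
                  title = sprintf("Ks mixture (k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot syntenic depth histograms for a genome pair
#'
#' @param profiles Output of [depth_profiles()].
#' @param names_ab Labels for the two genomes.
#' @return A ggplot object.
#' @export
plot_depth_histogram <- function(profiles, names_ab = c("A", "B")) {
  dat <- bind_rows(
    mutate(profiles$a, genome = names_ab[1]),
    mutate(profiles$b, genome = names_ab[2])
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$depth))) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::facet_wrap(~genome, scales = "free_y") +
    ggplot2::labs(x = "syntenic depth (covering blocks)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Synteny dot plot of anchors, coloured by block membership
#'
#' @param blocks Block tibble from [chain_anchors()].
#' @return A ggplot object.
#' @export
plot_synteny_dotplot <- function(blocks) {
  dat <- blocks %>%
    select("block_id", "anchors") %>%
    tidyr::unnest("anchors")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank_a, y = .data$rank_b,
                                    colour = factor(.data$block_id))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(chrom_b ~ chrom_a, scales = "free", space = "free") +
    ggplot2::labs(x = "gene rank (genome A)", y = "gene rank (genome B)") +
    ggplot2::theme_minimal()
}

#' Plot per-node shared-duplication percentages for a MAPS analysis
#'
#' @param observed A `maps_result` tibble.
#' @param null Optional null-simulation `maps_result`.
#' @param ci Optional resampling intervals from [resample_percentages()].
#' @return A ggplot object.
#' @export
plot_maps <- function(observed, null = NULL, ci = NULL) {
  dat <- mutate(as_tibble(observed), which = "observed")
  if (!is.null(null)) {
    dat <- bind_rows(dat, mutate(as_tibble(null), which = "null"))
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$node, y = .data$pct,
                                         colour = .data$which,
                                         group = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "species-tree node", y = "% subtrees with shared duplication") +
    ggplot2::theme_minimal()
  if (!is.null(ci)) {
    p <- p + ggplot2::geom_errorbar(
      data = mutate(ci, pct = NA_real_, which = "observed"),
      ggplot2::aes(x = .data$node, ymin = .data$pct_lo, ymax = .data$pct_hi),
      inherit.aes = FALSE, width = 0.2, colour = "grey40"
    )
  }
  p
}
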