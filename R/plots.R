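# Figure-style visualisations of event profiles and length distributions.

#' Strip-plot of per-event marker profiles
#'
#' Draws each event as a pair of horizontal strips (one per product) with
#' markers coloured by call: recipient allele, donor allele, heteroduplex
#' (both alleles present), or no-call. The anchor (break or inferred
#' crossover point) is drawn as a vertical line.
#'
#' @param events Event tibble with `event_id`, `genotype_trunc`,
#'   `genotype_full` (and optionally `anchor`).
#' @param map A `marker_map`.
#' @param anchor Single anchor position, vector, or `NULL` to use the
#'   events' `anchor` column (if absent, no line is drawn).
#' @return A ggplot object.
#' @export
plot_event_profiles <- function(events, map, anchor = NULL) {
  m <- as_tibble(map)
  anchors <- anchor %||% events[["anchor"]]
  long <- purrr::map(seq_len(nrow(events)), function(i) {
    tibble(
      event_id = as.character(events$event_id[i]),
      pos = rep(m$pos_recipient, 2),
      product = rep(c("truncated product", "full-length product"), each = nrow(m)),
      call = c(events$genotype_trunc[[i]], events$genotype_full[[i]])
    )
  }) |> list_rbind()
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$pos, y = .data$event_id, fill = .data$call
  )) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::facet_wrap(~ .data$product, ncol = 2) +
    ggplot2::scale_fill_manual(values = c(
      R = "white", D = "black", H = "grey55", N = "tomato"
    ), name = "call") +
    ggplot2::labs(x = "position (bp, recipient frame)", y = "event") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (!is.null(anchors)) {
    p <- p + ggplot2::geom_vline(
      xintercept = unique(anchors[!is.na(anchors)]),
      colour = "red", linewidth = 0.3
    )
  }
  p
}

#' Cumulative hetDNA length distribution per side
#'
#' Fraction of events whose hetDNA extends at least a given distance from
#' the anchor, per side — the standard way tract-length distributions are
#' compared between event cohorts.
#'
#' @param length_table Per-event table from [hetdna_length_table()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(length_table) {
  lt <- filter(length_table, .data$has_hetdna)
  long <- tidyr::pivot_longer(
    select(lt, "event_id", "upstream_bp", "downstream_bp"),
    cols = c("upstream_bp", "downstream_bp"),
    names_to = "side", values_to = "length_bp"
  ) |>
    filter(.data$length_bp > 0) |>
    mutate(side = sub("_bp$", "", .data$side))
  ggplot2::ggplot(long, ggplot2::aes(.data$length_bp, colour = .data$side)) +
    ggplot2::stat_ecdf(ggplot2::aes(y = 1 - ggplot2::after_stat(.data$ecdf))) +
    ggplot2::labs(
      x = "hetDNA length (bp)",
      y = "fraction of events with hetDNA extending this far"
    ) +
    ggplot2::theme_minimal()
}
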