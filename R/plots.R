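#' @import ggplot2
NULL

species_distance_order <- function(species_tree, reference) {
  d <- ape::cophenetic.phylo(species_tree)[reference, ]
  names(sort(d))
}

#' Plot per-species domain loss / gain / divergence
#'
#' Bars of the overall percentages per species, ordered by phylogenetic
#' distance from the reference when a tree is supplied.
#'
#' @param summary [summarize_divergence()] output.
#' @param species_tree Optional `phylo` for distance ordering.
#' @param reference Reference species label (with `species_tree`).
#' @return A ggplot.
#' @export
plot_divergence_summary <- function(summary, species_tree = NULL,
                                    reference = NULL) {
  df <- filter(summary, .data$stratum_type == "overall", !is.na(.data$value))
  if (!is.null(species_tree) && !is.null(reference)) {
    ord <- species_distance_order(species_tree, reference)
    df$species <- factor(df$species, levels = ord)
  }
  ggplot(df, aes(x = .data$species, y = .data$value)) +
    geom_col(fill = "grey25") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = "% of domains") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Violin plot of normalized evolutionary-rate ranks by residue class
#'
#' @param rate_ranks [rate_rank_analysis()] output.
#' @return A ggplot.
#' @export
plot_rate_ranks <- function(rate_ranks) {
  ggplot(rate_ranks$values,
         aes(x = .data$class, y = .data$normalized_rank)) +
    geom_violin(fill = "steelblue", alpha = 0.6, scale = "area") +
    stat_summary(fun = stats::median, geom = "crossbar", width = 0.5,
                 linewidth = 0.3) +
    facet_wrap(~species) +
    labs(x = NULL, y = "normalized rate rank") +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Folded site-frequency spectrum plot per residue class
#'
#' @param sfs [folded_sfs()] output.
#' @param species Optional single species to display.
#' @return A ggplot.
#' @export
plot_sfs <- function(sfs, species = NULL) {
  df <- if (is.null(species)) sfs else
    filter(sfs, .data$species == !!species)
  ggplot(df, aes(x = .data$bin, y = .data$proportion, fill = .data$class)) +
    geom_col(position = "dodge") +
    facet_wrap(~species) +
    labs(x = "minor-allele count", y = "proportion of polymorphic sites") +
    theme_bw()
}

#' Sequence-logo style probability plot of a PWM
#'
#' Stacked per-position base probabilities (height-proportional bars).
#'
#' @param object A `zf_pwm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zf_pwm <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(position = rep(seq_len(ncol(m)), each = 4),
               base = rep(DNA_BASES, ncol(m)),
               probability = as.numeric(m))
  ggplot(df, aes(x = .data$position, y = .data$probability,
                 fill = .data$base)) +
    geom_col(colour = "grey30", linewidth = 0.2) +
    scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                 G = "#F7B32B", T = "#D62839")) +
    scale_x_continuous(breaks = seq_len(ncol(m))) +
    labs(y = "probability") +
    theme_bw()
}

#' Conserved-versus-diverged binding conservation plot
#'
#' Per-species conservation fractions with class medians, the analogue of a
#' binding-landscape turnover figure.
#'
#' @param comparison [compare_conserved_vs_diverged()] output.
#' @return A ggplot.
#' @export
plot_landscape_comparison <- function(comparison) {
  ggplot(comparison$values,
         aes(x = .data$species, y = .data$fraction_promoters_conserved,
             colour = .data$label)) +
    geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    geom_point(data = comparison$medians,
               aes(y = .data$median_fraction), colour = "black", size = 2,
               shape = 18) +
    scale_colour_manual(values = c(conserved_all = "#2166AC",
                                   diverged_here = "#D6604D")) +
    labs(x = NULL, y = "fraction of bound promoters conserved",
         colour = NULL) +
    theme_bw() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
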