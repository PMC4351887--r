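#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a class-comparison result
#'
#' One row per (species, residue class) with counts and proportions.
#'
#' @param x A `zf_class_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.zf_class_comparison <- function(x, ...) {
  mutate(x$classes, analysis = x$analysis, .before = 1)
}

#' Per-species test summary of a class comparison
#'
#' @param x A `zf_class_comparison`.
#' @param ... Unused.
#' @return One row per species with the BINDING-vs-BACKGROUND test.
#' @export
glance.zf_class_comparison <- function(x, ...) {
  mutate(x$tests, analysis = x$analysis, .before = 1)
}

#' Tidy a reconciliation
#'
#' One row per gene-tree internal node with its species image and
#' duplication flag.
#'
#' @param x A `zf_reconciliation`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.zf_reconciliation <- function(x, ...) {
  n <- length(x$gene_tree$tip.label)
  nnode <- n + x$gene_tree$Nnode
  sp_labels <- c(x$species_tree$tip.label,
                 sprintf("node%d", seq_len(x$species_tree$Nnode)))
  tibble(node = seq_len(nnode),
         is_leaf = seq_len(nnode) <= n,
         label = c(x$gene_tree$tip.label, rep(NA_character_, x$gene_tree$Nnode)),
         species_image = sp_labels[x$image],
         is_duplication = x$is_duplication)
}

#' Event totals of a reconciliation
#' @param x A `zf_reconciliation`.
#' @param ... Unused.
#' @return A one-row tibble with `duplications` and `losses`.
#' @export
glance.zf_reconciliation <- function(x, ...) {
  tibble(duplications = x$duplications, losses = x$losses,
         n_leaves = length(x$gene_tree$tip.label))
}

#' Headline quantities of a pipeline run
#'
#' @param x A `zf_pipeline`.
#' @param ... Unused.
#' @return One-row tibble: domain counts, orthogroup counts, divergence
#'   ranges, confident-prediction fraction, and landscape test p-value where
#'   the corresponding stages ran.
#' @export
glance.zf_pipeline <- function(x, ...) {
  out <- tibble(seed = x$manifest$seed,
                n_domains = nrow(x$domains),
                n_genes_with_domains = length(unique(x$domains$gene_id)))
  if (!is.null(x$orthogroups)) {
    out$n_orthogroups <- length(unique(x$orthogroups$group_id))
  }
  if (!is.null(x$divergence_summary)) {
    overall <- x$divergence_summary %>%
      filter(.data$stratum_type == "overall")
    dv <- filter(overall, .data$metric == "pct_domains_diverged")
    out$pct_diverged_min <- min(dv$value, na.rm = TRUE)
    out$pct_diverged_max <- max(dv$value, na.rm = TRUE)
  }
  if (!is.null(x$specificity)) {
    out$fraction_confident <- mean(x$specificity$confident)
  }
  if (!is.null(x$landscape_comparison) &&
        !inherits(x$landscape_comparison, "try-error")) {
    out$landscape_p <- x$landscape_comparison$test$p_value
  }
  out
}
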