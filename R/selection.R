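new_class_comparison <- function(classes, tests, analysis) {
  structure(list(classes = classes, tests = tests, analysis = analysis),
            class = "zf_class_comparison")
}

#' @export
print.zf_class_comparison <- function(x, ...) {
  cat(sprintf("<zf_class_comparison> %s: %d species\n", x$analysis,
              length(unique(x$classes$species))))
  print(x$tests)
  invisible(x)
}

binding_vs_background <- function(classes, analysis,
                                  alternative = "two.sided") {
  tests <- classes %>%
    tidyr::pivot_wider(id_cols = "species", names_from = "class",
                       values_from = c("numerator", "denominator")) %>%
    split(seq_len(length(unique(classes$species)))) %>%
    map(function(r) {
      getcol <- function(nm) if (nm %in% names(r)) r[[nm]] else NA_integer_
      k <- getcol("numerator_BINDING")
      n <- getcol("denominator_BINDING")
      kb <- getcol("numerator_BACKGROUND")
      nb <- getcol("denominator_BACKGROUND")
      p0 <- if (!is.na(kb) && !is.na(nb) && nb > 0) kb / nb else NA_real_
      if (is.na(k) || is.na(n) || n == 0 || is.na(p0) || p0 <= 0 || p0 >= 1) {
        return(tibble(species = r$species, statistic = NA_real_,
                      p_value = NA_real_, n1 = n, n2 = nb,
                      null_proportion = p0, sidedness = alternative,
                      undefined = TRUE))
      }
      bt <- binomial_compare(k, n, p0, alternative)
      tibble(species = r$species, statistic = bt$statistic,
             p_value = bt$p_value, n1 = n, n2 = nb, null_proportion = p0,
             sidedness = alternative, undefined = FALSE)
    }) %>% list_rbind()
  new_class_comparison(classes, tests, analysis)
}

#' Clade support of divergent residues
#'
#' A divergent site in species A (reference residue differing from A's) is
#' supported when A's partner species carries the identical residue at the
#' same reference column. Sites whose partner column is gapped, or whose
#' partner lacks the ortholog, are excluded from the denominator. Support
#' proportions are computed per residue class and species, and the BINDING
#' class is compared to BACKGROUND with an exact binomial test whose null
#' proportion is the background support proportion.
#'
#' @param sites Divergent-site tibble (pooled [call_divergent_sites()] output).
#' @param alignments Named list of [align_orthologs()] results keyed by
#'   `group_id`.
#' @param pairing Tibble `species_a`, `species_b` of disjoint sister pairs.
#' @param alternative Sidedness of the binomial comparison.
#' @return A `zf_class_comparison`; `$classes` has per-class counts,
#'   `$tests` the per-species binomial results.
#' @export
clade_support <- function(sites, alignments, pairing,
                          alternative = "two.sided") {
  stopifnot_cols(pairing, c("species_a", "species_b"), "pairing")
  partner <- c(setNames(pairing$species_b, pairing$species_a),
               setNames(pairing$species_a, pairing$species_b))
  eligible <- sites %>% filter(.data$species %in% names(partner))
  skipped <- setdiff(unique(sites$species), names(partner))
  if (length(skipped) > 0) {
    rlang::inform(sprintf("species without a partner skipped: %s",
                          paste(skipped, collapse = ", ")))
  }
  # one joint lookup table of all alignment columns, then a vectorized join
  maps_all <- map(alignments, function(a)
    mutate(a$map, group_id = a$group_id)) %>%
    list_rbind() %>%
    select("group_id", "species", "ref_index",
           partner_residue = "sp_residue")
  rows <- eligible %>%
    mutate(partner_species = unname(partner[.data$species])) %>%
    inner_join(maps_all,
               by = c("group_id", partner_species = "species", "ref_index")) %>%
    mutate(supported = .data$partner_residue == .data$sp_residue)
  classes <- rows %>%
    group_by(.data$species, .data$class) %>%
    summarise(numerator = sum(.data$supported), denominator = n(),
              .groups = "drop") %>%
    mutate(proportion = .data$numerator / .data$denominator)
  binding_vs_background(classes, "clade_support", alternative)
}

#' Evolutionary-rate rank analysis of divergent residues
#'
#' Within each sequence (orthogroup x species), divergent sites are ranked
#' ascending by their per-site evolutionary rate (average ranks for ties) and
#' normalized to `[0, 1]` as `(rank - 1) / (m - 1)` (`0.5` for a single
#' site). Normalized ranks are pooled per species and residue class, and
#' BINDING is compared to BACKGROUND with a two-sided Wilcoxon rank-sum test.
#'
#' @param sites Divergent-site tibble.
#' @param rates SiteRateTable tibble `group_id`, `ref_index`, `rate`, and
#'   optionally `complete` (column has data for all species).
#' @param complete_columns_only Restrict to complete columns (default TRUE).
#' @return List with `values` (per-site normalized ranks) and `tests`
#'   (per-species Wilcoxon results).
#' @export
rate_rank_analysis <- function(sites, rates, complete_columns_only = TRUE) {
  stopifnot_cols(rates, c("group_id", "ref_index", "rate"), "rates")
  if (complete_columns_only && "complete" %in% names(rates)) {
    rates <- filter(rates, .data$complete)
  }
  values <- sites %>%
    inner_join(rates, by = c("group_id", "ref_index")) %>%
    group_by(.data$group_id, .data$species) %>%
    mutate(normalized_rank = normalize_ranks(.data$rate)) %>%
    ungroup()
  tests <- values %>%
    split(values$species) %>%
    map(function(v) {
      a <- v$normalized_rank[v$class == "BINDING"]
      b <- v$normalized_rank[v$class == "BACKGROUND"]
      if (length(a) == 0 || length(b) == 0) {
        return(tibble(species = v$species[1], statistic = NA_real_,
                      p_value = NA_real_, n1 = length(a), n2 = length(b),
                      sidedness = "two.sided", undefined = TRUE))
      }
      wt <- wilcoxon_rank_sum(a, b)
      tibble(species = v$species[1], statistic = wt$statistic,
             p_value = wt$p_value, n1 = wt$n1, n2 = wt$n2,
             sidedness = wt$sidedness, undefined = FALSE)
    }) %>% list_rbind()
  list(values = values, tests = tests)
}

#' Fixation test: divergence absent from population polymorphism
#'
#' For each divergent site, asks whether the same reference position
#' segregates in the reference-species population. Per class, the proportion
#' of divergent sites absent from the polymorphism table (candidate rapid
#' fixations) is computed, and BINDING is compared to BACKGROUND with an
#' exact binomial test (null = background proportion). All divergent sites
#' are eligible regardless of alignment to other species.
#'
#' @param sites Divergent-site tibble.
#' @param polymorphisms Tibble `gene_id`, `ref_index`, `minor_count`,
#'   `sample_size` keyed by reference protein coordinates.
#' @param alternative Sidedness of the binomial comparison.
#' @return A `zf_class_comparison`.
#' @export
fixation_test <- function(sites, polymorphisms, alternative = "two.sided") {
  stopifnot_cols(polymorphisms, c("gene_id", "ref_index"), "polymorphisms")
  poly_key <- paste(polymorphisms$gene_id, polymorphisms$ref_index)
  classes <- sites %>%
    mutate(non_polymorphic = !(paste(.data$ref_gene, .data$ref_index) %in%
                                 poly_key)) %>%
    group_by(.data$species, .data$class) %>%
    summarise(numerator = sum(.data$non_polymorphic), denominator = n(),
              .groups = "drop") %>%
    mutate(proportion = .data$numerator / .data$denominator)
  binding_vs_background(classes, "fixation", alternative)
}

#' Folded site-frequency spectrum of divergent polymorphic sites
#'
#' Among sites both divergent (versus the given species) and polymorphic in
#' the reference population, tallies the minor-allele count distribution per
#' residue class: bins `1 .. aggregate_at - 1` plus a final `>=aggregate_at`
#' bin labelled e.g. `"7+"`. Proportions sum to 1 within each class.
#'
#' @param sites Divergent-site tibble (one or more species).
#' @param polymorphisms Polymorphism tibble with `minor_count`, `sample_size`.
#' @param aggregate_at Counts at or above this value share the final bin.
#' @return Tibble `species`, `class`, `bin`, `count`, `proportion`; classes
#'   with zero sites are flagged via `empty` in the attribute table.
#' @export
folded_sfs <- function(sites, polymorphisms, aggregate_at = 7L) {
  stopifnot_cols(polymorphisms,
                 c("gene_id", "ref_index", "minor_count", "sample_size"))
  if (any(polymorphisms$minor_count < 1 |
            polymorphisms$minor_count > polymorphisms$sample_size / 2)) {
    abort("minor_count must lie in [1, sample_size/2]")
  }
  joined <- sites %>%
    inner_join(polymorphisms, by = c(ref_gene = "gene_id", "ref_index"))
  bins <- c(as.character(seq_len(aggregate_at - 1L)),
            paste0(aggregate_at, "+"))
  joined %>%
    mutate(bin = if_else(.data$minor_count >= aggregate_at,
                         paste0(aggregate_at, "+"),
                         as.character(.data$minor_count))) %>%
    group_by(.data$species, .data$class, .data$bin) %>%
    summarise(count = n(), .groups = "drop") %>%
    tidyr::complete(.data$species, .data$class,
                    bin = bins, fill = list(count = 0L)) %>%
    group_by(.data$species, .data$class) %>%
    mutate(proportion = if (sum(.data$count) > 0)
      .data$count / sum(.data$count) else NA_real_) %>%
    ungroup() %>%
    mutate(bin = factor(.data$bin, levels = bins)) %>%
    arrange(.data$species, .data$class, .data$bin)
}

fitch_count <- function(tree, states) {
  # states: named character vector over (a subset of) tip labels
  tips <- names(states)
  if (length(tips) < 2) return(0L)
  if (length(setdiff(tree$tip.label, tips)) > 0) {
    tree <- ape::keep.tip(tree, tips)
  }
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- states[[tree$tip.label[i]]]
  changes <- 0L
  for (e in ape::postorder(tree)) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    if (is.null(sets[[a]])) {
      sets[[a]] <- sets[[b]]
    } else {
      inter <- intersect(sets[[a]], sets[[b]])
      if (length(inter) > 0) {
        sets[[a]] <- inter
      } else {
        sets[[a]] <- union(sets[[a]], sets[[b]])
        changes <- changes + 1L
      }
    }
  }
  changes
}

#' Parsimony-based per-site evolutionary rate proxy
#'
#' For each reference column of an orthogroup alignment, the minimum
#' substitution count by Fitch parsimony over the species tree (pruned to the
#' species with data at that column) divided by the pruned tree's total
#' branch length. Deterministic; a stand-in for likelihood-based per-site
#' rates when only the pipeline's own alignments are available.
#'
#' @param alignment A [align_orthologs()] result.
#' @param species_tree Rooted `phylo` with branch lengths.
#' @return SiteRateTable tibble `group_id`, `ref_index`, `rate`, `complete`
#'   (data present for every species-tree species).
#' @export
parsimony_rate_proxy <- function(alignment, species_tree) {
  all_sp <- species_tree$tip.label
  ref_chars <- seq_chars(alignment$ref_sequence)
  by_col <- split(alignment$map, alignment$map$ref_index)
  tree_cache <- new.env(parent = emptyenv())
  pruned_for <- function(species) {
    key <- paste(sort(species), collapse = ",")
    hit <- tree_cache[[key]]
    if (is.null(hit)) {
      tr <- if (length(species) == length(all_sp)) species_tree else
        ape::keep.tip(species_tree, species)
      hit <- list(tree = tr, total_len = sum(tr$edge.length))
      tree_cache[[key]] <- hit
    }
    hit
  }
  n_col <- length(by_col)
  idx_v <- integer(n_col); rate_v <- numeric(n_col); compl_v <- logical(n_col)
  for (k in seq_len(n_col)) {
    m <- by_col[[k]]
    idx <- m$ref_index[1]
    states <- setNames(m$sp_residue, m$species)
    states[[alignment$reference]] <- ref_chars[idx + 1L]
    pt <- pruned_for(names(states))
    idx_v[k] <- idx
    rate_v[k] <- fitch_count(pt$tree, states) / pt$total_len
    compl_v[k] <- length(states) == length(all_sp)
  }
  tibble(group_id = alignment$group_id, ref_index = idx_v,
         rate = rate_v, complete = compl_v) %>%
    arrange(.data$ref_index)
}

#' Read a Rate4Site-style per-residue score file
#'
#' Parses the standard text output (comment lines starting `#`, then columns
#' POS, SEQ, SCORE, ...). Positions are converted to 0-based indices.
#'
#' @param path File path.
#' @return Tibble `ref_index`, `residue`, `rate`.
#' @export
read_rate4site <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  f <- strsplit(trimws(lines), "\\s+")
  bad <- which(map_int(f, length) < 3)
  if (length(bad) > 0) abort(sprintf("malformed rate line %d", bad[1]))
  tibble(ref_index = as.integer(map_chr(f, 1)) - 1L,
         residue = map_chr(f, 2),
         rate = as.numeric(map_chr(f, 3)))
}
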