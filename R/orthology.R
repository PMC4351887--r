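#' Build raw reference-anchored orthogroups from pairwise ortholog lists
#'
#' One raw group per reference gene, collecting every partner gene from every
#' species; a species may contribute more than one gene at this stage. The
#' reference gene itself is included as a row under the reference species.
#' A partner gene paired with two or more reference genes is kept in every
#' group it belongs to and flagged `ambiguous`.
#'
#' @param pairs Tibble with `ref_gene`, `species`, `gene_id` rows, one per
#'   pairwise ortholog assignment against the reference species.
#' @param reference Reference species label.
#' @return Tibble `group_id`, `ref_gene`, `species`, `gene_id`, `ambiguous`.
#' @export
build_orthogroups <- function(pairs, reference) {
  stopifnot_cols(pairs, c("ref_gene", "species", "gene_id"), "pairs")
  amb <- pairs %>%
    distinct(.data$ref_gene, .data$species, .data$gene_id) %>%
    group_by(.data$species, .data$gene_id) %>%
    mutate(ambiguous = n() > 1L) %>%
    ungroup()
  ref_rows <- amb %>%
    distinct(.data$ref_gene) %>%
    mutate(species = reference, gene_id = .data$ref_gene, ambiguous = FALSE)
  bind_rows(amb, ref_rows) %>%
    distinct(.data$ref_gene, .data$species, .data$gene_id, .keep_all = TRUE) %>%
    mutate(group_id = .data$ref_gene) %>%
    select("group_id", "ref_gene", "species", "gene_id", "ambiguous") %>%
    arrange(.data$group_id, .data$species, .data$gene_id)
}

#' Truncate raw groups to 1-to-1 orthogroups
#'
#' Every species contributing two or more genes to a group is removed from
#' that group. Groups retaining fewer than two species (the reference plus at
#' least one partner) are dropped. Untouched groups carry provenance
#' `"direct"`, truncated ones `"truncated"`.
#'
#' @param raw_groups Output of [build_orthogroups()].
#' @param reference Reference species label.
#' @return Orthogroup tibble `group_id`, `ref_gene`, `species`, `gene_id`,
#'   `provenance` with exactly one gene per retained species.
#' @export
truncate_one_to_one <- function(raw_groups, reference) {
  out <- raw_groups %>%
    group_by(.data$group_id) %>%
    mutate(n_species_before = length(unique(.data$species))) %>%
    group_by(.data$group_id, .data$species) %>%
    filter(n() == 1L) %>%
    group_by(.data$group_id) %>%
    filter(reference %in% .data$species,
           length(unique(.data$species)) >= 2L) %>%
    mutate(provenance = if_else(
      length(unique(.data$species)) == .data$n_species_before[1],
      "direct", "truncated")) %>%
    ungroup() %>%
    select("group_id", "ref_gene", "species", "gene_id", "provenance") %>%
    arrange(.data$group_id, .data$species)
  out
}

merge_overlapping_groups <- function(raw_groups) {
  # connected components (union-find) over shared (species, gene) members
  groups <- unique(raw_groups$group_id)
  parent <- seq_along(groups)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  gid <- match(raw_groups$group_id, groups)
  key <- paste(raw_groups$species, raw_groups$gene_id, sep = "\r")
  for (gs in split(gid, key)) {
    gs <- unique(gs)
    if (length(gs) > 1) {
      for (g in gs[-1]) {
        ri <- find(gs[1]); rj <- find(g)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  setNames(groups[vapply(seq_along(groups), find, integer(1))], groups)
}

#' Assemble 1-to-1 orthogroups, reconciling many-to-many components
#'
#' Raw groups are merged into connected components via shared member genes.
#' Components with a single reference gene go through 1-to-many truncation;
#' components with several reference genes (many-to-many families) are
#' resolved by duplication/loss reconciliation of a gene tree against the
#' species tree and decomposition into duplication-free subtrees. Gene trees
#' may be supplied per component (named list keyed by any member reference
#' gene) or are built by neighbor joining on pairwise alignment distances.
#'
#' @param raw_groups Output of [build_orthogroups()].
#' @param reference Reference species label.
#' @param species_tree Rooted `phylo`; required when reconciliation is needed.
#' @param proteins Protein tibble used to build gene trees (one representative
#'   sequence per gene) when `gene_trees` does not supply one.
#' @param gene_trees Optional named list of `phylo` gene trees with
#'   `species|gene` leaf labels.
#' @return Orthogroup tibble with provenance `direct`, `truncated`, or
#'   `reconciled+truncated`.
#' @export
assemble_orthogroups <- function(raw_groups, reference, species_tree = NULL,
                                 proteins = NULL, gene_trees = NULL) {
  comp <- merge_overlapping_groups(raw_groups)
  raw_groups$component <- comp[raw_groups$group_id]
  simple <- raw_groups %>%
    group_by(.data$component) %>%
    filter(length(unique(.data$ref_gene)) == 1L) %>%
    ungroup()
  multi <- anti_join(raw_groups, simple,
                     by = c("group_id", "species", "gene_id"))
  out <- truncate_one_to_one(select(simple, -"component"), reference)
  if (nrow(multi) > 0) {
    if (is.null(species_tree)) {
      abort("species_tree required to reconcile many-to-many orthogroups")
    }
    for (cmp in unique(multi$component)) {
      members <- multi %>%
        filter(.data$component == cmp) %>%
        distinct(.data$species, .data$gene_id)
      gt <- NULL
      if (!is.null(gene_trees)) {
        hit <- intersect(names(gene_trees),
                         unique(multi$ref_gene[multi$component == cmp]))
        if (length(hit) > 0) gt <- gene_trees[[hit[1]]]
      }
      if (is.null(gt)) {
        if (is.null(proteins)) {
          abort("proteins required to build gene trees for reconciliation")
        }
        gt <- build_gene_tree(members, proteins)
      }
      gt <- root_gene_tree(gt, species_tree)
      rec <- reconcile(gt, species_tree)
      out <- bind_rows(out, extract_one_to_one_subtrees(rec, reference))
    }
  }
  arrange(out, .data$group_id, .data$species)
}

#' Build a gene tree by neighbor joining on alignment distances
#'
#' Pairwise global protein alignments (BLOSUM62, affine gaps) give percent
#' mismatch distances; the unrooted NJ topology is returned with
#' `species|gene` leaf labels.
#'
#' @param members Tibble `species`, `gene_id` of the family.
#' @param proteins Protein tibble; the longest isoform per gene is used.
#' @return An (unrooted) `phylo`.
#' @export
build_gene_tree <- function(members, proteins) {
  seqs <- proteins %>%
    semi_join(members, by = c("species", "gene_id")) %>%
    group_by(.data$species, .data$gene_id) %>%
    arrange(desc(nchar(.data$sequence)), .data$protein_id) %>%
    slice(1) %>%
    ungroup()
  if (nrow(seqs) < 3) abort("gene tree requires at least 3 member genes")
  labs <- paste(seqs$species, seqs$gene_id, sep = "|")
  k <- nrow(seqs)
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      aln <- align_pair(seqs$sequence[i], seqs$sequence[j])
      cols <- nchar(aln$a)
      same <- sum(seq_chars(aln$a) == seq_chars(aln$b))
      d[i, j] <- d[j, i] <- 1 - same / cols
    }
  }
  ape::nj(stats::as.dist(d))
}

#' Keep orthogroups whose reference gene is poly-ZF
#'
#' @param orthogroups Orthogroup tibble.
#' @param domains Domain tibble (typically restricted to representative
#'   isoforms); domains are counted per reference gene.
#' @param reference Reference species label.
#' @param min_domains Minimum domain count for the reference gene.
#' @return Filtered orthogroup tibble.
#' @export
filter_polyzf <- function(orthogroups, domains, reference, min_domains = 2L) {
  counts <- domains %>%
    filter(.data$species == reference) %>%
    count(.data$gene_id, name = "n_domains")
  keep_genes <- counts$gene_id[counts$n_domains >= min_domains]
  filter(orthogroups, .data$ref_gene %in% keep_genes)
}
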