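# Species-tree indexing helpers -------------------------------------------

species_tree_index <- function(species_tree) {
  if (!inherits(species_tree, "phylo")) abort("species_tree must be a phylo")
  if (!ape::is.rooted(species_tree)) abort("species_tree must be rooted")
  n <- length(species_tree$tip.label)
  nnode <- n + species_tree$Nnode
  parent <- rep(NA_integer_, nnode)
  parent[species_tree$edge[, 2]] <- species_tree$edge[, 1]
  root <- setdiff(species_tree$edge[, 1], species_tree$edge[, 2])[1]
  depth <- rep(NA_integer_, nnode)
  depth[root] <- 0L
  ord <- rev(ape::postorder(species_tree))  # preorder: parents before children
  for (e in ord) {
    a <- species_tree$edge[e, 1]; b <- species_tree$edge[e, 2]
    depth[b] <- depth[a] + 1L
  }
  list(tree = species_tree, n_tip = n, parent = parent, root = root,
       depth = depth,
       tip_of = setNames(seq_len(n), species_tree$tip.label))
}

sp_lca2 <- function(idx, a, b) {
  while (a != b) {
    if (idx$depth[a] < idx$depth[b]) b <- idx$parent[b] else a <- idx$parent[a]
  }
  a
}

# leaf -> species mapping: tibble(leaf, species) or default "species|gene"
gene_leaf_species <- function(gene_tree, leaf_species = NULL) {
  labs <- gene_tree$tip.label
  if (is.null(leaf_species)) {
    sp <- sub("\\|.*$", "", labs)
  } else {
    stopifnot_cols(leaf_species, c("leaf", "species"), "leaf_species")
    sp <- leaf_species$species[match(labs, leaf_species$leaf)]
    if (anyNA(sp)) {
      abort(sprintf("gene-tree leaves without a species mapping: %s",
                    paste(labs[is.na(sp)], collapse = ", ")))
    }
  }
  sp
}

#' Reconcile a rooted gene tree against the species tree
#'
#' Standard last-common-ancestor (LCA) mapping: every gene-tree node maps to
#' the LCA of its leaves' species; an internal node is a duplication iff its
#' image equals the image of at least one child. Losses are counted per gene
#' edge from the species-tree path length between the parent and child images
#' (minus one below speciation nodes). For a fixed rooted topology this is the
#' parsimony minimum of duplications and losses.
#'
#' @param gene_tree Rooted `phylo`; leaves labelled `species|gene` or mapped
#'   via `leaf_species`.
#' @param species_tree Rooted `phylo` over species labels.
#' @param leaf_species Optional tibble `leaf`, `species`.
#' @return A `zf_reconciliation` list: the tree, per-node species images,
#'   duplication flags, per-edge loss counts, and total `duplications`,
#'   `losses`.
#' @export
reconcile <- function(gene_tree, species_tree, leaf_species = NULL) {
  if (!inherits(gene_tree, "phylo")) abort("gene_tree must be a phylo")
  idx <- species_tree_index(species_tree)
  sp <- gene_leaf_species(gene_tree, leaf_species)
  unmapped <- setdiff(unique(sp), names(idx$tip_of))
  if (length(unmapped) > 0) {
    abort(sprintf("species absent from the species tree: %s",
                  paste(unmapped, collapse = ", ")))
  }
  n <- length(gene_tree$tip.label)
  nnode <- n + gene_tree$Nnode
  image <- rep(NA_integer_, nnode)
  image[seq_len(n)] <- idx$tip_of[sp]
  po <- ape::postorder(gene_tree)
  for (e in po) {
    a <- gene_tree$edge[e, 1]; b <- gene_tree$edge[e, 2]
    image[a] <- if (is.na(image[a])) image[b] else sp_lca2(idx, image[a], image[b])
  }
  is_dup <- rep(FALSE, nnode)
  for (v in (n + 1):nnode) {
    kids <- gene_tree$edge[gene_tree$edge[, 1] == v, 2]
    is_dup[v] <- any(image[kids] == image[v])
  }
  edge_losses <- integer(nrow(gene_tree$edge))
  for (e in seq_len(nrow(gene_tree$edge))) {
    a <- gene_tree$edge[e, 1]; b <- gene_tree$edge[e, 2]
    d <- idx$depth[image[b]] - idx$depth[image[a]]
    edge_losses[e] <- if (is_dup[a]) d else max(0L, d - 1L)
  }
  structure(list(gene_tree = gene_tree, species_tree = species_tree,
                 leaf_species = sp, image = image, is_duplication = is_dup,
                 edge_losses = edge_losses,
                 duplications = sum(is_dup), losses = sum(edge_losses)),
            class = "zf_reconciliation")
}

#' @export
print.zf_reconciliation <- function(x, ...) {
  cat(sprintf("<zf_reconciliation> %d leaves: %d duplication(s), %d loss(es)\n",
              length(x$gene_tree$tip.label), x$duplications, x$losses))
  invisible(x)
}

#' Root an unrooted gene tree by duplication/loss parsimony
#'
#' Tries rooting on every edge (at the midpoint) and keeps the rooting with
#' the fewest duplications, breaking ties by losses and then by edge order.
#' Rooted input is returned unchanged.
#'
#' @inheritParams reconcile
#' @return A rooted `phylo`.
#' @export
root_gene_tree <- function(gene_tree, species_tree, leaf_species = NULL) {
  if (ape::is.rooted(gene_tree) && ape::is.binary(gene_tree)) return(gene_tree)
  if (is.null(gene_tree$edge.length)) {
    gene_tree$edge.length <- rep(1, nrow(gene_tree$edge))
  }
  best <- NULL
  for (e in seq_len(nrow(gene_tree$edge))) {
    node <- gene_tree$edge[e, 2]
    cand <- try(phytools::reroot(gene_tree, node,
                                 position = gene_tree$edge.length[e] / 2),
                silent = TRUE)
    if (inherits(cand, "try-error")) next
    rec <- reconcile(cand, species_tree, leaf_species)
    score <- c(rec$duplications, rec$losses)
    if (is.null(best) || score[1] < best$score[1] ||
        (score[1] == best$score[1] && score[2] < best$score[2])) {
      best <- list(tree = cand, score = score)
    }
  }
  if (is.null(best)) abort("could not root gene tree")
  best$tree
}

#' Extract maximal duplication-free subtrees as 1-to-1 orthogroups
#'
#' Recursively descends the reconciled gene tree: a clade containing no
#' duplication node is emitted whole; otherwise its children are examined.
#' Each emitted clade is truncated to 1-to-1 species, must contain exactly one
#' reference gene, and must retain at least two species.
#'
#' @param reconciliation A [reconcile()] result.
#' @param reference Reference species label.
#' @return Tibble `group_id`, `ref_gene`, `species`, `gene_id`, `provenance`
#'   (`"reconciled+truncated"`).
#' @export
extract_one_to_one_subtrees <- function(reconciliation, reference) {
  gt <- reconciliation$gene_tree
  n <- length(gt$tip.label)
  nnode <- n + gt$Nnode
  kids_of <- split(gt$edge[, 2], gt$edge[, 1])
  contains_dup <- rep(FALSE, nnode)
  for (e in ape::postorder(gt)) {
    a <- gt$edge[e, 1]; b <- gt$edge[e, 2]
    contains_dup[a] <- contains_dup[a] || contains_dup[b] ||
      reconciliation$is_duplication[b]
  }
  root <- setdiff(gt$edge[, 1], gt$edge[, 2])[1]
  contains_dup[root] <- contains_dup[root] || reconciliation$is_duplication[root]
  groups <- list()
  emit_or_descend <- function(v) {
    if (v <= n || !(contains_dup[v] || reconciliation$is_duplication[v])) {
      tips <- if (v <= n) v else
        intersect(seq_len(n), phangorn_descendants(gt, v, kids_of))
      groups[[length(groups) + 1L]] <<- tips
    } else {
      for (k in kids_of[[as.character(v)]]) emit_or_descend(k)
    }
  }
  emit_or_descend(root)
  sp <- reconciliation$leaf_species
  genes <- sub("^[^|]*\\|", "", gt$tip.label)
  out <- imap(groups, function(tips, i) {
    g <- tibble(species = sp[tips], gene_id = genes[tips])
    g <- g %>% group_by(.data$species) %>% filter(n() == 1L) %>% ungroup()
    ref_genes <- g$gene_id[g$species == reference]
    if (length(ref_genes) != 1L) return(NULL)
    if (length(unique(g$species)) < 2L) return(NULL)
    mutate(g, ref_gene = ref_genes, provenance = "reconciled+truncated")
  }) %>% list_rbind()
  if (nrow(out) == 0) {
    return(tibble(group_id = character(), ref_gene = character(),
                  species = character(), gene_id = character(),
                  provenance = character()))
  }
  out %>%
    mutate(group_id = .data$ref_gene) %>%
    select("group_id", "ref_gene", "species", "gene_id", "provenance") %>%
    arrange(.data$group_id, .data$species)
}

phangorn_descendants <- function(tree, v, kids_of) {
  out <- integer(0)
  stack <- v
  while (length(stack) > 0) {
    x <- stack[[1]]; stack <- stack[-1]
    out <- c(out, x)
    kk <- kids_of[[as.character(x)]]
    if (!is.null(kk)) stack <- c(stack, kk)
  }
  out
}
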