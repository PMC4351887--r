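# Independent oracles used to freeze expected values. These deliberately use
# naive algorithms (explicit backtracking, exhaustive enumeration) and never
# share code with the implementation paths they check.

# --- naive backtracking C2H2 regex oracle ---------------------------------
# left-greedy: earliest start; shortest c1, then c2, then c3; resume after
# the reported match end.
naive_c2h2_scan <- function(sequence, c1 = c(2, 4), c2 = c(8, 12),
                            c3 = c(3, 5), psi = c("F","Y","W","L","I","V","M")) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  out <- list()
  i <- 1
  while (i <= n) {
    hit <- NULL
    if (s[i] == "C") {
      for (a in c1[1]:c1[2]) {
        if (!is.null(hit)) break
        p2 <- i + a + 1
        if (p2 > n || s[p2] != "C") next
        for (b in c2[1]:c2[2]) {
          if (!is.null(hit)) break
          ppsi <- p2 + b + 1
          if (ppsi > n || !(s[ppsi] %in% psi)) next
          ph <- ppsi + 3
          if (ph > n || s[ph] != "H") next
          for (cc in c3[1]:c3[2]) {
            pend <- ph + cc + 1
            if (pend > n || !(s[pend] %in% c("H", "C"))) next
            hit <- list(start = i - 1L, end = pend, pos7 = ph - 1L)
            break
          }
        }
      }
    }
    if (is.null(hit)) {
      i <- i + 1
    } else {
      out[[length(out) + 1L]] <- hit
      i <- hit$end + 1L
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      pos7_index = integer()))
  }
  data.frame(start = as.integer(vapply(out, `[[`, 0, "start")),
             end = as.integer(vapply(out, `[[`, 0, "end")),
             pos7_index = as.integer(vapply(out, `[[`, 0, "pos7")))
}

# --- exhaustive duplication/loss reconciliation oracle --------------------
# enumerates every valid mapping of gene-tree internal nodes to species-tree
# vertices (each node at or above the LCA of its children's images) and
# minimizes total duplications + losses.
brute_force_reconcile <- function(gene_tree, species_tree) {
  stree <- species_tree
  ns <- length(stree$tip.label)
  s_nnode <- ns + stree$Nnode
  s_parent <- rep(NA_integer_, s_nnode)
  s_parent[stree$edge[, 2]] <- stree$edge[, 1]
  s_root <- setdiff(stree$edge[, 1], stree$edge[, 2])[1]
  s_depth <- rep(NA_integer_, s_nnode)
  s_depth[s_root] <- 0L
  for (e in rev(ape::postorder(stree))) {
    s_depth[stree$edge[e, 2]] <- s_depth[stree$edge[e, 1]] + 1L
  }
  lca2 <- function(a, b) {
    while (a != b) {
      if (s_depth[a] < s_depth[b]) b <- s_parent[b] else a <- s_parent[a]
    }
    a
  }
  ancestors_inclusive <- function(v) {
    out <- v
    while (!is.na(s_parent[v])) { v <- s_parent[v]; out <- c(out, v) }
    out
  }
  is_desc_or_equal <- function(x, anc) anc %in% ancestors_inclusive(x)

  gt <- gene_tree
  ng <- length(gt$tip.label)
  g_nnode <- ng + gt$Nnode
  kids <- split(gt$edge[, 2], gt$edge[, 1])
  g_root <- setdiff(gt$edge[, 1], gt$edge[, 2])[1]
  leaf_sp <- sub("\\|.*$", "", gt$tip.label)
  leaf_img <- match(leaf_sp, stree$tip.label)

  # candidate images per internal node: ancestors (inclusive) of the LCA of
  # the node's leaf species
  clade_lca <- rep(NA_integer_, g_nnode)
  for (v in seq_len(ng)) clade_lca[v] <- leaf_img[v]
  for (e in ape::postorder(gt)) {
    a <- gt$edge[e, 1]; b <- gt$edge[e, 2]
    clade_lca[a] <- if (is.na(clade_lca[a])) clade_lca[b] else
      lca2(clade_lca[a], clade_lca[b])
  }
  internal <- (ng + 1):g_nnode
  cand <- lapply(seq_len(g_nnode), function(v) {
    if (v <= ng) leaf_img[v] else ancestors_inclusive(clade_lca[v])
  })

  # child of `anc` through which `x` descends (NA if x == anc)
  child_lineage <- function(x, anc) {
    if (x == anc) return(NA_integer_)
    while (!is.na(s_parent[x]) && s_parent[x] != anc) x <- s_parent[x]
    x
  }
  score_mapping <- function(img) {
    dup <- logical(g_nnode)
    for (v in internal) {
      lineages <- integer(0)
      for (k in kids[[as.character(v)]]) {
        # invalid if child image not at/below node image
        if (!is_desc_or_equal(img[k], img[v])) return(NULL)
        if (img[k] == img[v]) dup[v] <- TRUE
        lineages <- c(lineages, child_lineage(img[k], img[v]))
      }
      # speciation requires the children to descend through distinct
      # child lineages of the image
      if (anyDuplicated(lineages[!is.na(lineages)]) > 0) dup[v] <- TRUE
    }
    losses <- 0L
    for (e in seq_len(nrow(gt$edge))) {
      a <- gt$edge[e, 1]; b <- gt$edge[e, 2]
      d <- s_depth[img[b]] - s_depth[img[a]]
      losses <- losses + if (dup[a]) d else max(0L, d - 1L)
    }
    c(dup = sum(dup), loss = losses)
  }

  best <- NULL
  img <- vapply(cand, `[`, 0L, 1)
  recurse <- function(i) {
    if (i > length(internal)) {
      sc <- score_mapping(img)
      if (!is.null(sc)) {
        tot <- sum(sc)
        if (is.null(best) || tot < sum(best) ||
            (tot == sum(best) && sc[1] < best[1])) best <<- sc
      }
      return(invisible())
    }
    v <- internal[i]
    for (x in cand[[v]]) {
      img[v] <<- x
      recurse(i + 1)
    }
  }
  recurse(1)
  list(duplications = unname(best["dup"]), losses = unname(best["loss"]))
}

# random rooted binary gene tree over k leaves with species drawn (with
# replacement) from the species tree
random_gene_tree <- function(species_tree, k) {
  sp <- sample(species_tree$tip.label, k, replace = TRUE)
  labels <- paste0(sp, "|g", seq_len(k))
  nodes <- as.list(labels)
  while (length(nodes) > 1) {
    i <- sample(length(nodes), 2)
    merged <- sprintf("(%s:1,%s:1)", nodes[[i[1]]], nodes[[i[2]]])
    nodes <- c(nodes[-i], merged)
  }
  ape::read.tree(text = paste0(nodes[[1]], ";"))
}

# --- exact minimum set cover by subset enumeration ------------------------
brute_force_min_cover_size <- function(sets, universe) {
  k <- length(sets)
  for (s in seq_len(k)) {
    for (idx in utils::combn(k, s, simplify = FALSE)) {
      if (length(setdiff(universe, unique(unlist(sets[idx])))) == 0) {
        return(s)
      }
    }
  }
  Inf
}

# --- 4^L enumeration oracle for scan p-values -----------------------------
# shares only the discretized integer score matrix with the implementation
# ("matched discretization"); probabilities are enumerated word by word.
enumerate_scan_pvalues <- function(int_mat, background) {
  L <- ncol(int_mat)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- integer(nrow(words))
  probs <- numeric(nrow(words)) + 1
  for (j in seq_len(L)) {
    scores <- scores + int_mat[cbind(words[, j], j)]
    probs <- probs * background[words[, j]]
  }
  list(words = words, scores = scores, probs = probs,
       pvalue_of = function(t) sum(probs[scores >= t]))
}

# --- Fitch parsimony by exhaustive internal labeling ----------------------
brute_force_fitch <- function(tree, states) {
  tr <- if (length(setdiff(tree$tip.label, names(states))) > 0) {
    ape::keep.tip(tree, names(states))
  } else tree
  n <- length(tr$tip.label)
  nnode <- n + tr$Nnode
  alphabet <- unique(unname(states))
  internal <- (n + 1):nnode
  tip_state <- states[tr$tip.label]
  grids <- rep(list(alphabet), length(internal))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- c(tip_state, unlist(combos[r, ], use.names = FALSE))
    changes <- sum(lab[tr$edge[, 1]] != lab[tr$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# --- clade-support replay from simulation ground truth --------------------
# recomputes per-class support counts purely from the stable-residue-id
# states, independently of alignment and domain calling
truth_clade_support <- function(sim, pairing, min_domains = 2L) {
  ref <- sim$reference
  states <- sim$truth$species_states
  ref_states <- states[[ref]]
  gd <- function(gs) unique(gs$domain[!is.na(gs$domain)])
  genes <- names(ref_states)[vapply(ref_states, function(gs)
    length(gd(gs)) >= min_domains, logical(1))]
  partner <- c(stats::setNames(pairing$species_b, pairing$species_a),
               stats::setNames(pairing$species_a, pairing$species_b))
  rows <- list()
  for (sp in names(partner)) {
    pb <- partner[[sp]]
    for (g in genes) {
      rs <- ref_states[[g]]
      as_ <- states[[sp]][[g]]
      bs <- states[[pb]][[g]]
      ia <- match(rs$id, as_$id)
      ib <- match(rs$id, bs$id)
      div <- !is.na(ia) & rs$char != as_$char[ia]
      elig <- which(div & !is.na(ib))
      if (length(elig) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, class = rs$class[elig],
        supported = as_$char[ia[elig]] == bs$char[ib[elig]])
    }
  }
  df <- do.call(rbind, rows)
  out <- aggregate(supported ~ species + class, df,
                   function(x) cbind(sum(x), length(x)))
  data.frame(species = out$species, class = out$class,
             numerator = out$supported[, 1],
             denominator = out$supported[, 2])
}
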