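#' @importFrom Biostrings pairwiseAlignment AAString alignedPattern alignedSubject
NULL

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# global alignment of two amino-acid strings; returns the aligned strings
align_pair <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  aln <- pairwiseAlignment(AAString(a), AAString(b), type = "global",
                           substitutionMatrix = blosum62(),
                           gapOpening = gap_opening,
                           gapExtension = gap_extension)
  list(a = as.character(alignedPattern(aln)),
       b = as.character(alignedSubject(aln)))
}

# rebuild the gapped alignment strings from the indel ranges, which
# pairwiseAlignment reports in alignment-column coordinates (insertions =
# columns where the subject is gapped, deletions = columns where the pattern
# is gapped); end overhangs of the pattern are not reported as indels and are
# recovered from the pattern's aligned range
gapped_from_indels <- function(ref_seq, sp_seq, ins_ranges, del_ranges,
                               p_start = 1L, p_end = nchar(sp_seq)) {
  rch <- seq_chars(ref_seq)
  sch <- seq_chars(sp_seq)
  plen <- length(sch)
  slen <- length(rch)
  lead <- p_start - 1L
  trail <- plen - p_end
  # reported ranges exclude the lead-overhang columns and the columns of
  # earlier ranges of their own kind; shift cumulatively to column space
  expand <- function(rng) {
    s <- BiocGenerics::start(rng)
    e <- BiocGenerics::end(rng)
    if (length(s) == 0) return(integer(0))
    w <- e - s + 1L
    off <- lead + c(0L, cumsum(w))[seq_along(s)]
    unlist(mapply(function(si, ei, oi) seq.int(si + oi, ei + oi),
                  s, e, off, SIMPLIFY = FALSE), use.names = FALSE)
  }
  ins_cols <- expand(ins_ranges)
  del_cols <- expand(del_ranges)
  n_cols <- slen + length(ins_cols) + lead + trail
  ref_row <- rep("-", n_cols)
  sp_row <- rep("-", n_cols)
  ref_gap_cols <- c(seq_len(lead), ins_cols,
                    if (trail > 0) (n_cols - trail + 1L):n_cols else integer(0))
  ref_row[setdiff(seq_len(n_cols), ref_gap_cols)] <- rch
  sp_row[setdiff(seq_len(n_cols), del_cols)] <- sch
  list(ref_aln = paste(ref_row, collapse = ""),
       sp_aln = paste(sp_row, collapse = ""))
}

# column map between two aligned (gapped) strings: 0-based indices of columns
# where both rows are ungapped
aligned_column_map <- function(ref_aln, sp_aln) {
  rc <- seq_chars(ref_aln); sc <- seq_chars(sp_aln)
  ref_idx <- cumsum(rc != "-") - 1L
  sp_idx <- cumsum(sc != "-") - 1L
  both <- rc != "-" & sc != "-"
  tibble(ref_index = ref_idx[both], sp_index = sp_idx[both],
         ref_residue = rc[both], sp_residue = sc[both])
}

#' Align orthologous proteins to the reference
#'
#' Global pairwise alignment (BLOSUM62, affine gaps) of each species'
#' representative protein against the reference protein of one orthogroup,
#' giving a monotone reference-index to species-index column map per species.
#' Pre-computed alignments (a tibble `species`, `ref_aln`, `sp_aln` of equal
#' gapped lengths per row pair) are accepted verbatim. Species listed in the
#' orthogroup but missing a sequence are skipped with a message.
#'
#' @param orthogroup Rows of one orthogroup (`group_id`, `ref_gene`,
#'   `species`, `gene_id`).
#' @param proteins Protein tibble; the longest isoform per gene is aligned.
#' @param reference Reference species label.
#' @param supplied Optional pre-computed alignment tibble as above.
#' @return A `zf_alignment`: group/reference metadata, per-species aligned
#'   strings, and the per-species column `map`.
#' @export
align_orthologs <- function(orthogroup, proteins, reference, supplied = NULL) {
  group_id <- orthogroup$group_id[1]
  pick <- proteins %>%
    semi_join(orthogroup, by = c("species", "gene_id")) %>%
    group_by(.data$species, .data$gene_id) %>%
    arrange(desc(nchar(.data$sequence)), .data$protein_id) %>%
    slice(1) %>%
    ungroup()
  ref_row <- filter(pick, .data$species == reference)
  if (nrow(ref_row) != 1) abort("reference sequence missing from orthogroup")
  others <- orthogroup$species[orthogroup$species != reference]
  pre <- NULL
  if (!is.null(supplied)) {
    pre_sp <- intersect(others, supplied$species)
    pre <- map(pre_sp, function(sp) {
      srow <- filter(supplied, .data$species == sp)[1, ]
      pid <- pick$protein_id[pick$species == sp]
      tibble(species = sp,
             protein_id = if (length(pid)) pid[1] else NA_character_,
             ref_aln = srow$ref_aln, sp_aln = srow$sp_aln)
    }) %>% list_rbind()
    others <- setdiff(others, pre_sp)
  }
  todo <- pick[match(others, pick$species), , drop = FALSE]
  missing <- others[is.na(todo$protein_id)]
  if (length(missing) > 0) {
    rlang::inform(sprintf("orthogroup %s: no sequence for species %s; skipped",
                          group_id, paste(missing, collapse = ", ")))
    todo <- todo[!is.na(todo$protein_id), , drop = FALSE]
  }
  rows <- pre
  if (nrow(todo) > 0) {
    # one batched call: all species sequences against the reference subject;
    # aligned views + indel ranges are far cheaper to extract than the
    # gapped strings, which are reconstructed in R
    aln <- pairwiseAlignment(
      Biostrings::AAStringSet(todo$sequence), AAString(ref_row$sequence),
      type = "global", substitutionMatrix = blosum62(),
      gapOpening = 10, gapExtension = 0.5)
    ind <- Biostrings::indel(aln)
    ins <- Biostrings::insertion(ind)
    del <- Biostrings::deletion(ind)
    p_starts <- BiocGenerics::start(Biostrings::pattern(aln))
    p_ends <- BiocGenerics::end(Biostrings::pattern(aln))
    rebuilt <- map(seq_len(nrow(todo)), function(i) {
      gapped_from_indels(ref_row$sequence, todo$sequence[i],
                         ins[[i]], del[[i]], p_starts[i], p_ends[i])
    })
    rows <- bind_rows(pre, tibble(
      species = todo$species, protein_id = todo$protein_id,
      ref_aln = map_chr(rebuilt, "ref_aln"),
      sp_aln = map_chr(rebuilt, "sp_aln")))
  }
  maps <- rows %>%
    split(seq_len(nrow(rows))) %>%
    map(function(r) mutate(aligned_column_map(r$ref_aln, r$sp_aln),
                           species = r$species, .before = 1)) %>%
    list_rbind()
  structure(list(group_id = group_id, reference = reference,
                 ref_gene = orthogroup$ref_gene[1],
                 ref_protein_id = ref_row$protein_id,
                 ref_sequence = ref_row$sequence,
                 rows = rows, map = maps),
            class = "zf_alignment")
}

#' @export
print.zf_alignment <- function(x, ...) {
  cat(sprintf("<zf_alignment> group %s: reference %s vs %d species\n",
              x$group_id, x$reference, nrow(x$rows)))
  invisible(x)
}

domain_key <- function(d) paste(d$protein_id, d$start, sep = ":")

helix_window_indices <- function(pos7_index) {
  map(pos7_index, function(p) c(p - 7L, (p - 6L):p))
}

#' Establish reference/species domain correspondence
#'
#' Reference and species domains are paired when their helix windows (-1..7)
#' share at least `min_overlap` aligned columns (greedy by overlap, ties
#' resolved N-terminal first). Unpaired reference domains are lost in that
#' species; unpaired species domains are gains. A reference domain lost in
#' every species is re-labelled `not_evaluated` everywhere, since it most
#' likely is a reference-specific gain.
#'
#' @param alignment A [align_orthologs()] result.
#' @param domains Domain tibble covering the proteins in the alignment.
#' @param min_overlap Minimum shared aligned helix columns (window of 8).
#' @return Tibble `group_id`, `species`, `ref_domain`, `sp_domain`, `status`
#'   in aligned/lost/gained/not_evaluated.
#' @export
match_domains <- function(alignment, domains, min_overlap = 5L) {
  ref_d <- domains %>%
    filter(.data$protein_id == alignment$ref_protein_id) %>%
    arrange(.data$start)
  ref_keys <- domain_key(ref_d)
  rwin <- helix_window_indices(ref_d$pos7_index)
  ref_len <- nchar(alignment$ref_sequence)
  dom_by_protein <- split(domains, domains$protein_id)
  out <- map(unique(alignment$rows$species), function(sp) {
    pid <- alignment$rows$protein_id[alignment$rows$species == sp][1]
    sp_d <- dom_by_protein[[pid]]
    sp_d <- if (is.null(sp_d)) ref_d[0, ] else arrange(sp_d, .data$start)
    sp_keys <- domain_key(sp_d)
    m <- alignment$map[alignment$map$species == sp, ]
    colmap <- rep(NA_integer_, ref_len)
    colmap[m$ref_index + 1L] <- m$sp_index
    swin <- helix_window_indices(sp_d$pos7_index)
    nr <- nrow(ref_d); ns <- nrow(sp_d)
    ov <- matrix(0L, nr, ns)
    for (ri in seq_len(nr)) {
      mapped <- colmap[rwin[[ri]] + 1L]
      for (si in seq_len(ns)) {
        ov[ri, si] <- sum(!is.na(mapped) & mapped %in% swin[[si]])
      }
    }
    used_r <- logical(nr); used_s <- logical(ns)
    pr <- integer(0); ps <- integer(0)
    if (nr > 0 && ns > 0) {
      cand <- which(ov >= min_overlap, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        # greedy by overlap, ties N-terminal first
        o <- order(-ov[cand], cand[, 1], cand[, 2])
        for (k in o) {
          ri <- cand[k, 1]; si <- cand[k, 2]
          if (!used_r[ri] && !used_s[si]) {
            used_r[ri] <- TRUE; used_s[si] <- TRUE
            pr <- c(pr, ri); ps <- c(ps, si)
          }
        }
      }
    }
    tibble(
      species = sp,
      ref_domain = c(ref_keys[pr], ref_keys[!used_r],
                     rep(NA_character_, sum(!used_s))),
      sp_domain = c(sp_keys[ps], rep(NA_character_, sum(!used_r)),
                    sp_keys[!used_s]),
      status = c(rep("aligned", length(pr)), rep("lost", sum(!used_r)),
                 rep("gained", sum(!used_s))))
  }) %>% list_rbind()
  if (nrow(out) == 0) {
    return(tibble(group_id = character(), species = character(),
                  ref_domain = character(), sp_domain = character(),
                  status = character()))
  }
  # reference domains lost everywhere are reference-specific gains
  status_by_ref <- out %>%
    filter(!is.na(.data$ref_domain)) %>%
    group_by(.data$ref_domain) %>%
    summarise(all_lost = all(.data$status == "lost"))
  never_aligned <- status_by_ref$ref_domain[status_by_ref$all_lost]
  out <- out %>%
    mutate(status = if_else(.data$ref_domain %in% never_aligned &
                              .data$status == "lost",
                            "not_evaluated", .data$status)) %>%
    mutate(group_id = alignment$group_id, .before = 1)
  out
}

map2_int_ <- function(x, y, f) {
  vapply(seq_along(x), function(i) as.integer(f(x[[i]], y[[i]])), integer(1))
}

#' Partition reference residues into functional classes
#'
#' Every reference residue receives exactly one class: helix positions
#' -1, 2, 3, 6 are BINDING; helix 1, 4, 5 are HELIX_EXCLUDED; the remaining
#' domain residues (including the zinc-coordinating positions) are
#' C2H2_NONBINDING; residues between adjacent canonically linked domains are
#' LINKER; everything else is BACKGROUND.
#'
#' @param arrays Array-annotated domain tibble (one protein or many).
#' @param proteins Protein tibble.
#' @return Tibble `protein_id`, `index` (0-based), `residue`, `class`, and
#'   `domain_id` for residues inside a domain.
#' @export
classify_residues <- function(arrays, proteins) {
  one <- function(prow) {
    len <- nchar(prow$sequence)
    cls <- rep("BACKGROUND", len)
    dom <- rep(NA_character_, len)
    d <- arrays %>% filter(.data$protein_id == prow$protein_id) %>%
      arrange(.data$start)
    for (i in seq_len(nrow(d))) {
      span <- (d$start[i] + 1L):d$end[i]
      cls[span] <- "C2H2_NONBINDING"
      dom[span] <- domain_key(d[i, ])
      for (p in HELIX_POSITIONS) {
        idx <- helix_position_index(d$pos7_index[i], p) + 1L
        if (p %in% BINDING_POSITIONS) cls[idx] <- "BINDING"
        else if (p %in% HELIX_EXCLUDED_POSITIONS) cls[idx] <- "HELIX_EXCLUDED"
      }
      if (i < nrow(d) && isTRUE(d$canonical_after[i])) {
        gap <- (d$end[i] + 1L):d$start[i + 1L]
        cls[gap] <- "LINKER"
      }
    }
    tibble(protein_id = prow$protein_id, index = seq_len(len) - 1L,
           residue = seq_chars(prow$sequence), class = cls, domain_id = dom)
  }
  pp <- filter(proteins, .data$protein_id %in% unique(arrays$protein_id))
  pp %>%
    split(seq_len(nrow(pp))) %>%
    map(one) %>%
    list_rbind()
}

#' Call divergent domains and divergent sites
#'
#' For every aligned reference/species domain pair, the domain is diverged iff
#' at least one of helix positions -1, 2, 3, 6 differs between the two
#' sequences (gapped positions are skipped; a pair with all four specificity
#' positions gapped is not evaluable). Independently, every reference residue
#' that differs from the aligned species residue (any class) is emitted as a
#' divergent site with its residue class.
#'
#' @param alignment A [align_orthologs()] result.
#' @param correspondence Output of [match_domains()] for the same group.
#' @param domains Domain tibble.
#' @param residue_classes Output of [classify_residues()] for the reference
#'   protein.
#' @return List with `domains` (per aligned pair: `diverged`, `evaluable`,
#'   `n_compared`) and `sites` (DivergentSite tibble).
#' @export
call_divergent_sites <- function(alignment, correspondence, domains,
                                 residue_classes) {
  ref_classes <- residue_classes %>%
    filter(.data$protein_id == alignment$ref_protein_id)
  cls_of <- setNames(ref_classes$class, ref_classes$index)
  dom_of <- setNames(ref_classes$domain_id, ref_classes$index)
  dtab <- domains
  dtab$domain_id <- domain_key(dtab)
  sites <- alignment$map %>%
    filter(.data$ref_residue != .data$sp_residue) %>%
    mutate(group_id = alignment$group_id,
           ref_gene = alignment$ref_gene,
           class = unname(cls_of[as.character(.data$ref_index)]),
           domain_id = unname(dom_of[as.character(.data$ref_index)])) %>%
    select("group_id", "ref_gene", "species", "ref_index", "sp_index",
           "ref_residue", "sp_residue", "class", "domain_id")
  pairs <- filter(correspondence, .data$status == "aligned")
  pos7_of <- setNames(dtab$pos7_index, dtab$domain_id)
  # per-species lookup vectors indexed by reference position
  sp_lookup <- map(split(alignment$map, alignment$map$species), function(m) {
    ref_len <- nchar(alignment$ref_sequence)
    sp_idx <- rep(NA_integer_, ref_len)
    sp_idx[m$ref_index + 1L] <- m$sp_index
    rres <- rep(NA_character_, ref_len); rres[m$ref_index + 1L] <- m$ref_residue
    sres <- rep(NA_character_, ref_len); sres[m$ref_index + 1L] <- m$sp_residue
    list(sp_idx = sp_idx, ref_res = rres, sp_res = sres)
  })
  n_pair <- nrow(pairs)
  n_comp_v <- integer(n_pair); div_v <- logical(n_pair)
  for (i in seq_len(n_pair)) {
    lu <- sp_lookup[[pairs$species[i]]]
    r7 <- pos7_of[[pairs$ref_domain[i]]]
    s7 <- pos7_of[[pairs$sp_domain[i]]]
    n_comp <- 0L; div <- FALSE
    for (p in BINDING_POSITIONS) {
      r_idx <- helix_position_index(r7, p)
      s_idx <- helix_position_index(s7, p)
      mapped <- lu$sp_idx[r_idx + 1L]
      if (is.na(mapped) || mapped != s_idx) next  # gapped or shifted: skip
      n_comp <- n_comp + 1L
      if (lu$ref_res[r_idx + 1L] != lu$sp_res[r_idx + 1L]) div <- TRUE
    }
    n_comp_v[i] <- n_comp; div_v[i] <- div
  }
  dom_calls <- tibble(group_id = alignment$group_id, species = pairs$species,
                      ref_domain = pairs$ref_domain,
                      sp_domain = pairs$sp_domain,
                      n_compared = n_comp_v, evaluable = n_comp_v > 0L,
                      diverged = if_else(n_comp_v > 0L, div_v, NA))
  list(domains = dom_calls, sites = sites)
}

#' Stratified loss / gain / divergence summaries
#'
#' Per species: percent of reference domains lost (of those evaluated),
#' percent of species domains gained (of aligned plus gained), and percent of
#' evaluable aligned domains with a divergent specificity residue - overall
#' and stratified by canonical linkage, array size, array position, and
#' bordering-linker mean length of the reference domain. Strata with zero
#' denominator report `value = NA`, never 0.
#'
#' @param correspondences Combined [match_domains()] output across groups.
#' @param domain_calls Combined `domains` element of [call_divergent_sites()].
#' @param arrays Array-annotated domain tibble (for reference-domain strata).
#' @return Long tibble `species`, `metric`, `stratum_type`, `stratum`,
#'   `numerator`, `denominator`, `value`.
#' @export
summarize_divergence <- function(correspondences, domain_calls, arrays) {
  ref_attr <- arrays %>%
    mutate(domain_id = domain_key(arrays),
           border_linker = as.character(.data$mean_border_linker)) %>%
    select("domain_id", "canonically_linked", "array_size", "array_position",
           "border_linker")
  cors <- correspondences %>%
    left_join(ref_attr, by = c(ref_domain = "domain_id"))
  calls <- domain_calls %>%
    left_join(ref_attr, by = c(ref_domain = "domain_id"))
  strata <- list(
    overall = function(df) rep("all", nrow(df)),
    canonical = function(df) as.character(df$canonically_linked),
    array_size = function(df) as.character(df$array_size),
    array_position = function(df) df$array_position,
    border_linker = function(df) df$border_linker
  )
  summarize_metric <- function(df, metric) {
    # df carries logical .num and .den columns
    map(names(strata), function(st) {
      df$stratum <- strata[[st]](df)
      df %>%
        filter(!is.na(.data$stratum), .data$.den) %>%
        group_by(.data$species, .data$stratum) %>%
        summarise(numerator = sum(.data$.num, na.rm = TRUE),
                  denominator = n(), .groups = "drop") %>%
        mutate(metric = metric, stratum_type = st)
    }) %>% list_rbind()
  }
  lost <- cors %>%
    filter(.data$status %in% c("aligned", "lost"), !is.na(.data$ref_domain)) %>%
    mutate(.num = .data$status == "lost", .den = TRUE) %>%
    summarize_metric("pct_domains_lost")
  gained <- cors %>%  # gains: overall only (species-domain strata not defined)
    filter(.data$status %in% c("aligned", "gained")) %>%
    group_by(.data$species) %>%
    summarise(numerator = sum(.data$status == "gained"),
              denominator = n(), .groups = "drop") %>%
    mutate(stratum = "all", metric = "pct_domains_gained",
           stratum_type = "overall")
  diverged <- calls %>%
    filter(.data$evaluable) %>%
    mutate(.num = .data$diverged, .den = TRUE) %>%
    summarize_metric("pct_domains_diverged")
  bind_rows(lost, gained, diverged) %>%
    mutate(value = if_else(.data$denominator > 0,
                           100 * .data$numerator / .data$denominator,
                           NA_real_)) %>%
    select("species", "metric", "stratum_type", "stratum",
           "numerator", "denominator", "value") %>%
    arrange(.data$metric, .data$stratum_type, .data$species, .data$stratum)
}
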