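#' Promoter alignment container
#'
#' Aligned upstream regions over a fixed window: one gapped row per species
#' per promoter, all rows of one promoter with the same column count, plus a
#' per-row genomic offset for report coordinates.
#'
#' @param df Tibble with `promoter_id`, `species`, `aligned` (gapped
#'   sequence) and optionally `offset` (default 0).
#' @return A `zf_promoters` tibble.
#' @export
promoter_alignment <- function(df) {
  stopifnot_cols(df, c("promoter_id", "species", "aligned"), "promoters")
  if (!"offset" %in% names(df)) df$offset <- 0L
  widths <- tapply(nchar(df$aligned), df$promoter_id, function(w) length(unique(w)))
  if (any(widths != 1)) {
    abort("all rows of one promoter must have the same aligned width")
  }
  structure(as_tibble(df), class = c("zf_promoters", class(as_tibble(df))))
}

#' Read aligned promoter blocks from FASTA
#'
#' Headers are `>promoter_id|species` or `>promoter_id|species|offset=N`.
#'
#' @param path Aligned FASTA path.
#' @return A [promoter_alignment()] tibble.
#' @export
read_promoter_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  parts <- str_split(names(seqs), "\\|")
  offset <- map_int(parts, function(p) {
    off <- grep("^offset=", p, value = TRUE)
    if (length(off) == 1) as.integer(sub("^offset=", "", off)) else 0L
  })
  promoter_alignment(tibble(
    promoter_id = map_chr(parts, 1),
    species = map_chr(parts, 2),
    offset = offset,
    aligned = unname(as.character(seqs))
  ))
}

#' Write aligned promoter blocks to FASTA
#' @param promoters A [promoter_alignment()] tibble.
#' @param path Output path.
#' @export
write_promoter_fasta <- function(promoters, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(promoters))) {
    writeLines(sprintf(">%s|%s|offset=%d", promoters$promoter_id[i],
                       promoters$species[i], promoters$offset[i]), con)
    writeLines(promoters$aligned[i], con)
  }
  invisible(path)
}

# log-odds score matrix (bits) with a small pseudocount
pwm_score_matrix <- function(pwm, background = rep(0.25, 4),
                             pseudocount = 0.001) {
  p <- (unclass(pwm) + pseudocount) / (1 + 4 * pseudocount)
  log2(p / background)
}

# exact score distribution under the background via dynamic programming over
# the discretized per-column scores
pwm_score_distribution <- function(score_mat, background = rep(0.25, 4),
                                   granularity = 1000L) {
  L <- ncol(score_mat)
  col_min <- apply(score_mat, 2, min)
  rng <- sum(apply(score_mat, 2, max)) - sum(col_min)
  eps <- if (rng > 0) rng / granularity else 1
  int_mat <- matrix(as.integer(round(sweep(score_mat, 2, col_min) / eps)),
                    nrow = 4)
  max_total <- sum(apply(int_mat, 2, max))
  dist <- numeric(max_total + 1L)
  dist[1] <- 1
  for (j in seq_len(L)) {
    nd <- numeric(max_total + 1L)
    for (b in 1:4) {
      s <- int_mat[b, j]
      idx <- which(dist > 0)
      nd[idx + s] <- nd[idx + s] + dist[idx] * background[b]
    }
    dist <- nd
  }
  tail_p <- rev(cumsum(rev(dist)))
  tail_p <- pmin(tail_p, 1)
  list(int_mat = int_mat, tail_p = tail_p, eps = eps, col_min = col_min)
}

scan_one_strand <- function(codes, score_mat, dist, strand) {
  L <- ncol(score_mat)
  n <- length(codes)
  if (n < L) {
    return(list(start = integer(), strand = character(),
                score = numeric(), p_value = numeric()))
  }
  n_win <- n - L + 1L
  total_int <- rep(0L, n_win)
  total_real <- rep(0, n_win)
  ok <- rep(TRUE, n_win)
  for (j in seq_len(L)) {
    cj <- codes[j:(j + n_win - 1L)]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    total_int <- total_int + dist$int_mat[cbind(cj, j)]
    total_real <- total_real + score_mat[cbind(cj, j)]
  }
  list(start = which(ok) - 1L, strand = rep(strand, sum(ok)),
       score = total_real[ok],
       p_value = dist$tail_p[total_int[ok] + 1L])
}

#' Scan a sequence with a PWM using exact p-values
#'
#' Log-odds scores (bits, small pseudocount) at every position on both
#' strands; the p-value of a score is the exact probability under the
#' background of scoring at least as high, computed by dynamic programming
#' over the discretized score distribution. Sites with `p <= p_threshold`
#' are reported; `p_threshold = 1` reports every position.
#'
#' @param sequence DNA string (gaps and non-ACGT positions yield no site).
#' @param pwm A PWM.
#' @param background Base frequencies summing to 1.
#' @param p_threshold Site p-value threshold (default 1e-4).
#' @param granularity Number of discretization bins over the score range.
#' @param pseudocount Added to PWM probabilities before log-odds.
#' @param both_strands Scan the reverse complement too.
#' @return Tibble `start` (0-based, leftmost coordinate), `strand`, `score`,
#'   `p_value`.
#' @export
scan_pwm <- function(sequence, pwm, background = rep(0.25, 4),
                     p_threshold = 1e-4, granularity = 1000L,
                     pseudocount = 0.001, both_strands = TRUE) {
  if (abs(sum(background) - 1) > 1e-9) abort("background must sum to 1")
  codes <- match(seq_chars(toupper(sequence)), DNA_BASES)
  sm_p <- pwm_score_matrix(pwm, background, pseudocount)
  dist_p <- pwm_score_distribution(sm_p, background, granularity)
  hits <- list(scan_one_strand(codes, sm_p, dist_p, "+"))
  if (both_strands) {
    rc <- pwm_reverse_complement(pwm)
    sm_m <- pwm_score_matrix(rc, background, pseudocount)
    dist_m <- pwm_score_distribution(sm_m, background, granularity)
    hits[[2]] <- scan_one_strand(codes, sm_m, dist_m, "-")
  }
  out <- tibble(start = unlist(map(hits, "start")),
                strand = unlist(map(hits, "strand")),
                score = unlist(map(hits, "score")),
                p_value = unlist(map(hits, "p_value")))
  out %>%
    filter(.data$p_value <= p_threshold) %>%
    arrange(.data$start, .data$strand)
}

#' Scan aligned promoters with a set of PWMs
#'
#' Gaps are removed per row before scanning and site coordinates are mapped
#' back to alignment columns, so cross-species distances can be measured in
#' alignment space.
#'
#' @param promoters A [promoter_alignment()] tibble.
#' @param pwms Named list of PWMs.
#' @inheritParams scan_pwm
#' @return Tibble `pwm_id`, `promoter_id`, `species`, `start` (ungapped,
#'   0-based), `aln_col` (0-based alignment column of the site start),
#'   `strand`, `score`, `p_value`.
#' @export
scan_promoters <- function(promoters, pwms, background = rep(0.25, 4),
                           p_threshold = 1e-4, granularity = 1000L,
                           pseudocount = 0.001, both_strands = TRUE) {
  # per-PWM scoring structures computed once
  engines <- map(pwms, function(pwm) {
    sm_p <- pwm_score_matrix(pwm, background, pseudocount)
    eng <- list(sm_p = sm_p,
                dist_p = pwm_score_distribution(sm_p, background, granularity))
    if (both_strands) {
      rc <- pwm_reverse_complement(pwm)
      eng$sm_m <- pwm_score_matrix(rc, background, pseudocount)
      eng$dist_m <- pwm_score_distribution(eng$sm_m, background, granularity)
    }
    eng
  })
  acc <- list()
  for (i in seq_len(nrow(promoters))) {
    chars <- seq_chars(promoters$aligned[i])
    ungapped_cols <- which(chars != "-") - 1L  # aln col per ungapped offset
    codes <- match(chars[chars != "-"], DNA_BASES)
    for (id in names(pwms)) {
      eng <- engines[[id]]
      strands <- list(scan_one_strand(codes, eng$sm_p, eng$dist_p, "+"))
      if (both_strands) {
        strands[[2]] <- scan_one_strand(codes, eng$sm_m, eng$dist_m, "-")
      }
      for (h in strands) {
        keep <- which(h$p_value <= p_threshold)
        if (length(keep) == 0) next
        acc[[length(acc) + 1L]] <- list(
          pwm_id = rep(id, length(keep)),
          promoter_id = rep(promoters$promoter_id[i], length(keep)),
          species = rep(promoters$species[i], length(keep)),
          aln_col = ungapped_cols[h$start[keep] + 1L],
          start = h$start[keep], strand = h$strand[keep],
          score = h$score[keep], p_value = h$p_value[keep])
      }
    }
  }
  if (length(acc) == 0) {
    return(tibble(pwm_id = character(), promoter_id = character(),
                  species = character(), aln_col = integer(),
                  start = integer(), strand = character(),
                  score = numeric(), p_value = numeric()))
  }
  as_tibble(setNames(map(names(acc[[1]]), function(f)
    unlist(map(acc, f), use.names = FALSE)), names(acc[[1]])))
}

#' High-confidence reference binding sites
#'
#' A reference site is confident iff every species of the confidence set has
#' at least one site for the same PWM and promoter whose alignment-mapped
#' start lies within `window` columns. The empty set leaves every reference
#' site confident.
#'
#' @param sites [scan_promoters()] output across species.
#' @param reference Reference species label.
#' @param confidence_species Character vector of species (presets of size
#'   1-4; windows 15/25/50 are the preconfigured choices).
#' @param window Distance tolerance in alignment columns.
#' @return The reference-species site rows with a `confident` flag.
#' @export
high_confidence_sites <- function(sites, reference, confidence_species,
                                  window = 25L) {
  ref_sites <- filter(sites, .data$species == reference)
  if (nrow(ref_sites) == 0) return(mutate(ref_sites, confident = logical(0)))
  conf <- rep(TRUE, nrow(ref_sites))
  for (sp in confidence_species) {
    sp_sites <- filter(sites, .data$species == sp)
    key <- paste(sp_sites$pwm_id, sp_sites$promoter_id)
    by_key <- split(sp_sites$aln_col, key)
    rk <- paste(ref_sites$pwm_id, ref_sites$promoter_id)
    conf <- conf & map_lgl(seq_len(nrow(ref_sites)), function(i) {
      cols <- by_key[[rk[i]]]
      !is.null(cols) && any(abs(cols - ref_sites$aln_col[i]) <= window)
    })
  }
  mutate(ref_sites, confident = conf)
}

#' Per-species binding conservation fractions
#'
#' For every evaluated species (neither the reference nor a species used to
#' establish confidence): the fraction of confident reference sites with a
#' species site within `window` alignment columns, and the fraction of bound
#' reference promoters (>=1 confident site) whose orthologous region is also
#' bound (>=1 species site within `window` of any confident site).
#'
#' @param confident_sites Output of [high_confidence_sites()] (only rows with
#'   `confident = TRUE` are used).
#' @param sites All species' sites.
#' @param reference Reference species.
#' @param exclude_species Species excluded from evaluation (the confidence
#'   set).
#' @param window Distance tolerance in alignment columns.
#' @return Tibble per (`pwm_id`, `species`) with site- and promoter-level
#'   conservation counts and fractions.
#' @export
conservation_fractions <- function(confident_sites, sites, reference,
                                   exclude_species = character(),
                                   window = 25L) {
  conf <- filter(confident_sites, .data$confident)
  eval_species <- setdiff(unique(sites$species),
                          c(reference, exclude_species))
  out <- map(eval_species, function(sp) {
    sp_sites <- filter(sites, .data$species == sp)
    key <- paste(sp_sites$pwm_id, sp_sites$promoter_id)
    by_key <- split(sp_sites$aln_col, key)
    ck <- paste(conf$pwm_id, conf$promoter_id)
    conserved <- map_lgl(seq_len(nrow(conf)), function(i) {
      cols <- by_key[[ck[i]]]
      !is.null(cols) && any(abs(cols - conf$aln_col[i]) <= window)
    })
    conf %>%
      mutate(conserved = conserved) %>%
      group_by(.data$pwm_id) %>%
      summarise(
        n_confident_sites = n(),
        n_sites_conserved = sum(.data$conserved),
        fraction_sites_conserved = mean(.data$conserved),
        n_bound_promoters = length(unique(.data$promoter_id)),
        n_promoters_conserved = length(unique(.data$promoter_id[.data$conserved])),
        fraction_promoters_conserved = n_promoters_conserved / n_bound_promoters,
        .groups = "drop") %>%
      mutate(species = sp, .before = 1)
  }) %>% list_rbind()
  out
}

#' Label TF constructs by DNA-contacting-residue conservation
#'
#' Per (TF, species): `absent` when the species lacks a 1-to-1 ortholog;
#' `diverged_here` when at least one of the construct's domains diverged in
#' that species; `conserved_all` when no species diverged; otherwise
#' `conserved_here_diverged_elsewhere`.
#'
#' @param tf_map Tibble `pwm_id`, `ref_gene` linking motifs to reference
#'   genes.
#' @param orthogroups Orthogroup tibble.
#' @param domain_calls Pooled per-domain divergence calls.
#' @param species All species labels (to enumerate absences).
#' @param reference Reference species.
#' @return Tibble `pwm_id`, `species`, `label`.
#' @export
classify_tf_constructs <- function(tf_map, orthogroups, domain_calls,
                                   species, reference) {
  non_ref <- setdiff(species, reference)
  map(seq_len(nrow(tf_map)), function(i) {
    gene <- tf_map$ref_gene[i]
    og <- filter(orthogroups, .data$ref_gene == gene)
    calls <- filter(domain_calls, .data$group_id %in% unique(og$group_id),
                    .data$evaluable)
    diverged_sp <- unique(calls$species[calls$diverged])
    tibble(pwm_id = tf_map$pwm_id[i], species = non_ref,
           label = case_when(
             !(non_ref %in% og$species) ~ "absent",
             non_ref %in% diverged_sp ~ "diverged_here",
             length(diverged_sp) == 0 ~ "conserved_all",
             TRUE ~ "conserved_here_diverged_elsewhere"
           ))
  }) %>% list_rbind()
}

#' Compare binding conservation of conserved versus diverged TFs
#'
#' Within each species, conservation fractions are rank-normalized to
#' `[0, 1]` (average ranks for ties; a lone observation maps to 0.5), pooled
#' across species, and the fully conserved TFs are compared to the TFs
#' diverged in that species with a two-sided Wilcoxon rank-sum test.
#'
#' @param fractions [conservation_fractions()] output.
#' @param tf_classes [classify_tf_constructs()] output.
#' @param value Which fraction column to compare.
#' @return List `values` (normalized observations), `test` (pooled Wilcoxon),
#'   `medians` (per species and label).
#' @export
compare_conserved_vs_diverged <- function(fractions, tf_classes,
                                          value = "fraction_promoters_conserved") {
  df <- fractions %>%
    inner_join(tf_classes, by = c("pwm_id", "species")) %>%
    filter(.data$label %in% c("conserved_all", "diverged_here"))
  df <- df %>%
    group_by(.data$species) %>%
    mutate(normalized = normalize_ranks(.data[[value]])) %>%
    ungroup()
  conserved <- df$normalized[df$label == "conserved_all"]
  diverged <- df$normalized[df$label == "diverged_here"]
  if (length(conserved) == 0 || length(diverged) == 0) {
    abort("need at least one conserved and one diverged observation")
  }
  medians <- df %>%
    group_by(.data$species, .data$label) %>%
    summarise(median_fraction = stats::median(.data[[value]]),
              n = n(), .groups = "drop")
  list(values = df, test = wilcoxon_rank_sum(conserved, diverged),
       medians = medians)
}
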