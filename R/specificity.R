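#' The C2H2-ZF protein-DNA contact model
#'
#' Edges between helix positions (-1, 2, 3, 6) and target-site base positions
#' b1..b4 (optionally on the complementary strand). The four canonical
#' contacts (6-b1, 3-b2, -1-b3, 2-b4') are always present; the default adds
#' three secondary contacts for a 7-edge expanded model.
#'
#' @param extended Include the three secondary contacts (default TRUE).
#' @return Tibble `helix_pos`, `base_pos`, `complementary`, `canonical`.
#' @export
zf_contact_model <- function(extended = TRUE) {
  canonical <- tibble(
    helix_pos = c(6L, 3L, -1L, 2L),
    base_pos = c(1L, 2L, 3L, 4L),
    complementary = c(FALSE, FALSE, FALSE, TRUE),
    canonical = TRUE
  )
  if (!extended) return(canonical)
  bind_rows(canonical, tibble(
    helix_pos = c(6L, -1L, 2L),
    base_pos = c(2L, 4L, 3L),
    complementary = c(FALSE, TRUE, TRUE),
    canonical = FALSE
  ))
}

read_baseline_code <- function() {
  path <- system.file("extdata", "baseline_zf_code.tsv", package = "polyzf")
  if (!nzchar(path)) abort("bundled baseline code table not found")
  read_tsv_plain(path)
}

#' The bundled deterministic specificity predictor
#'
#' Maps each DNA-contacting residue to a base-preference column via the
#' bundled lookup table and combines multi-edge contributions per base
#' position by a normalized product. `flavor` selects deterministic variants
#' that sharpen or flatten the table (exponent transform), standing in for
#' independently trained predictors so consensus filtering can run
#' hermetically. The table is versioned data, not a trained model.
#'
#' @param flavor `"primary"` (table as-is), `"sharp"` (exponent 1.5) or
#'   `"flat"` (exponent 0.6).
#' @param contact_model A [zf_contact_model()].
#' @return A `zf_predictor` list usable with [predict_specificity()].
#' @export
baseline_predictor <- function(flavor = c("primary", "sharp", "flat"),
                               contact_model = zf_contact_model()) {
  flavor <- match.arg(flavor)
  alpha <- switch(flavor, primary = 1, sharp = 1.5, flat = 0.6)
  tab <- read_baseline_code()
  mat <- as.matrix(tab[, DNA_BASES])^alpha
  mat <- mat / rowSums(mat)
  structure(list(name = paste0("baseline_", flavor),
                 positions = tab$position, residues = tab$residue,
                 table = mat, contact_model = contact_model),
            class = "zf_predictor")
}

#' A predictor backed by externally supplied per-domain PWMs
#'
#' Plugs any external specificity predictor into the pipeline: PWMs in MEME
#' minimal format (or a named list) keyed by domain id are returned verbatim
#' by [predict_specificity()]; domains without an entry are flagged.
#'
#' @param pwms Named list of `zf_pwm` (length 4) or a MEME file path.
#' @param name Predictor label.
#' @return A `zf_predictor`.
#' @export
table_predictor <- function(pwms, name = "external") {
  if (is.character(pwms)) pwms <- read_meme(pwms)
  structure(list(name = name, lookup = pwms), class = "zf_predictor")
}

base_preference <- function(predictor, helix_pos, residue) {
  hit <- which(predictor$positions == helix_pos &
                 predictor$residues == residue)
  if (length(hit) == 0) return(rep(0.25, 4))  # unknown residue: uniform
  as.numeric(predictor$table[hit[1], ])
}

complement_column <- function(p) rev(p)  # rows A,C,G,T -> T,G,C,A

# residues at helix positions -1, 2, 3, 6 from an 8-char -1..7 window
window_specificity_residues <- function(helix_window) {
  ch <- seq_chars(helix_window)
  setNames(ch[c(1, 3, 4, 7)], c("-1", "2", "3", "6"))
}

#' Predict per-domain binding specificity over b1..b4
#'
#' Deterministic for a fixed predictor. The bundled baseline combines, for
#' each base position, the base preferences of every contacting residue
#' (complemented for complementary-strand edges) by product and normalizes.
#' Domains with a gap at any specificity position get no prediction and are
#' flagged `predicted = FALSE`.
#'
#' @param domains Domain tibble with `helix_window` (and `protein_id`,
#'   `start` for the domain id).
#' @param predictor A `zf_predictor`.
#' @return Tibble `domain_id`, `predicted`, `pwm` (list of length-4 PWMs).
#' @export
predict_specificity <- function(domains, predictor = baseline_predictor()) {
  ids <- domain_key(domains)
  n <- nrow(domains)
  predicted <- logical(n)
  pwms <- vector("list", n)
  if (!is.null(predictor$lookup)) {
    for (i in seq_len(n)) {
      hit <- predictor$lookup[[ids[i]]]
      predicted[i] <- !is.null(hit)
      pwms[i] <- list(hit)
    }
    return(tibble(domain_id = ids, predicted = predicted, pwm = pwms))
  }
  cm <- predictor$contact_model
  edges_by_base <- map(1:4, function(b) {
    e <- cm[cm$base_pos == b, ]
    list(helix_pos = as.character(e$helix_pos), complementary = e$complementary)
  })
  pref_key <- paste(predictor$positions, predictor$residues)
  lookup_pref <- function(pos, res) {
    hit <- match(paste(pos, res), pref_key)
    if (is.na(hit)) rep(0.25, 4) else as.numeric(predictor$table[hit, ])
  }
  for (i in seq_len(n)) {
    res <- window_specificity_residues(domains$helix_window[i])
    if (any(res == "-")) next  # gapped specificity position: no prediction
    mat <- matrix(0, 4, 4)
    for (b in 1:4) {
      e <- edges_by_base[[b]]
      contrib <- rep(1, 4)
      for (k in seq_along(e$helix_pos)) {
        p <- lookup_pref(e$helix_pos[k], res[[e$helix_pos[k]]])
        if (e$complementary[k]) p <- complement_column(p)
        contrib <- contrib * p
      }
      mat[, b] <- if (sum(contrib) == 0) rep(0.25, 4) else
        contrib / sum(contrib)
    }
    predicted[i] <- TRUE
    pwms[[i]] <- new_pwm(mat)
  }
  tibble(domain_id = ids, predicted = predicted, pwm = pwms)
}

#' Build specificity records with consensus confidence
#'
#' Predicts with the primary predictor and every secondary predictor, stores
#' the average b1..b4 PCC between the primary and each secondary, and marks a
#' record confident when any secondary average PCC exceeds `threshold`.
#'
#' @param domains Domain tibble.
#' @param primary Primary `zf_predictor`.
#' @param secondaries Named list of secondary predictors.
#' @param threshold Confidence threshold on the average PCC (thresholds 0,
#'   0.25, 0.5, 0.75 are the preconfigured operating points).
#' @return Tibble `domain_id`, `pwm`, per-secondary `pcc_<name>` columns,
#'   `max_secondary_pcc`, `confident`.
#' @export
specificity_records <- function(domains,
                                primary = baseline_predictor("primary"),
                                secondaries = list(
                                  sharp = baseline_predictor("sharp"),
                                  flat = baseline_predictor("flat")),
                                threshold = 0.25) {
  prim <- predict_specificity(domains, primary)
  recs <- prim %>% rename(pwm_primary = "pwm")
  for (nm in names(secondaries)) {
    sec <- predict_specificity(domains, secondaries[[nm]])
    recs[[paste0("pcc_", nm)]] <- map2_dbl_(recs$pwm_primary, sec$pwm,
                                            function(a, b) {
      if (is.null(a) || is.null(b)) return(NA_real_)
      pwm_pcc(a, b)$average
    })
  }
  pcc_cols <- paste0("pcc_", names(secondaries))
  recs$max_secondary_pcc <- do.call(pmax, c(recs[pcc_cols], na.rm = TRUE))
  recs %>%
    mutate(confident = .data$predicted &
             !is.na(.data$max_secondary_pcc) &
             .data$max_secondary_pcc > threshold) %>%
    rename(pwm = "pwm_primary")
}

map2_dbl_ <- function(x, y, f) {
  vapply(seq_along(x), function(i) as.numeric(f(x[[i]], y[[i]])), numeric(1))
}

#' Apply the consensus-confidence filter
#'
#' @param records Output of [specificity_records()].
#' @param threshold Average-PCC threshold; keep iff any secondary exceeds it.
#' @return The confident subset.
#' @export
consensus_filter <- function(records, threshold = 0.25) {
  filter(records, .data$predicted,
         !is.na(.data$max_secondary_pcc),
         .data$max_secondary_pcc > threshold)
}

#' Specificity change of divergent domains versus their reference domains
#'
#' For each diverged, aligned domain pair with confident predictions on both
#' sides: the per-position PCCs to the reference prediction, their minimum
#' and sum, and per species the fraction of divergent domains whose minimum
#' PCC falls below `cutoff`.
#'
#' @param records Confident [specificity_records()] (reference and species
#'   domains together).
#' @param domain_calls Per-domain divergence calls (from
#'   [call_divergent_sites()], pooled).
#' @param cutoff Per-position PCC cutoff (default 0.25).
#' @return List `domains` (per divergent domain) and `by_species` (fractions).
#' @export
divergent_specificity_summary <- function(records, domain_calls,
                                          cutoff = 0.25) {
  pwms <- setNames(records$pwm, records$domain_id)
  conf <- setNames(records$confident, records$domain_id)
  rows <- domain_calls %>%
    filter(.data$evaluable, .data$diverged) %>%
    split(seq_len(sum(domain_calls$evaluable & domain_calls$diverged,
                      na.rm = TRUE))) %>%
    map(function(d) {
      a <- pwms[[d$ref_domain]]; b <- pwms[[d$sp_domain]]
      if (is.null(a) || is.null(b) ||
          !isTRUE(conf[[d$ref_domain]]) || !isTRUE(conf[[d$sp_domain]])) {
        return(NULL)
      }
      pcc <- pwm_pcc(a, b)
      tibble(group_id = d$group_id, species = d$species,
             ref_domain = d$ref_domain, sp_domain = d$sp_domain,
             min_pcc = min(pcc$per_position), sum_pcc = sum(pcc$per_position),
             avg_pcc = pcc$average)
    }) %>% list_rbind()
  by_species <- rows %>%
    group_by(.data$species) %>%
    summarise(n_divergent = n(),
              n_changed = sum(.data$min_pcc < cutoff),
              fraction_changed = mean(.data$min_pcc < cutoff),
              .groups = "drop")
  list(domains = rows, by_species = by_species)
}

#' Predicted specificity change versus phylogenetic distance
#'
#' For each reference domain with aligned, confidently predicted orthologous
#' domains in at least `min_species` species, the Spearman correlation
#' between the patristic reference-to-species distance and the average PCC of
#' the species prediction to the reference prediction. Constant-PCC profiles
#' are undefined and recorded as rho 0 with `all_tied = TRUE`.
#'
#' @param records Specificity records (confidence flags used).
#' @param domain_calls Pooled per-domain divergence calls (aligned pairs).
#' @param species_tree Rooted `phylo` with branch lengths.
#' @param reference Reference species label.
#' @param min_species Minimum species for a per-domain correlation.
#' @return List `per_domain` (rho per reference domain), `summary` (fractions
#'   of domains with rho < 0 and < -0.5), `pcc_by_species` (pooled PCCs).
#' @export
specificity_vs_distance <- function(records, domain_calls, species_tree,
                                    reference, min_species = 3L) {
  dist_mat <- ape::cophenetic.phylo(species_tree)
  pwms <- setNames(records$pwm, records$domain_id)
  conf <- setNames(records$confident, records$domain_id)
  pairs <- domain_calls %>%
    filter(map_lgl(.data$ref_domain, function(d) isTRUE(conf[[d]])),
           map_lgl(.data$sp_domain, function(d) isTRUE(conf[[d]])))
  if (nrow(pairs) == 0) {
    return(list(per_domain = tibble(), summary = tibble(),
                pcc_by_species = tibble()))
  }
  pairs$avg_pcc <- map2_dbl_(pairs$ref_domain, pairs$sp_domain,
                             function(a, b) pwm_pcc(pwms[[a]], pwms[[b]])$average)
  pairs$distance <- dist_mat[reference, ][pairs$species]
  per_domain <- pairs %>%
    group_by(.data$group_id, .data$ref_domain) %>%
    summarise(n_species = n(),
              rho = if (n() >= min_species)
                spearman(.data$distance, .data$avg_pcc)$rho else NA_real_,
              all_tied = if (n() >= min_species)
                spearman(.data$distance, .data$avg_pcc)$all_tied else NA,
              insufficient = n() < min_species,
              .groups = "drop")
  evaluated <- filter(per_domain, !.data$insufficient)
  summary <- tibble(
    n_domains = nrow(evaluated),
    fraction_rho_negative = mean(evaluated$rho < 0),
    fraction_rho_below_m05 = mean(evaluated$rho < -0.5)
  )
  pcc_by_species <- pairs %>%
    group_by(.data$species) %>%
    summarise(n = n(), median_pcc = stats::median(.data$avg_pcc),
              mean_pcc = mean(.data$avg_pcc), .groups = "drop")
  list(per_domain = per_domain, summary = summary,
       pcc_by_species = pcc_by_species)
}
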