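#' C2H2-ZF structural pattern configuration
#'
#' Spacer-length ranges and the large-hydrophobic set for the C2H2-ZF
#' structural expression `C-X(c1)-C-X(c2)-Psi-X(2)-H-X(c3)-[H|C]`. The default
#' ranges cover the classic C2H2 envelope; `preset = "strict"` fixes the
#' spacers at their literal counts (2, 8, 3).
#'
#' @param c1,c2,c3 Integer length-2 vectors giving inclusive spacer ranges.
#' @param psi Characters allowed at the large-hydrophobic position.
#' @param preset Optional `"strict"` for the fixed-count reading.
#' @return A `zf_pattern` list.
#' @export
zf_pattern <- function(c1 = c(2L, 4L), c2 = c(8L, 12L), c3 = c(3L, 5L),
                       psi = c("F", "Y", "W", "L", "I", "V", "M"),
                       preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "strict")
    c1 <- c(2L, 2L); c2 <- c(8L, 8L); c3 <- c(3L, 3L)
  }
  for (r in list(c1, c2, c3)) {
    if (length(r) != 2 || any(r < 0) || r[1] > r[2]) {
      abort("spacer ranges must be length-2 non-decreasing and non-negative")
    }
  }
  structure(list(c1 = as.integer(c1), c2 = as.integer(c2),
                 c3 = as.integer(c3), psi = toupper(psi)),
            class = "zf_pattern")
}

zf_pattern_regex <- function(pattern) {
  sprintf("(C)(.{%d,%d}?)(C)(.{%d,%d}?)([%s])(.{2})(H)(.{%d,%d}?)([HC])",
          pattern$c1[1], pattern$c1[2], pattern$c2[1], pattern$c2[2],
          paste(pattern$psi, collapse = ""), pattern$c3[1], pattern$c3[2])
}

# index of helix position p given the 0-based index of position 7
helix_position_index <- function(pos7_index, position) {
  ifelse(position == -1L, pos7_index - 7L, pos7_index - (7L - position))
}

#' Match the C2H2-ZF structural expression in a protein sequence
#'
#' Scans left to right; overlapping candidates are resolved left-greedily
#' (earliest start wins, shortest spacers at each level, and scanning resumes
#' after the reported match). Helix position 7 is mapped to the anchor
#' histidine of the `H-X(c3)-[H|C]` block; positions -1 and 1..6 are the seven
#' residues immediately preceding it.
#'
#' @param sequence Amino-acid string (20 residues plus X).
#' @param pattern A [zf_pattern()].
#' @return Tibble with 0-based half-open `start`, `end`, the 0-based
#'   `pos7_index`, and the 8-residue `helix_window` (positions -1..7).
#' @export
regex_match_c2h2 <- function(sequence, pattern = zf_pattern()) {
  check_aa_sequence(sequence)
  m <- gregexpr(zf_pattern_regex(pattern), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble(start = integer(), end = integer(),
                  pos7_index = integer(), helix_window = character()))
  }
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  cap_start <- attr(m, "capture.start")
  pos7 <- as.integer(cap_start[, 7]) - 1L
  tibble(
    start = starts, end = ends, pos7_index = pos7,
    helix_window = substr0(rep(sequence, length(starts)), pos7 - 7L, pos7 + 1L)
  )
}

#' Parse a HMMER per-domain hit table (domtblout)
#'
#' Reads the standard whitespace-delimited HMMER3 `--domtblout` format and
#' attaches per-HMM gathering thresholds. Envelope coordinates are converted
#' from 1-based inclusive to 0-based half-open.
#'
#' @param path Path to the domtblout file.
#' @param thresholds Tibble with columns `hmm_id`, `gathering_threshold` (or a
#'   named numeric vector).
#' @param default_threshold Optional threshold for HMM ids absent from
#'   `thresholds`; without it an unknown id is an error.
#' @return Tibble of domain hits: `protein_id`, `hmm_id`, `bitscore`,
#'   `evalue`, `envelope_start`, `envelope_end`, `gathering_threshold`.
#' @export
read_domtblout <- function(path, thresholds, default_threshold = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.numeric(thresholds) && !is.null(names(thresholds))) {
    thresholds <- tibble(hmm_id = names(thresholds),
                         gathering_threshold = unname(thresholds))
  }
  stopifnot_cols(thresholds, c("hmm_id", "gathering_threshold"), "thresholds")
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) {
    return(tibble(protein_id = character(), hmm_id = character(),
                  bitscore = numeric(), evalue = numeric(),
                  envelope_start = integer(), envelope_end = integer(),
                  gathering_threshold = numeric()))
  }
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  hits <- map2(fields, rows, function(f, ln) {
    if (length(f) < 22) {
      abort(sprintf("malformed domtblout record at line %d (%d fields)",
                    ln, length(f)))
    }
    num <- suppressWarnings(as.numeric(f[c(13, 14, 20, 21)]))
    if (anyNA(num)) {
      abort(sprintf("malformed domtblout record at line %d (non-numeric field)",
                    ln))
    }
    tibble(protein_id = f[1], hmm_id = f[4], bitscore = num[2],
           evalue = num[1], envelope_start = as.integer(num[3]) - 1L,
           envelope_end = as.integer(num[4]))
  }) %>% list_rbind()
  out <- left_join(hits, thresholds, by = "hmm_id")
  unknown <- is.na(out$gathering_threshold)
  if (any(unknown)) {
    if (is.null(default_threshold)) {
      abort(sprintf("no gathering threshold for HMM id(s): %s",
                    paste(unique(out$hmm_id[unknown]), collapse = ", ")))
    }
    out$gathering_threshold[unknown] <- default_threshold
  }
  out
}

#' Call C2H2-ZF domains from hits plus the structural expression
#'
#' A hit becomes a domain only if its envelope fully contains a structural
#' regex match (hits without one are degenerate and dropped regardless of
#' score). Above-threshold matching hits are always kept; sub-threshold
#' matching hits are rescued only when the protein carries at least one
#' above-threshold kept domain.
#'
#' @param proteins Tibble with `protein_id`, `gene_id`, `species`, `sequence`.
#' @param hits Tibble as returned by [read_domtblout()], or `NULL` for
#'   pure-regex scanning, in which case every match is a domain with
#'   `above_threshold = TRUE`.
#' @param pattern A [zf_pattern()].
#' @return Tibble of domains sorted by protein and start: coordinates,
#'   `pos7_index`, `helix_window`, `bitscore`, `above_threshold`, `rescued`.
#' @export
call_domains <- function(proteins, hits = NULL, pattern = zf_pattern()) {
  stopifnot_cols(proteins, c("protein_id", "gene_id", "species", "sequence"),
                 "proteins")
  if (anyDuplicated(proteins[, c("protein_id", "species")])) {
    abort("(protein_id, species) pairs must be unique")
  }
  per_protein <- function(prow) {
    matches <- regex_match_c2h2(prow$sequence, pattern)
    base <- function(m) {
      tibble(protein_id = prow$protein_id, gene_id = prow$gene_id,
             species = prow$species, start = m$start, end = m$end,
             pos7_index = m$pos7_index, helix_window = m$helix_window)
    }
    if (is.null(hits)) {
      out <- base(matches)
      out$hmm_id <- NA_character_
      out$bitscore <- NA_real_
      out$above_threshold <- rep(TRUE, nrow(out))
      out$rescued <- rep(FALSE, nrow(out))
      return(out)
    }
    h <- filter(hits, .data$protein_id == prow$protein_id)
    if (nrow(h) == 0 || nrow(matches) == 0) return(NULL)
    cand <- pmap(h, function(...) {
      hit <- list(...)
      inside <- matches$start >= hit$envelope_start &
        matches$end <= hit$envelope_end
      if (!any(inside)) return(NULL)
      m <- matches[which(inside)[1], , drop = FALSE]  # leftmost contained match
      out <- base(m)
      out$hmm_id <- hit$hmm_id
      out$bitscore <- hit$bitscore
      out$above_threshold <- hit$bitscore >= hit$gathering_threshold
      out
    }) %>% list_rbind()
    if (is.null(cand) || nrow(cand) == 0) return(NULL)
    # one domain per distinct match span: best-scoring supporting hit wins
    cand <- cand %>%
      arrange(.data$start, desc(.data$above_threshold), desc(.data$bitscore)) %>%
      distinct(.data$start, .data$end, .keep_all = TRUE)
    if (!any(cand$above_threshold)) return(NULL)
    cand$rescued <- !cand$above_threshold
    cand
  }
  out <- proteins %>%
    split(seq_len(nrow(proteins))) %>%
    map(per_protein) %>%
    list_rbind()
  if (nrow(out) == 0) return(out)
  arrange(out, .data$species, .data$protein_id, .data$start)
}

covering_sets <- function(windows_by_protein, universe) {
  # exact minimum set cover by subset enumeration, increasing size
  k <- length(windows_by_protein)
  for (s in seq_len(k)) {
    combos <- utils::combn(k, s, simplify = FALSE)
    covering <- keep(combos, function(idx) {
      length(setdiff(universe, unique(unlist(windows_by_protein[idx])))) == 0
    })
    if (length(covering) > 0) return(covering)
  }
  list()
}

#' Select representative isoforms per gene
#'
#' If a single isoform contains every unique helix window (-1..7 string) of
#' the gene, the longest such isoform is the representative (ties broken by
#' protein id). Otherwise a minimum-cardinality set of isoforms covering all
#' unique windows is chosen (exact search up to `exact_limit` candidate
#' isoforms, greedy beyond; ties prefer longer proteins, then smaller ids).
#'
#' @param domains Domain tibble from [call_domains()].
#' @param proteins Protein tibble (for isoform lengths).
#' @param exact_limit Max candidate isoforms for the exact cover search.
#' @return Tibble `gene_id`, `species`, `protein_id` of representatives.
#' @export
select_isoforms <- function(domains, proteins, exact_limit = 15L) {
  stopifnot_cols(domains, c("protein_id", "gene_id", "species", "helix_window"))
  if (nrow(domains) == 0) abort("no candidate proteins with called domains")
  lens <- setNames(nchar(proteins$sequence), proteins$protein_id)
  one_gene <- function(d) {
    wins <- split(d$helix_window, d$protein_id) %>% map(unique)
    universe <- unique(d$helix_window)
    prot_ids <- names(wins)
    covers_all <- map_lgl(wins, function(w) length(setdiff(universe, w)) == 0)
    if (any(covers_all)) {
      ids <- prot_ids[covers_all]
      ids <- ids[order(-lens[ids], ids)]
      chosen <- ids[1]
    } else if (length(prot_ids) <= exact_limit) {
      covering <- covering_sets(wins, universe)
      scored <- map(covering, function(idx) {
        ids <- sort(prot_ids[idx])
        list(ids = ids, len = sum(lens[ids]))
      })
      ord <- order(-map_dbl(scored, "len"),
                   map_chr(scored, function(s) paste(s$ids, collapse = "|")))
      chosen <- scored[[ord[1]]]$ids
    } else {
      chosen <- character()
      left <- universe
      while (length(left) > 0) {
        gain <- map_int(wins, function(w) length(intersect(w, left)))
        cand <- prot_ids[gain == max(gain)]
        cand <- cand[order(-lens[cand], cand)]
        chosen <- c(chosen, cand[1])
        left <- setdiff(left, wins[[cand[1]]])
        wins[[cand[1]]] <- character()
      }
    }
    tibble(gene_id = d$gene_id[1], species = d$species[1],
           protein_id = sort(chosen))
  }
  domains %>%
    split(paste(domains$species, domains$gene_id)) %>%
    map(one_gene) %>%
    list_rbind() %>%
    arrange(.data$species, .data$gene_id, .data$protein_id)
}

#' Assemble tandem-array structure over called domains
#'
#' Computes inter-domain linker sequences and lengths, array membership
#' (gap <= `max_array_gap`), canonical-linker status (length between
#' `canonical_min` and `canonical_max`; the consensus motif is recorded as a
#' separate flag, not required), and within-array position labels
#' (beginning/middle/end for arrays of 3+, beginning/end for pairs,
#' singleton otherwise).
#'
#' @param domains Domain tibble (one or more proteins).
#' @param proteins Protein tibble (for linker sequences).
#' @param max_array_gap Max inter-domain gap within one array.
#' @param canonical_min,canonical_max Canonical linker length bounds.
#' @param canonical_motif Regex anchored at the linker start, recorded as
#'   `motif_before`/`motif_after`.
#' @param motif_strict If `TRUE`, canonical linkers must also match the motif.
#' @return Domain tibble with linker/array annotation columns.
#' @export
build_arrays <- function(domains, proteins, max_array_gap = 12L,
                         canonical_min = 5L, canonical_max = 12L,
                         canonical_motif = "TGE[KR]P[FY].",
                         motif_strict = FALSE) {
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  one_protein <- function(d) {
    d <- arrange(d, .data$start)
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)])) {
      abort(sprintf("overlapping domains in protein %s", d$protein_id[1]))
    }
    s <- seqs[[d$protein_id[1]]]
    n <- nrow(d)
    gap_len <- if (n > 1) d$start[-1] - d$end[-n] else integer(0)
    gap_seq <- if (n > 1) {
      map_chr(seq_len(n - 1), function(i) substr0(s, d$end[i], d$start[i + 1]))
    } else character(0)
    is_canon <- gap_len >= canonical_min & gap_len <= canonical_max
    motif_ok <- str_detect(gap_seq, paste0("^", canonical_motif))
    if (motif_strict) is_canon <- is_canon & motif_ok
    d$linker_before <- c(NA_integer_, gap_len)
    d$linker_after <- c(gap_len, NA_integer_)
    d$linker_before_seq <- c(NA_character_, gap_seq)
    d$linker_after_seq <- c(gap_seq, NA_character_)
    d$canonical_before <- c(NA, is_canon)
    d$canonical_after <- c(is_canon, NA)
    d$motif_before <- c(NA, motif_ok)
    d$motif_after <- c(motif_ok, NA)
    d$canonically_linked <- (!is.na(d$canonical_before) & d$canonical_before) |
      (!is.na(d$canonical_after) & d$canonical_after)
    in_same_array <- gap_len <= max_array_gap
    d$array_id <- cumsum(c(1L, as.integer(!in_same_array)))
    d <- d %>%
      group_by(.data$array_id) %>%
      mutate(array_size = n(),
             array_position = case_when(
               .data$array_size == 1L ~ "singleton",
               row_number() == 1L ~ "beginning",
               row_number() == .data$array_size ~ "end",
               TRUE ~ "middle"
             )) %>%
      ungroup()
    d$in_array <- d$array_size > 1L
    border <- cbind(d$linker_before, d$linker_after)
    d$mean_border_linker <- rowMeans(border, na.rm = TRUE)
    d$mean_border_linker[is.nan(d$mean_border_linker)] <- NA_real_
    d$domain_ordinal <- seq_len(n)
    d
  }
  domains %>%
    split(domains$protein_id) %>%
    map(one_protein) %>%
    list_rbind() %>%
    arrange(.data$species, .data$protein_id, .data$start)
}

#' Write the per-domain report table
#'
#' Tab-separated domain table with 1-based inclusive coordinates: species,
#' protein, gene, domain ordinal, HMM id, e-value/bitscore when available, the
#' indices of helix positions -1 and 7, the -1..7 window, and the domain
#' subsequence.
#'
#' @param arrays Output of [build_arrays()].
#' @param proteins Protein tibble.
#' @param path Output path.
#' @export
write_domain_table <- function(arrays, proteins, path) {
  seqs <- setNames(proteins$sequence, proteins$protein_id)
  out <- arrays %>%
    mutate(
      pos_m1_index_1based = helix_position_index(.data$pos7_index, -1L) + 1L,
      pos7_index_1based = .data$pos7_index + 1L,
      start_1based = .data$start + 1L,
      end_1based = .data$end,
      domain_sequence = map2_chr_(seqs[.data$protein_id], .data$start,
                                  .data$end)
    ) %>%
    select("species", "protein_id", "gene_id", "domain_ordinal", "hmm_id",
           "bitscore", "above_threshold", "rescued", "pos_m1_index_1based",
           "pos7_index_1based", "helix_window", "start_1based", "end_1based",
           "domain_sequence", "canonically_linked", "array_id", "array_size",
           "array_position")
  write_tsv_plain(out, path,
                  "coordinates 1-based inclusive; helix window spans positions -1..7")
}

map2_chr_ <- function(seqs, start, end) {
  map_chr(seq_along(seqs), function(i) substr0(seqs[[i]], start[i], end[i]))
}
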