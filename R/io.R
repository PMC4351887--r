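#' Read a proteome FASTA with gene mapping
#'
#' @param path FASTA path.
#' @param species Species label attached to every record.
#' @param gene_map Optional tibble `protein_id`, `gene_id` (or TSV path with
#'   those columns). Without it, headers of the form `protein|gene` are
#'   parsed; otherwise the gene id defaults to the protein id.
#' @return Protein tibble `protein_id`, `gene_id`, `species`, `sequence`.
#' @export
read_proteome <- function(path, species, gene_map = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- map_chr(str_split(names(seqs), "\\s+"), 1)
  prot <- map_chr(str_split(ids, "\\|"), 1)
  gene <- map_chr(str_split(ids, "\\|"), function(p)
    if (length(p) >= 2) p[2] else p[1])
  out <- tibble(protein_id = prot, gene_id = gene, species = species,
                sequence = toupper(as.character(seqs)))
  if (!is.null(gene_map)) {
    if (is.character(gene_map)) gene_map <- read_tsv_plain(gene_map)
    stopifnot_cols(gene_map, c("protein_id", "gene_id"), "gene_map")
    out$gene_id <- gene_map$gene_id[match(out$protein_id, gene_map$protein_id)]
    if (anyNA(out$gene_id)) {
      abort("gene_map does not cover every protein in the FASTA")
    }
  }
  for (s in out$sequence) check_aa_sequence(s)
  out
}

#' Write a proteome FASTA (`protein|gene` headers)
#' @param proteins Protein tibble.
#' @param path Output path.
#' @export
write_proteome <- function(proteins, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(sprintf(">%s|%s", proteins$protein_id[i],
                       proteins$gene_id[i]), con)
    writeLines(proteins$sequence[i], con)
  }
  invisible(path)
}

#' Read pairwise ortholog lists
#'
#' One or more TSV files with columns `ref_gene`, `species`, `gene_id`.
#'
#' @param paths File path(s).
#' @return Combined pairs tibble.
#' @export
read_ortholog_pairs <- function(paths) {
  map(paths, function(p) {
    df <- read_tsv_plain(p)
    stopifnot_cols(df, c("ref_gene", "species", "gene_id"), p)
    df
  }) %>% list_rbind()
}

#' Read a population polymorphism table
#'
#' TSV with columns `gene_id`, `position` (1-based protein coordinate),
#' `minor_count`, `sample_size`.
#'
#' @param path File path.
#' @return Tibble with 0-based `ref_index`.
#' @export
read_polymorphisms <- function(path) {
  df <- read_tsv_plain(path)
  stopifnot_cols(df, c("gene_id", "position", "minor_count", "sample_size"),
                 path)
  df %>%
    mutate(ref_index = as.integer(.data$position) - 1L) %>%
    select("gene_id", "ref_index", "minor_count", "sample_size")
}

#' Read a sister-pair configuration (YAML)
#'
#' Expects `pairs:` as a list of two-element species lists.
#'
#' @param path YAML path.
#' @return Pairing tibble `species_a`, `species_b`.
#' @export
read_pairing_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pairs)) abort("pairing YAML must contain a 'pairs' list")
  tibble(species_a = map_chr(cfg$pairs, 1),
         species_b = map_chr(cfg$pairs, 2))
}

#' Write the orthogroup report table
#' @param orthogroups Orthogroup tibble.
#' @param proteins Protein tibble (for protein ids).
#' @param path Output path.
#' @export
write_orthogroup_table <- function(orthogroups, proteins, path) {
  out <- orthogroups %>%
    left_join(proteins %>%
                group_by(.data$species, .data$gene_id) %>%
                arrange(desc(nchar(.data$sequence)), .data$protein_id) %>%
                slice(1) %>%
                ungroup() %>%
                select("species", "gene_id", "protein_id"),
              by = c("species", "gene_id")) %>%
    select("group_id", "protein_id", "gene_id", "species", "provenance")
  write_tsv_plain(out, path, "one gene per retained species per group")
}

#' Write divergent sites as a per-site table (1-based positions)
#' @param sites Divergent-site tibble.
#' @param path Output path.
#' @export
write_site_table <- function(sites, path) {
  out <- mutate(sites, position = .data$ref_index + 1L) %>%
    select("group_id", "ref_gene", "species", "position", "ref_residue",
           "sp_residue", "class", "domain_id")
  write_tsv_plain(out, path, "positions 1-based in the reference protein")
}

#' Write binding sites in a BED-like table
#' @param sites [scan_promoters()] output.
#' @param pwms Named PWM list (for site lengths).
#' @param path Output path.
#' @export
write_binding_sites <- function(sites, pwms, path) {
  w <- map_int(pwms, ncol)
  out <- sites %>%
    mutate(end = .data$start + w[.data$pwm_id]) %>%
    select("promoter_id", "start", "end", "strand", "score", "p_value",
           "pwm_id", "species", "aln_col")
  write_tsv_plain(out, path, "start/end 0-based half-open within promoter")
}
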