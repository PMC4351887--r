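#' Pipeline parameters
#'
#' Analysis-stage knobs with the study defaults: consensus-confidence PCC
#' threshold 0.25, 25-bp conservation window over 2000-bp promoter windows,
#' canonical linkers of 5-12 residues, specificity positions -1/2/3/6.
#'
#' @param pattern A [zf_pattern()].
#' @param max_array_gap,canonical_min,canonical_max Array/linker bounds.
#' @param min_overlap Helix-window overlap for domain correspondence.
#' @param min_domains Poly-ZF threshold on reference domains.
#' @param pcc_threshold Consensus-confidence threshold.
#' @param scan_p_threshold Motif-scan site p-value threshold.
#' @param granularity Scan score-distribution bins.
#' @param window Site-conservation window (alignment columns).
#' @param confidence_species Species defining high-confidence sites (default:
#'   the four species closest to the reference in the species tree).
#' @param pairing Sister-pair tibble for clade support.
#' @return A list of parameters.
#' @export
pipeline_params <- function(pattern = zf_pattern(),
                            max_array_gap = 12L,
                            canonical_min = 5L, canonical_max = 12L,
                            min_overlap = 5L, min_domains = 2L,
                            pcc_threshold = 0.25,
                            scan_p_threshold = 1e-4,
                            granularity = 1000L,
                            window = 25L,
                            confidence_species = NULL,
                            pairing = default_clade_pairing()) {
  as.list(environment())
}

closest_species <- function(species_tree, reference, k = 4L) {
  d <- ape::cophenetic.phylo(species_tree)[reference, ]
  names(sort(d[names(d) != reference]))[seq_len(k)]
}

#' Run the full comparative analysis on a simulation (or equivalent inputs)
#'
#' Executes the stages in order: domain scanning and array construction,
#' orthogroup assembly, per-group alignment and divergence classification,
#' the three functional-constraint analyses plus folded spectra, specificity
#' prediction and distance trends, and the promoter binding-landscape
#' comparison. Every output is a tibble; a machine-readable manifest records
#' the seed and parameters. Deterministic for a fixed seed.
#'
#' @param sim A [simulate_families()] result (or a list with `proteins`,
#'   `ortholog_pairs`, `species_tree`, `reference`, `config`).
#' @param params A [pipeline_params()].
#' @param stages Stage subset to run (later stages need earlier ones).
#' @param hits Optional HMMER hit tibble; without it domains are called in
#'   pure-regex mode.
#' @return A `zf_pipeline` list of stage outputs plus `manifest`.
#' @export
run_pipeline <- function(sim, params = pipeline_params(),
                         stages = c("scan", "orthogroups", "divergence",
                                    "selection", "specificity", "landscape"),
                         hits = NULL) {
  stages <- match.arg(stages, several.ok = TRUE,
                      choices = c("scan", "orthogroups", "divergence",
                                  "selection", "specificity", "landscape"))
  tree <- sim$species_tree
  ref <- sim$reference
  res <- list(manifest = list(
    seed = sim$config$seed, reference = ref,
    species = tree$tip.label, n_genes = sim$config$n_genes,
    params = params[setdiff(names(params), c("pattern", "pairing"))],
    package_version = as.character(utils::packageVersion("polyzf"))))
  # --- scan ---------------------------------------------------------------
  domains <- call_domains(sim$proteins, hits = hits, pattern = params$pattern)
  reps <- select_isoforms(domains, sim$proteins)
  rep_domains <- semi_join(domains, reps, by = c("species", "protein_id"))
  arrays <- build_arrays(rep_domains, sim$proteins,
                         max_array_gap = params$max_array_gap,
                         canonical_min = params$canonical_min,
                         canonical_max = params$canonical_max)
  res$domains <- domains
  res$representatives <- reps
  res$arrays <- arrays
  if (!"orthogroups" %in% stages) return(structure(res, class = "zf_pipeline"))
  # --- orthogroups --------------------------------------------------------
  raw <- build_orthogroups(sim$ortholog_pairs, ref)
  og <- assemble_orthogroups(raw, ref, species_tree = tree,
                             proteins = sim$proteins)
  og <- filter_polyzf(og, arrays, ref, min_domains = params$min_domains)
  res$orthogroups <- og
  if (!"divergence" %in% stages) return(structure(res, class = "zf_pipeline"))
  # --- divergence ---------------------------------------------------------
  classes <- classify_residues(arrays, sim$proteins)
  alignments <- list()
  correspondences <- list()
  domain_calls <- list()
  sites <- list()
  for (gid in unique(og$group_id)) {
    grp <- filter(og, .data$group_id == gid)
    aln <- align_orthologs(grp, sim$proteins, ref)
    cor <- match_domains(aln, arrays, min_overlap = params$min_overlap)
    dv <- call_divergent_sites(aln, cor, arrays, classes)
    alignments[[gid]] <- aln
    correspondences[[gid]] <- cor
    domain_calls[[gid]] <- dv$domains
    sites[[gid]] <- dv$sites
  }
  correspondences <- list_rbind(correspondences)
  domain_calls <- list_rbind(domain_calls)
  sites <- list_rbind(sites)
  res$alignments <- alignments
  res$correspondence <- correspondences
  res$domain_calls <- domain_calls
  res$sites <- sites
  res$residue_classes <- classes
  res$divergence_summary <- summarize_divergence(correspondences,
                                                 domain_calls, arrays)
  if (!"selection" %in% stages) return(structure(res, class = "zf_pipeline"))
  # --- selection ----------------------------------------------------------
  rates <- map(alignments, parsimony_rate_proxy, species_tree = tree) %>%
    list_rbind()
  poly <- simulate_polymorphisms(sim)
  res$rates <- rates
  res$polymorphisms <- poly$table
  res$clade_support <- clade_support(sites, alignments, params$pairing)
  res$rate_ranks <- rate_rank_analysis(sites, rates)
  res$fixation <- fixation_test(sites, poly$table)
  res$sfs <- folded_sfs(sites, poly$table)
  if (!"specificity" %in% stages) return(structure(res, class = "zf_pipeline"))
  # --- specificity --------------------------------------------------------
  group_prots <- sim$proteins %>%
    semi_join(og, by = c("species", "gene_id")) %>%
    semi_join(reps, by = c("species", "protein_id"))
  spec_domains <- semi_join(arrays, group_prots,
                            by = c("species", "protein_id"))
  records <- specificity_records(spec_domains,
                                 threshold = params$pcc_threshold)
  res$specificity <- records
  res$divergent_specificity <-
    divergent_specificity_summary(records, domain_calls,
                                  cutoff = params$pcc_threshold)
  res$specificity_distance <-
    specificity_vs_distance(records, domain_calls, tree, ref)
  if (!"landscape" %in% stages) return(structure(res, class = "zf_pipeline"))
  # --- landscape ----------------------------------------------------------
  conf_sp <- params$confidence_species %||% closest_species(tree, ref, 4L)
  tf_genes <- og %>%
    distinct(.data$group_id, .data$ref_gene) %>%
    arrange(.data$ref_gene) %>%
    head(sim$config$n_tfs)
  diverged_groups <- domain_calls %>%
    filter(.data$evaluable, .data$diverged) %>%
    pull(.data$group_id) %>%
    unique()
  tf_map <- tf_genes %>%
    mutate(pwm_id = sprintf("tf_%s", .data$ref_gene),
           tf_class = if_else(.data$group_id %in% diverged_groups,
                              "diverged", "conserved"))
  prom <- simulate_promoters(
    sim$config,
    tf_classes = select(tf_map, "pwm_id", "tf_class"))
  qc <- map(names(prom$pwms), function(id) {
    n_sp <- og %>%
      filter(.data$ref_gene ==
               tf_map$ref_gene[tf_map$pwm_id == id],
             .data$species != ref) %>%
      nrow()
    mutate(qc_pwm(prom$pwms[[id]], n_partner_species = n_sp), pwm_id = id,
           .before = 1)
  }) %>% list_rbind()
  kept <- prom$pwms[qc$pwm_id[qc$pass]]
  scan <- scan_promoters(prom$promoters, kept,
                         p_threshold = params$scan_p_threshold,
                         granularity = params$granularity)
  conf_sites <- high_confidence_sites(scan, ref, conf_sp,
                                      window = params$window)
  fracs <- conservation_fractions(conf_sites, scan, ref,
                                  exclude_species = conf_sp,
                                  window = params$window)
  tf_labels <- classify_tf_constructs(tf_map, og, domain_calls,
                                      tree$tip.label, ref)
  res$promoters <- prom
  res$pwm_qc <- qc
  res$binding_sites <- scan
  res$confident_sites <- conf_sites
  res$conservation <- fracs
  res$tf_classes <- tf_labels
  res$landscape_comparison <-
    try(compare_conserved_vs_diverged(fracs, tf_labels), silent = TRUE)
  structure(res, class = "zf_pipeline")
}

#' @export
print.zf_pipeline <- function(x, ...) {
  cat(sprintf("<zf_pipeline> seed %d: %s\n", x$manifest$seed,
              paste(setdiff(names(x), "manifest"), collapse = ", ")))
  invisible(x)
}

#' Simulate a dataset and run every stage
#'
#' One-shot end-to-end entry point: builds the synthetic dataset for `seed`
#' and runs the full pipeline on it.
#'
#' @param seed Integer seed.
#' @param config A [sim_config()] (its seed is replaced by `seed`).
#' @param params A [pipeline_params()].
#' @return A `zf_pipeline`.
#' @export
simulate_and_run <- function(seed = 1L, config = sim_config(),
                             params = pipeline_params()) {
  config$seed <- as.integer(seed)
  sim <- simulate_families(config)
  run_pipeline(sim, params = params)
}
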