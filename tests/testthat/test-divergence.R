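make_group_fixture <- function(binding_by_species = NULL, drop_domain = NULL) {
  # reference R with 2 domains; species A and B carry orthologs whose binding
  # residues (and domain complement) can be perturbed per species
  b_ref <- list(c("R","D","E","R"), c("K","N","S","T"))
  species <- c("R", "A", "B")
  seqs <- vapply(species, function(sp) {
    b <- b_ref
    if (!is.null(binding_by_species[[sp]])) b <- binding_by_species[[sp]]
    if (!is.null(drop_domain[[sp]])) b <- b[-drop_domain[[sp]]]
    make_protein_seq(length(b), binding = b, flank = 12)
  }, character(1))
  prot <- make_proteins(paste0("P_", species), seqs, species = species,
                        genes = paste0("g_", species))
  og <- tibble::tibble(group_id = "g_R", ref_gene = "g_R",
                       species = species,
                       gene_id = paste0("g_", species),
                       provenance = "direct")
  domains <- call_domains(prot)
  arrays <- build_arrays(domains, prot)
  aln <- align_orthologs(og, prot, reference = "R")
  list(prot = prot, og = og, domains = domains, arrays = arrays, aln = aln)
}

test_that("identical orthologs give an identity column map", {
  fx <- make_group_fixture()
  m <- fx$aln$map[fx$aln$map$species == "A", ]
  expect_equal(m$ref_index, m$sp_index)
  expect_true(all(m$ref_residue == m$sp_residue))
})

test_that("a deleted residue leaves one reference column unmapped", {
  og <- tibble::tibble(group_id = "g", ref_gene = "gR",
                       species = c("R", "A"), gene_id = c("gR", "gA"),
                       provenance = "direct")
  prot <- make_proteins(c("pR", "pA"), c("ACDEF", "ACEF"),
                        species = c("R", "A"), genes = c("gR", "gA"))
  aln <- align_orthologs(og, prot, reference = "R")
  m <- aln$map[aln$map$species == "A", ]
  expect_equal(nrow(m), 4)
  expect_equal(setdiff(0:4, m$ref_index), 2)  # the D column is unmapped
})

test_that("pre-supplied alignments are used verbatim", {
  og <- tibble::tibble(group_id = "g", ref_gene = "gR",
                       species = c("R", "A"), gene_id = c("gR", "gA"),
                       provenance = "direct")
  prot <- make_proteins(c("pR", "pA"), c("ACDEF", "ACEF"),
                        species = c("R", "A"), genes = c("gR", "gA"))
  supplied <- tibble::tibble(species = "A", ref_aln = "ACDEF",
                             sp_aln = "AC-EF")
  aln <- align_orthologs(og, prot, reference = "R", supplied = supplied)
  expect_equal(aln$rows$ref_aln, "ACDEF")
  expect_equal(aln$rows$sp_aln, "AC-EF")
})

test_that("missing species sequences are skipped with a message", {
  og <- tibble::tibble(group_id = "g", ref_gene = "gR",
                       species = c("R", "A", "Z"),
                       gene_id = c("gR", "gA", "gZ"), provenance = "direct")
  prot <- make_proteins(c("pR", "pA"), c("ACDEF", "ACDEF"),
                        species = c("R", "A"), genes = c("gR", "gA"))
  expect_message(aln <- align_orthologs(og, prot, reference = "R"),
                 "skipped")
  expect_equal(aln$rows$species, "A")
})

test_that("domain correspondence distinguishes aligned, lost and gained", {
  fx <- make_group_fixture()
  cor0 <- match_domains(fx$aln, fx$arrays)
  expect_true(all(cor0$status == "aligned"))
  expect_equal(nrow(cor0), 4)  # 2 domains x 2 species

  # drop domain 2 in species A only: lost in A, aligned in B
  fx1 <- make_group_fixture(drop_domain = list(A = 2))
  cor1 <- match_domains(fx1$aln, fx1$arrays)
  a <- cor1[cor1$species == "A", ]
  expect_equal(sort(a$status), c("aligned", "lost"))
  expect_true(all(cor1$status[cor1$species == "B"] == "aligned"))

  # extra domain in A only: a gain with respect to the reference
  b3 <- list(c("R","D","E","R"), c("K","N","S","T"), c("Q","E","D","A"))
  fx2 <- make_group_fixture(binding_by_species = list(A = b3))
  cor2 <- match_domains(fx2$aln, fx2$arrays)
  expect_equal(sum(cor2$status == "gained" & cor2$species == "A"), 1)

  # reference domain absent everywhere: not_evaluated in all species
  fx3 <- make_group_fixture(drop_domain = list(A = 2, B = 2))
  cor3 <- match_domains(fx3$aln, fx3$arrays)
  expect_equal(sum(cor3$status == "not_evaluated"), 2)
  expect_equal(sum(cor3$status == "lost"), 0)
})

test_that("divergence calls use positions -1, 2, 3, 6 only", {
  # species A: position 6 of domain 1 changes R -> K  => diverged
  bA <- list(c("R","D","E","K"), c("K","N","S","T"))
  fx <- make_group_fixture(binding_by_species = list(A = bA))
  classes <- classify_residues(fx$arrays, fx$prot)
  cor <- match_domains(fx$aln, fx$arrays)
  dv <- call_divergent_sites(fx$aln, cor, fx$arrays, classes)
  a1 <- dv$domains[dv$domains$species == "A", ]
  expect_equal(sum(a1$diverged), 1)
  expect_true(all(dv$domains$evaluable))
  expect_equal(sum(dv$domains$diverged[dv$domains$species == "B"]), 0)
  site <- dv$sites[dv$sites$species == "A", ]
  expect_equal(nrow(site), 1)
  expect_equal(site$class, "BINDING")
  expect_equal(site$ref_residue, "R")
  expect_equal(site$sp_residue, "K")
})

test_that("a helix position 4 change records a site but no divergence", {
  # psi swap F -> L sits at excluded position 4
  fx <- make_group_fixture()
  protA <- fx$prot
  seqA <- protA$sequence[protA$species == "A"]
  d1 <- fx$domains[fx$domains$species == "A", ][1, ]
  idx4 <- d1$pos7_index - 3L  # helix position 4
  substr(seqA, idx4 + 1, idx4 + 1) <- "L"
  protA$sequence[protA$species == "A"] <- seqA
  domains <- call_domains(protA)
  arrays <- build_arrays(domains, protA)
  aln <- align_orthologs(fx$og, protA, reference = "R")
  classes <- classify_residues(arrays, protA)
  dv <- call_divergent_sites(aln, match_domains(aln, arrays), arrays, classes)
  expect_equal(sum(dv$domains$diverged), 0)
  siteA <- dv$sites[dv$sites$species == "A", ]
  expect_equal(nrow(siteA), 1)
  expect_equal(siteA$class, "HELIX_EXCLUDED")
})

test_that("residue classes partition the reference protein", {
  fx <- make_group_fixture()
  classes <- classify_residues(fx$arrays, fx$prot)
  ref <- classes[classes$protein_id == "P_R", ]
  expect_equal(nrow(ref),
               unname(nchar(fx$prot$sequence[fx$prot$species == "R"])))
  expect_true(all(ref$class %in% c("BINDING", "HELIX_EXCLUDED",
                                   "C2H2_NONBINDING", "LINKER",
                                   "BACKGROUND")))
  expect_equal(sum(ref$class == "BINDING"), 8)          # 4 per domain
  expect_equal(sum(ref$class == "HELIX_EXCLUDED"), 6)   # 3 per domain
  expect_equal(sum(ref$class == "LINKER"), 7)           # one canonical linker
  # linker between non-canonically linked domains is background
  short <- make_proteins("p2", make_protein_seq(2, linker = "GGGG"))
  arr2 <- build_arrays(call_domains(short), short)
  cls2 <- classify_residues(arr2, short)
  expect_equal(sum(cls2$class == "LINKER"), 0)
})

test_that("summaries stratify and leave empty strata undefined", {
  fx1 <- make_group_fixture(
    binding_by_species = list(A = list(c("R","D","E","K"), c("K","N","S","T"))),
    drop_domain = list(B = 2))
  classes <- classify_residues(fx1$arrays, fx1$prot)
  cor <- match_domains(fx1$aln, fx1$arrays)
  dv <- call_divergent_sites(fx1$aln, cor, fx1$arrays, classes)
  sm <- summarize_divergence(cor, dv$domains, fx1$arrays)
  overall <- sm[sm$stratum_type == "overall", ]
  getv <- function(sp, metric)
    overall$value[overall$species == sp & overall$metric == metric]
  expect_equal(getv("A", "pct_domains_diverged"), 50)   # 1 of 2
  expect_equal(getv("B", "pct_domains_lost"), 50)       # 1 of 2 evaluated
  expect_equal(getv("A", "pct_domains_lost"), 0)
  expect_equal(getv("A", "pct_domains_gained"), 0)
  # zero-denominator strata are NA, not 0
  middle <- sm[sm$stratum_type == "array_position" &
                 sm$stratum == "middle", ]
  expect_true(nrow(middle) == 0 || all(is.na(middle$value) |
                                         middle$denominator > 0))
})

test_that("a zero-rate simulation shows no loss, gain or divergence", {
  cfg <- small_sim_config(seed = 5L,
                          rates = c(BINDING = 0, HELIX_EXCLUDED = 0,
                                    C2H2_NONBINDING = 0, LINKER = 0,
                                    BACKGROUND = 0),
                          domain_loss_rate = 0, domain_gain_rate = 0)
  sim <- simulate_families(cfg)
  seqs <- split(sim$proteins$sequence, sim$proteins$gene_base)
  expect_true(all(vapply(seqs, function(s) length(unique(s)) == 1,
                         logical(1))))
  res <- run_pipeline(sim, stages = c("scan", "orthogroups", "divergence"))
  overall <- res$divergence_summary[
    res$divergence_summary$stratum_type == "overall", ]
  expect_true(all(overall$value == 0))
})

test_that("planted events are recovered exactly when indel noise is off", {
  cfg <- small_sim_config(seed = 6L)
  sim <- simulate_families(cfg)
  res <- run_pipeline(sim, stages = c("scan", "orthogroups", "divergence"))
  obs <- res$divergence_summary[
    res$divergence_summary$stratum_type == "overall",
    c("species", "metric", "value")]
  exp <- expected_divergence_from_truth(sim)[, c("species", "metric", "value")]
  cmp <- merge(obs, exp, by = c("species", "metric"),
               suffixes = c("_obs", "_exp"))
  expect_equal(cmp$value_obs, cmp$value_exp, tolerance = 1e-12)
})
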