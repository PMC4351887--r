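fake_alignment <- function(group_id, ref_seq, sp_rows) {
  # sp_rows: named list species -> gapped string aligned to ungapped ref_seq
  maps <- lapply(names(sp_rows), function(sp) {
    m <- polyzf:::aligned_column_map(ref_seq, sp_rows[[sp]])
    m$species <- sp
    m[, c("species", "ref_index", "sp_index", "ref_residue", "sp_residue")]
  })
  structure(list(group_id = group_id, reference = "R", ref_gene = "gR",
                 ref_protein_id = "pR", ref_sequence = ref_seq,
                 rows = tibble::tibble(species = names(sp_rows)),
                 map = do.call(rbind, maps)),
            class = "zf_alignment")
}

site_row <- function(species, ref_index, ref_res, sp_res, class,
                     group_id = "g1") {
  tibble::tibble(group_id = group_id, ref_gene = "gR", species = species,
                 ref_index = ref_index, sp_index = ref_index,
                 ref_residue = ref_res, sp_residue = sp_res, class = class,
                 domain_id = NA_character_)
}

test_that("clade support counts identical partner mutations only", {
  aln <- fake_alignment("g1", "RDERG",
                        list(A = "VDERG",   # V at column 0
                             B = "VDERG",   # partner carries the same V
                             C = "LDERG",   # different residue
                             D = "-DERG"))  # partner gapped at column 0
  pairing <- tibble::tibble(species_a = c("A", "C"), species_b = c("B", "D"))
  sites <- rbind(site_row("A", 0L, "R", "V", "BINDING"),
                 site_row("C", 0L, "R", "L", "BINDING"),
                 site_row("B", 0L, "R", "V", "BACKGROUND"))
  cs <- clade_support(sites, list(g1 = aln), pairing)
  cls <- cs$classes
  # A's site supported by B; B's site supported by A; C's partner D is gapped
  expect_equal(cls$numerator[cls$species == "A"], 1)
  expect_equal(cls$numerator[cls$species == "B"], 1)
  expect_equal(nrow(cls[cls$species == "C", ]), 0)
})

test_that("species without a partner are skipped with a message", {
  aln <- fake_alignment("g1", "RDERG", list(A = "VDERG", B = "VDERG"))
  pairing <- tibble::tibble(species_a = "A", species_b = "B")
  sites <- rbind(site_row("A", 0L, "R", "V", "BINDING"),
                 site_row("Z", 0L, "R", "V", "BINDING"))
  expect_message(cs <- clade_support(sites, list(g1 = aln), pairing), "Z")
  expect_false("Z" %in% cs$classes$species)
})

test_that("rate ranks follow the stated normalization conventions", {
  rates <- tibble::tibble(group_id = "g1", ref_index = 0:3,
                          rate = c(0.1, 0.5, 0.9, 0.2), complete = TRUE)
  sites <- rbind(site_row("A", 0L, "R", "V", "BINDING"),
                 site_row("A", 1L, "D", "E", "BACKGROUND"),
                 site_row("A", 2L, "E", "D", "BACKGROUND"))
  rr <- rate_rank_analysis(sites, rates)
  expect_equal(sort(rr$values$normalized_rank), c(0, 0.5, 1))
  # single divergent site in a sequence -> 0.5
  one <- rate_rank_analysis(site_row("A", 0L, "R", "V", "BINDING"), rates)
  expect_equal(one$values$normalized_rank, 0.5)
  # tied rates share the average rank
  rates2 <- tibble::tibble(group_id = "g1", ref_index = 0:1,
                           rate = c(0.2, 0.2), complete = TRUE)
  two <- rate_rank_analysis(
    rbind(site_row("A", 0L, "R", "V", "BINDING"),
          site_row("A", 1L, "D", "E", "BACKGROUND")), rates2)
  expect_equal(two$values$normalized_rank, c(0.5, 0.5))
  # incomplete columns are excluded when requested
  rates3 <- rates
  rates3$complete[1] <- FALSE
  rr3 <- rate_rank_analysis(sites, rates3, complete_columns_only = TRUE)
  expect_false(0L %in% rr3$values$ref_index)
})

test_that("fixation test classifies sites by polymorphism overlap", {
  poly <- tibble::tibble(gene_id = "gR", ref_index = 5L, minor_count = 3L,
                         sample_size = 139L)
  sites <- rbind(site_row("A", 5L, "R", "V", "BINDING"),
                 site_row("A", 9L, "D", "E", "BINDING"),
                 site_row("A", 2L, "G", "S", "BACKGROUND"))
  fx <- fixation_test(sites, poly)
  cls <- fx$classes
  bind <- cls[cls$class == "BINDING", ]
  expect_equal(bind$numerator, 1)        # site 9 absent from the table
  expect_equal(bind$denominator, 2)
  expect_equal(cls$proportion[cls$class == "BACKGROUND"], 1)
  # empty table: everything is a candidate fixation
  empty <- tibble::tibble(gene_id = character(), ref_index = integer(),
                          minor_count = integer(), sample_size = integer())
  fx0 <- fixation_test(sites, empty)
  expect_true(all(fx0$classes$proportion == 1))
})

test_that("folded SFS bins counts and aggregates the tail", {
  poly <- tibble::tibble(gene_id = "gR", ref_index = c(0L, 1L, 2L, 3L),
                         minor_count = c(1L, 1L, 2L, 8L),
                         sample_size = 139L)
  sites <- do.call(rbind, lapply(0:3, function(i)
    site_row("A", i, "R", "V", "BINDING")))
  sfs <- folded_sfs(sites, poly)
  b <- sfs[sfs$class == "BINDING" & sfs$species == "A", ]
  expect_equal(b$proportion[b$bin == "1"], 0.5)
  expect_equal(b$proportion[b$bin == "2"], 0.25)
  expect_equal(b$proportion[b$bin == "7+"], 0.25)
  expect_equal(sum(b$proportion), 1)
  # a count of exactly 7 lands in the aggregate bin
  poly7 <- tibble::tibble(gene_id = "gR", ref_index = 0L, minor_count = 7L,
                          sample_size = 139L)
  sfs7 <- folded_sfs(site_row("A", 0L, "R", "V", "BINDING"), poly7)
  expect_equal(sfs7$proportion[sfs7$bin == "7+"], 1)
  # invalid minor counts are rejected
  bad <- tibble::tibble(gene_id = "gR", ref_index = 0L, minor_count = 100L,
                        sample_size = 139L)
  expect_error(folded_sfs(site_row("A", 0L, "R", "V", "BINDING"), bad),
               "minor_count")
})

test_that("parsimony rate proxy matches Fitch counts on a 4-leaf tree", {
  st <- four_species_tree()
  st$tip.label <- c("R", "A", "C", "D")
  total_len <- sum(st$edge.length)
  aln <- fake_alignment("g1", "AAA",
                        list(A = "AAD", C = "ADD", D = "ADE"))
  rates <- parsimony_rate_proxy(aln, st)
  expect_equal(rates$rate[rates$ref_index == 0], 0)           # invariant
  expect_equal(rates$rate[rates$ref_index == 1], 1 / total_len)
  # column 2: states A, D, D, E -> 2 changes (oracle-verified)
  oracle <- brute_force_fitch(st, c(R = "A", A = "D", C = "D", D = "E"))
  expect_equal(rates$rate[rates$ref_index == 2], oracle / total_len)
  expect_true(all(rates$complete))
  # all-distinct states on 4 leaves need 3 changes
  aln2 <- fake_alignment("g1", "A", list(A = "C", C = "G", D = "W"))
  r2 <- parsimony_rate_proxy(aln2, st)
  expect_equal(r2$rate, 3 / total_len)
})

test_that("Rate4Site-style score files parse to 0-based indices", {
  path <- withr::local_tempfile(fileext = ".res")
  writeLines(c("# Rates were calculated using the expectation of the",
               "# posterior rate distribution",
               "    1     M   0.6931  [ 0.2,  1.1]  0.3  12/12",
               "    2     K  -0.1054  [-0.5,  0.2]  0.2  12/12"), path)
  r <- read_rate4site(path)
  expect_equal(r$ref_index, c(0L, 1L))
  expect_equal(r$residue, c("M", "K"))
  expect_equal(r$rate, c(0.6931, -0.1054))
})

test_that("binomial comparison wiring flags undefined nulls", {
  classes <- tibble::tibble(
    species = "A", class = c("BINDING", "BACKGROUND"),
    numerator = c(8L, 0L), denominator = c(10L, 20L),
    proportion = c(0.8, 0))
  cc <- polyzf:::binding_vs_background(classes, "clade_support")
  expect_true(cc$tests$undefined)  # p0 = 0 admits no binomial null
  classes$numerator[2] <- 5L
  cc2 <- polyzf:::binding_vs_background(classes, "clade_support")
  expect_false(cc2$tests$undefined)
  expect_equal(cc2$tests$p_value,
               binomial_compare(8, 10, 0.25)$p_value)
})
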