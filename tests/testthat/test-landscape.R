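point_pwm <- function(bases) {
  new_pwm(vapply(bases, function(b) {
    p <- rep(0, 4); p[match(b, c("A", "C", "G", "T"))] <- 1; p
  }, numeric(4)))
}

test_that("information content and QC follow the stated rules", {
  expect_equal(pwm_ic(point_pwm(c("A")))[1], 2)       # point mass: 2 bits
  expect_equal(pwm_ic(new_pwm(matrix(0.25, 4, 1)))[1], 0)
  strong <- point_pwm(c("A", "C", "G", "T", "A", "C", "G"))
  expect_true(qc_pwm(strong)$pass)
  # only 5 informative columns: discarded
  weak <- new_pwm(cbind(unclass(point_pwm(c("A", "C", "G", "T", "A"))),
                        matrix(0.25, 4, 3)))
  qcw <- qc_pwm(weak)
  expect_false(qcw$pass)
  expect_match(qcw$reasons, "low_ic")
  # low complexity: > 80% of informative columns share the consensus
  poly_a <- point_pwm(rep("A", 7))
  expect_match(qc_pwm(poly_a)$reasons, "low_complexity")
  # too few orthologous species
  expect_match(qc_pwm(strong, n_partner_species = 1)$reasons,
               "too_few_orthologs")
  expect_error(qc_pwm(new_pwm(matrix(c(2, -1, 0, 0), 4, 1))), "non-negative")
})

test_that("consensus calls report N on ties", {
  tie <- new_pwm(matrix(c(0.4, 0.4, 0.1, 0.1), 4, 1))
  expect_equal(pwm_consensus(tie), "N")
})

test_that("scanning with p_threshold 1 reports every position and strand", {
  pwm <- point_pwm(c("A", "C"))
  hits <- scan_pwm("ACGTAC", pwm, p_threshold = 1)
  expect_equal(sum(hits$strand == "+"), 5)
  expect_equal(sum(hits$strand == "-"), 5)
  # shorter than the motif: nothing
  expect_equal(nrow(scan_pwm("A", pwm, p_threshold = 1)), 0)
})

test_that("scan p-values equal 4^L enumeration with matched discretization", {
  set.seed(31)
  for (L in c(2, 4, 6, 8)) {
    mat <- vapply(seq_len(L), function(j) {
      p <- runif(4) + 0.05; p / sum(p)
    }, numeric(4))
    pwm <- new_pwm(mat)
    bg <- rep(0.25, 4)
    sm <- polyzf:::pwm_score_matrix(pwm, bg)
    dist <- polyzf:::pwm_score_distribution(sm, bg)
    oracle <- enumerate_scan_pvalues(dist$int_mat, bg)
    # probe a sample of words through the public scanner
    words <- oracle$words[sample(nrow(oracle$words),
                                 min(40, nrow(oracle$words))), , drop = FALSE]
    for (i in seq_len(nrow(words))) {
      seqc <- paste(c("A", "C", "G", "T")[words[i, ]], collapse = "")
      hit <- scan_pwm(seqc, pwm, bg, p_threshold = 1, both_strands = FALSE)
      t_int <- sum(dist$int_mat[cbind(words[i, ], seq_len(L))])
      expect_equal(hit$p_value, oracle$pvalue_of(t_int), tolerance = 1e-9,
                   info = sprintf("L=%d word=%s", L, seqc))
    }
  }
})

test_that("a top-scoring dinucleotide has p = (# words at least as good)/16", {
  pwm <- new_pwm(matrix(c(0.7, 0.1, 0.1, 0.1,
                          0.1, 0.7, 0.1, 0.1), 4, 2))
  hit <- scan_pwm("AC", pwm, p_threshold = 1, both_strands = FALSE)
  expect_equal(hit$p_value, 1 / 16, tolerance = 1e-9)
})

test_that("reverse complements score identically on the opposite strand", {
  pwm <- point_pwm(c("A", "C", "G"))
  fwd <- scan_pwm("TTACGTT", pwm, p_threshold = 1)
  best_plus <- fwd[fwd$strand == "+", ]
  best_minus <- scan_pwm("AACGTAA", pwm, p_threshold = 1)
  best_minus <- best_minus[best_minus$strand == "-", ]
  expect_equal(max(best_plus$score), max(best_minus$score), tolerance = 1e-9)
})

test_that("promoter scanning maps sites back through alignment gaps", {
  prom <- promoter_alignment(tibble::tibble(
    promoter_id = "p1", species = c("R", "A"),
    aligned = c("AAACGTAA", "AA--GTAA")))
  pwm <- point_pwm(c("C", "G", "T"))
  sites <- scan_promoters(prom, list(m1 = pwm), p_threshold = 0.05)
  r <- sites[sites$species == "R" & sites$strand == "+", ]
  expect_equal(r$start, 3L)     # ungapped offset
  expect_equal(r$aln_col, 3L)   # same as alignment column for gapless row
})

test_that("confidence requires partners within the window in every species", {
  sites <- tibble::tibble(
    pwm_id = "m", promoter_id = "p",
    species = c("R", "A", "B"),
    aln_col = c(100L, 120L, 115L),
    start = c(100L, 120L, 115L), strand = "+",
    score = 5, p_value = 1e-5)
  conf <- high_confidence_sites(sites, "R", c("A", "B"), window = 25)
  expect_true(conf$confident)
  expect_false(high_confidence_sites(sites, "R", c("A", "B"),
                                     window = 15)$confident)
  # one species' nearest site at distance 30: not confident at 25
  sites2 <- sites
  sites2$aln_col <- c(100L, 130L, 120L)
  expect_false(high_confidence_sites(sites2, "R", c("A", "B"),
                                     window = 25)$confident)
  # a species entirely absent from the scan lacks sites: not confident
  expect_false(high_confidence_sites(sites, "R", c("A", "Z"),
                                     window = 25)$confident)
  # empty species set: vacuously confident
  expect_true(high_confidence_sites(sites, "R", character(0))$confident)
})

test_that("conservation fractions count sites and promoters correctly", {
  mk_sites <- function(c_cols) tibble::tibble(
    pwm_id = "m",
    promoter_id = c("p1", "p1", "p2", "p1", "p2"),
    species = c("R", "R", "R", "C", "C"),
    aln_col = c(10L, 200L, 50L, c_cols),
    start = 0L, strand = "+", score = 5, p_value = 1e-5)
  ref <- tibble::tibble(
    pwm_id = "m", promoter_id = c("p1", "p1", "p2"), species = "R",
    aln_col = c(10L, 200L, 50L), start = c(10L, 200L, 50L), strand = "+",
    score = 5, p_value = 1e-5, confident = TRUE)
  # species C matches both p1 sites and the p2 site
  fr <- conservation_fractions(ref, mk_sites(c(12L, 55L)), "R")
  expect_equal(fr$fraction_sites_conserved, 2 / 3)
  expect_equal(fr$fraction_promoters_conserved, 1)
  # p2's lone confident site unmatched: promoter unbound in C
  fr2 <- conservation_fractions(ref, mk_sites(c(12L, 500L)), "R")
  expect_equal(fr2$fraction_promoters_conserved, 0.5)
  # everything matched
  ref1 <- ref[c(1, 3), ]
  fr3 <- conservation_fractions(ref1, mk_sites(c(12L, 52L)), "R")
  expect_equal(fr3$fraction_sites_conserved, 1)
  expect_equal(fr3$fraction_promoters_conserved, 1)
})

test_that("site conservation is monotone in the window size", {
  set.seed(55)
  sim <- simulate_promoters(small_sim_config(seed = 9L))
  scan <- scan_promoters(sim$promoters, sim$pwms, p_threshold = 1e-4)
  confs <- lapply(c(15, 25, 50), function(w)
    high_confidence_sites(scan, "dmel", c("dsec", "dsim", "dyak", "dere"),
                          window = w))
  key <- function(cf) with(cf[cf$confident, ],
                           paste(pwm_id, promoter_id, aln_col, strand))
  expect_true(all(key(confs[[1]]) %in% key(confs[[2]])))
  expect_true(all(key(confs[[2]]) %in% key(confs[[3]])))
})

test_that("conserved and diverged TF classes separate in the rank test", {
  # identical fractions everywhere: p = 1
  frac_flat <- tibble::tibble(
    species = rep(c("s1", "s2"), each = 4),
    pwm_id = rep(sprintf("t%d", 1:4), 2),
    fraction_promoters_conserved = 0.5)
  labels <- tibble::tibble(
    pwm_id = rep(sprintf("t%d", 1:4), 2),
    species = rep(c("s1", "s2"), each = 4),
    label = rep(c("conserved_all", "conserved_all", "diverged_here",
                  "diverged_here"), 2))
  flat <- compare_conserved_vs_diverged(frac_flat, labels)
  expect_equal(flat$test$p_value, 1)
  # complete separation in every species: minimal exact rank-sum p
  frac_sep <- frac_flat
  frac_sep$fraction_promoters_conserved <-
    rep(c(0.9, 0.8, 0.2, 0.1), 2)
  sep <- compare_conserved_vs_diverged(frac_sep, labels)
  ref_p <- wilcoxon_rank_sum(
    sep$values$normalized[sep$values$label == "conserved_all"],
    sep$values$normalized[sep$values$label == "diverged_here"])$p_value
  expect_equal(sep$test$p_value, ref_p)
  expect_lt(sep$test$p_value, 0.05)
  expect_error(compare_conserved_vs_diverged(
    frac_flat, dplyr::mutate(labels, label = "diverged_here")),
    "at least one")
})

test_that("TF constructs are labelled from divergence calls", {
  tf_map <- tibble::tibble(pwm_id = c("m1", "m2"), ref_gene = c("g1", "g2"))
  og <- tibble::tibble(
    group_id = c("g1", "g1", "g1", "g2", "g2"),
    ref_gene = c("g1", "g1", "g1", "g2", "g2"),
    species = c("R", "A", "B", "R", "A"),
    gene_id = c("g1", "a1", "b1", "g2", "a2"), provenance = "direct")
  calls <- tibble::tibble(
    group_id = "g1", species = "A", ref_domain = "d", sp_domain = "d2",
    n_compared = 4L, evaluable = TRUE, diverged = TRUE)
  lab <- classify_tf_constructs(tf_map, og, calls, c("R", "A", "B"), "R")
  expect_equal(lab$label[lab$pwm_id == "m1" & lab$species == "A"],
               "diverged_here")
  expect_equal(lab$label[lab$pwm_id == "m1" & lab$species == "B"],
               "conserved_here_diverged_elsewhere")
  expect_equal(lab$label[lab$pwm_id == "m2" & lab$species == "A"],
               "conserved_all")
  expect_equal(lab$label[lab$pwm_id == "m2" & lab$species == "B"], "absent")
})

test_that("MEME minimal format round-trips PWMs", {
  pwms <- list(m1 = point_pwm(c("A", "C", "G")),
               m2 = new_pwm(matrix(c(0.7, 0.1, 0.1, 0.1), 4, 5)))
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(pwms, path)
  back <- read_meme(path)
  expect_equal(names(back), c("m1", "m2"))
  expect_equal(unclass(back$m2), unclass(pwms$m2), tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(attr(back, "background"), c(A = 0.25, C = 0.25, G = 0.25,
                                           T = 0.25))
})

test_that("aligned promoter FASTA round-trips with offsets", {
  prom <- promoter_alignment(tibble::tibble(
    promoter_id = c("p1", "p1"), species = c("R", "A"),
    offset = c(1000L, 2000L), aligned = c("ACGT", "AC-T")))
  path <- withr::local_tempfile(fileext = ".fa")
  write_promoter_fasta(prom, path)
  back <- read_promoter_fasta(path)
  expect_equal(back$promoter_id, prom$promoter_id)
  expect_equal(back$offset, prom$offset)
  expect_equal(back$aligned, prom$aligned)
  expect_error(promoter_alignment(tibble::tibble(
    promoter_id = "p", species = c("R", "A"), aligned = c("ACGT", "AC"))),
    "width")
})
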