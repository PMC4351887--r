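test_that("structural regex matches the hand-derived example", {
  m <- regex_match_c2h2("CAACDEDEDEDEFAAHAAAH", zf_pattern(preset = "strict"))
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 20L)
  expect_equal(m$pos7_index, 15L)
  # helix map: -1 -> 'D' (idx 8), 2 -> 'D' (10), 3 -> 'E' (11), 6 -> 'A' (14)
  w <- strsplit(m$helix_window, "")[[1]]
  expect_equal(w[c(1, 3, 4, 7, 8)], c("D", "D", "E", "A", "H"))
})

test_that("regex rejects non-matching and non-hydrophobic sequences", {
  expect_equal(nrow(regex_match_c2h2("AAAA")), 0)
  # psi position holds G: no match
  expect_equal(nrow(regex_match_c2h2("CAACDEDEDEDEGAAHAAAH",
                                     zf_pattern(preset = "strict"))), 0)
  expect_error(regex_match_c2h2("CAAB"), "alphabet")
})

test_that("regex engine agrees with the naive backtracking oracle", {
  set.seed(42)
  alphabet <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
                "S","T","V","W","Y")
  pat <- zf_pattern()
  for (i in 1:300) {
    # bias composition toward C/H so matches actually occur
    s <- paste(sample(c(alphabet, c("C", "H", "H")), sample(20:200, 1),
                      replace = TRUE), collapse = "")
    got <- regex_match_c2h2(s, pat)
    want <- naive_c2h2_scan(s)
    expect_equal(got$start, want$start, info = paste("seq", i))
    expect_equal(got$end, want$end, info = paste("seq", i))
    expect_equal(got$pos7_index, want$pos7_index, info = paste("seq", i))
  }
})

test_that("every called domain anchors on histidine at position 7", {
  set.seed(43)
  for (i in 1:50) {
    s <- paste(sample(c(LETTERS[LETTERS %in% c("A","C","D","E","F","G","H")],
                        "C", "H"), sample(30:150, 1), replace = TRUE),
               collapse = "")
    m <- regex_match_c2h2(s)
    if (nrow(m) > 0) {
      expect_true(all(substr(m$helix_window, 8, 8) == "H"))
      expect_true(all(substr(s, m$start + 1, m$start + 1) == "C"))
    }
  }
})

test_that("domtblout parsing converts coordinates and attaches thresholds", {
  thr <- tibble::tibble(hmm_id = "zf-C2H2", gathering_threshold = 18)
  path <- withr::local_tempfile(fileext = ".domtblout")
  writeLines(c("# comment only", "#"), path)
  expect_equal(nrow(read_domtblout(path, thr)), 0)

  write_domtblout(path, c("p1", "p1"), c("zf-C2H2", "zf-C2H2"),
                  c(25, 12), c(10, 40), c(30, 60))
  hits <- read_domtblout(path, thr)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$envelope_start, c(9L, 39L))  # 1-based 10 -> 0-based 9
  expect_equal(hits$envelope_end, c(30L, 60L))
  expect_equal(hits$bitscore, c(25, 12))
  expect_equal(hits$gathering_threshold, c(18, 18))

  writeLines("p1 - 500 zf short line", path)
  expect_error(read_domtblout(path, thr), "line 1")
  write_domtblout(path, "p1", "unknownHMM", 20, 1, 23)
  expect_error(read_domtblout(path, thr), "unknownHMM")
  expect_equal(read_domtblout(path, thr,
                              default_threshold = 10)$gathering_threshold, 10)
})

test_that("domain calling enforces the regex and the rescue rule", {
  seq2 <- make_protein_seq(2, linker = "TGEKPFQ")
  prot <- make_proteins("p1", seq2)
  m <- regex_match_c2h2(seq2)
  expect_equal(nrow(m), 2)
  mk_hits <- function(bit) tibble::tibble(
    protein_id = "p1", hmm_id = "zf", bitscore = bit,
    envelope_start = m$start, envelope_end = m$end,
    gathering_threshold = 18)

  # above + below threshold: both kept, the weak one rescued
  d <- call_domains(prot, mk_hits(c(20, 10)))
  expect_equal(nrow(d), 2)
  expect_equal(d$rescued, c(FALSE, TRUE))
  expect_equal(d$above_threshold, c(TRUE, FALSE))

  # a lone sub-threshold hit has nothing to rescue against
  lone <- mk_hits(c(10, 10))[1, ]
  expect_equal(nrow(call_domains(prot, lone)), 0)

  # a strong hit whose envelope contains no regex match is degenerate
  junk <- make_proteins("p2", paste0(strrep("A", 50)))
  hit <- tibble::tibble(protein_id = "p2", hmm_id = "zf", bitscore = 50,
                        envelope_start = 0L, envelope_end = 50L,
                        gathering_threshold = 18)
  expect_equal(nrow(call_domains(junk, hit)), 0)
})

test_that("rescue is monotone in added above-threshold evidence", {
  seq2 <- make_protein_seq(3, linker = "TGEKPFQ")
  prot <- make_proteins("p1", seq2)
  m <- regex_match_c2h2(seq2)
  base_hits <- tibble::tibble(
    protein_id = "p1", hmm_id = "zf", bitscore = c(20, 10, 10),
    envelope_start = m$start, envelope_end = m$end,
    gathering_threshold = 18)
  before <- call_domains(prot, base_hits[1:2, ])
  after <- call_domains(prot, base_hits)
  expect_true(all(paste(before$start, before$end) %in%
                    paste(after$start, after$end)))
})

test_that("pure-regex scanning marks everything above threshold", {
  prot <- make_proteins("p1", make_protein_seq(2))
  d <- call_domains(prot)
  expect_equal(nrow(d), 2)
  expect_true(all(d$above_threshold))
  expect_true(all(!d$rescued))
})

test_that("isoform selection prefers one covering isoform, else a minimal set", {
  b <- list(c("R","D","E","R"), c("K","N","S","T"), c("Q","E","D","A"))
  # A holds windows 1,2,3 (length 400 + padding); B holds 1,2 but is longer
  seqA <- make_protein_seq(3, binding = b, flank = 30)
  seqB <- paste0(make_protein_seq(2, binding = b[1:2], flank = 30),
                 strrep("G", 200))
  prot <- make_proteins(c("pA", "pB"), c(seqA, seqB), genes = c("g1", "g1"))
  doms <- call_domains(prot)
  sel <- select_isoforms(doms, prot)
  expect_equal(sel$protein_id, "pA")

  # no single isoform covers: A{1,2}, B{2,3}, C{3} -> {A, B}
  prot2 <- make_proteins(
    c("pA", "pB", "pC"),
    c(make_protein_seq(2, binding = b[1:2]),
      make_protein_seq(2, binding = b[2:3]),
      make_protein_seq(1, binding = b[3])),
    genes = "g2")
  sel2 <- select_isoforms(call_domains(prot2), prot2)
  expect_setequal(sel2$protein_id, c("pA", "pB"))

  # single isoform is its own representative
  prot3 <- make_proteins("pX", make_protein_seq(2))
  expect_equal(select_isoforms(call_domains(prot3), prot3)$protein_id, "pX")
})

test_that("isoform cover equals brute-force minimum on random instances", {
  set.seed(77)
  wins <- list(c("R","D","E","R"), c("K","N","S","T"), c("Q","E","D","A"),
               c("N","N","E","K"), c("T","S","R","Q"), c("E","R","K","D"))
  for (rep in 1:25) {
    k <- sample(3:7, 1)
    sets <- lapply(seq_len(k), function(i)
      sort(sample(length(wins), sample(1:4, 1))))
    universe <- sort(unique(unlist(sets)))
    prot <- make_proteins(
      sprintf("p%02d", seq_len(k)),
      vapply(sets, function(s)
        make_protein_seq(length(s), binding = wins[s]), character(1)),
      genes = "g1")
    doms <- call_domains(prot)
    sel <- select_isoforms(doms, prot)
    expect_equal(length(unique(sel$protein_id)),
                 brute_force_min_cover_size(sets, universe),
                 info = sprintf("instance %d", rep))
  }
})

test_that("arrays, linkers and position labels follow the gap rules", {
  b <- list(c("R","D","E","R"), c("K","N","S","T"), c("Q","E","D","A"))
  canonical <- make_proteins("p1", make_protein_seq(3, binding = b,
                                                    linker = "TGEKPFQ"))
  arr <- build_arrays(call_domains(canonical), canonical)
  expect_true(all(arr$canonically_linked))
  expect_true(all(arr$motif_after[1:2]))
  expect_equal(arr$array_position, c("beginning", "middle", "end"))
  expect_equal(arr$linker_after[1:2], c(7L, 7L))

  # length-4 gap: same array but not canonical
  short <- make_proteins("p2", make_protein_seq(2, linker = "GGGG"))
  arr2 <- build_arrays(call_domains(short), short)
  expect_equal(unique(arr2$array_id), 1L)
  expect_false(any(arr2$canonically_linked))
  expect_equal(arr2$array_position, c("beginning", "end"))

  # length-13 gap: array broken, two singletons
  long <- make_proteins("p3", make_protein_seq(2, linker = strrep("G", 13)))
  arr3 <- build_arrays(call_domains(long), long)
  expect_equal(arr3$array_id, c(1L, 2L))
  expect_equal(arr3$array_position, c("singleton", "singleton"))
  expect_false(any(arr3$canonically_linked))

  # overlapping domains are rejected
  doms <- call_domains(canonical)
  doms$start[2] <- doms$start[1] + 2L
  doms$end[2] <- doms$end[1] + 2L
  expect_error(build_arrays(doms, canonical), "overlap")
})
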