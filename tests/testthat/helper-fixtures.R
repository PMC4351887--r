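# Fixture builders: small proteins, domains and trees constructed in code.

SAFE_CHARS <- setdiff(c("A","D","E","F","G","I","K","L","M","N","P","Q","R",
                        "S","T","V","W","Y"), character(0))

rand_safe <- function(n) paste(sample(SAFE_CHARS, n, replace = TRUE),
                               collapse = "")

# a minimal C2H2 domain with chosen specificity residues:
# C xx C xxxxxxxx [psi-window] H xxx H, strict spacers (2, 8, 3)
make_domain_seq <- function(binding = c("R", "D", "E", "R"), psi = "F") {
  # helix window (-1,1,2,3,4,5,6,7): binding at -1,2,3,6; psi sits at 4
  w <- c(binding[1], "A", binding[2], binding[3], psi, "A", binding[4], "H")
  paste0("C", "AA", "C", "AAAA", paste(w[1:7], collapse = ""), "H", "AAA", "H")
}

# protein: flank + domains joined by linkers + flank
make_protein_seq <- function(n_domains = 2, linker = "TGEKPFQ",
                             binding = NULL, flank = 10) {
  doms <- vapply(seq_len(n_domains), function(i) {
    b <- if (is.null(binding)) c("R", "D", "E", "R") else binding[[i]]
    make_domain_seq(b)
  }, character(1))
  paste0(strrep("G", flank),
         paste(doms, collapse = linker),
         strrep("G", flank))
}

make_proteins <- function(ids, seqs, species = "dmel", genes = ids) {
  tibble::tibble(protein_id = ids, gene_id = genes, species = species,
                 sequence = seqs)
}

two_species_tree <- function() ape::read.tree(text = "(A:1,B:1);")

four_species_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

small_sim_config <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 8L, n_tfs = 4L, n_promoters = 20L,
                   promoter_length = 250L, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# write a domtblout file from a hit table (1-based envelope columns 20/21)
write_domtblout <- function(path, protein_id, hmm_id, bitscore, env_from,
                            env_to) {
  lines <- c("# domtblout fixture", "#")
  for (i in seq_along(protein_id)) {
    f <- rep("-", 23)
    f[1] <- protein_id[i]; f[3] <- "500"; f[4] <- hmm_id[i]; f[6] <- "23"
    f[7] <- "1e-10"; f[8] <- "50.0"; f[9] <- "0.1"; f[10] <- "1"; f[11] <- "1"
    f[12] <- "1e-9"; f[13] <- "1e-8"; f[14] <- sprintf("%.1f", bitscore[i])
    f[15] <- "0.1"; f[16] <- "1"; f[17] <- "23"
    f[18] <- as.character(env_from[i]); f[19] <- as.character(env_to[i])
    f[20] <- as.character(env_from[i]); f[21] <- as.character(env_to[i])
    f[22] <- "0.95"
    lines <- c(lines, paste(f, collapse = " "))
  }
  writeLines(lines, path)
  path
}
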