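# residues that can never create or destroy the C2H2 grammar outside the
# structural positions: the 20 standard amino acids minus C and H
SAFE_AA <- setdiff(AA_ALPHABET, c("C", "H", "X"))

#' The built-in 12-species clade
#'
#' A rooted binary tree over twelve fly-like species with four sister pairs
#' (sec/sim, yak/ere, pse/per, vir/moj) and reference `dmel`, with branch
#' lengths spanning roughly 0.1-0.7 substitutions/site to the reference.
#'
#' @return A `phylo`.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((dmel:0.06,(dsec:0.02,dsim:0.02):0.04):0.04,",
    "(dyak:0.06,dere:0.05):0.05):0.10,dana:0.21):0.07,",
    "((dpse:0.03,dper:0.03):0.18,dwil:0.25):0.06):0.08,",
    "((dvir:0.12,dmoj:0.14):0.08,dgri:0.23):0.12);"))
}

#' The default sister-species pairing for clade support
#' @return Tibble `species_a`, `species_b` of the four closest pairs.
#' @export
default_clade_pairing <- function() {
  tibble(species_a = c("dsec", "dyak", "dpse", "dvir"),
         species_b = c("dsim", "dere", "dper", "dmoj"))
}

#' Simulation configuration
#'
#' Defaults define the study conditions emulated by the generator: a
#' 12-species clade with paired sister taxa, class-specific substitution
#' rates with DNA-contacting residues slowest, a high clade-consistent
#' fraction for binding substitutions, per-branch domain loss and gain, a
#' polymorphism regime where binding divergences rarely segregate, and
#' promoters with planted, decaying binding sites.
#'
#' @param species_tree Rooted `phylo` (default [default_species_tree()]).
#' @param reference Reference species label.
#' @param n_genes Number of poly-ZF genes.
#' @param domain_range Inclusive range of domains per ancestral gene.
#' @param rates Named substitutions/site/unit-branch-length per residue class.
#' @param clade_consistent_fraction Probability a BINDING substitution lands
#'   on an internal branch (shared by the descendant clade).
#' @param domain_loss_rate,domain_gain_rate Per-domain / per-gene events per
#'   unit branch length.
#' @param indel_rate Per-site background deletions per unit branch length.
#' @param p_polymorphic_neutral,p_polymorphic_selected Probability a
#'   divergent non-binding / binding reference site segregates in the
#'   population sample.
#' @param background_poly_density Polymorphism probability for non-divergent
#'   reference sites.
#' @param sample_size Population sample size (individuals).
#' @param n_tfs,n_promoters,promoter_length,site_density Promoter module
#'   scale: TFs, promoters, upstream window (bp), planted sites per bp.
#' @param site_loss_conserved,site_loss_diverged Per-branch probability a
#'   planted site is destroyed for conserved / diverged TFs.
#' @param seed Integer random seed.
#' @return A `zf_sim_config` list.
#' @export
sim_config <- function(species_tree = default_species_tree(),
                       reference = "dmel",
                       n_genes = 200L,
                       domain_range = c(2L, 8L),
                       rates = c(BINDING = 0.08, HELIX_EXCLUDED = 0.04,
                                 C2H2_NONBINDING = 0.02, LINKER = 0.03,
                                 BACKGROUND = 0.06),
                       clade_consistent_fraction = 0.8,
                       domain_loss_rate = 0.15,
                       domain_gain_rate = 0.04,
                       indel_rate = 0,
                       p_polymorphic_neutral = 0.35,
                       p_polymorphic_selected = 0.06,
                       background_poly_density = 0.02,
                       sample_size = 139L,
                       n_tfs = 20L,
                       n_promoters = 200L,
                       promoter_length = 2000L,
                       site_density = 5e-4,
                       site_loss_conserved = 0.02,
                       site_loss_diverged = 0.12,
                       seed = 1L) {
  if (any(rates < 0)) abort("rates must be non-negative")
  probs <- c(clade_consistent_fraction, p_polymorphic_neutral,
             p_polymorphic_selected, background_poly_density,
             site_loss_conserved, site_loss_diverged)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  missing_cls <- setdiff(RESIDUE_CLASSES, names(rates))
  if (length(missing_cls) > 0) {
    abort(sprintf("rates must name every residue class (missing %s)",
                  paste(missing_cls, collapse = ", ")))
  }
  if (!reference %in% species_tree$tip.label) {
    abort("reference must be a species-tree leaf")
  }
  fields <- c("species_tree", "reference", "n_genes", "domain_range", "rates",
              "clade_consistent_fraction", "domain_loss_rate",
              "domain_gain_rate", "indel_rate", "p_polymorphic_neutral",
              "p_polymorphic_selected", "background_poly_density",
              "sample_size", "n_tfs", "n_promoters", "promoter_length",
              "site_density", "site_loss_conserved", "site_loss_diverged",
              "seed")
  structure(mget(fields), class = "zf_sim_config")
}

rand_aa <- function(n) sample(SAFE_AA, n, replace = TRUE)

# build one ancestral gene: residue-id-based state vectors
build_ancestral_gene <- function(gene, n_domains) {
  id_counter <- 0L
  new_ids <- function(n, tag) {
    id_counter <<- id_counter + n
    sprintf("%s:%s:%d", gene, tag, (id_counter - n + 1L):id_counter)
  }
  chars <- character(); cls <- character(); dom <- character()
  hpos <- integer(); seg <- character(); protected <- logical()
  add <- function(ch, cl, dm, hp, sg, pr) {
    chars <<- c(chars, ch); cls <<- c(cls, cl)
    dom <<- c(dom, dm); hpos <<- c(hpos, hp)
    seg <<- c(seg, sg); protected <<- c(protected, pr)
  }
  add_flank <- function(len, sg) {
    add(rand_aa(len), rep("BACKGROUND", len), rep(NA_character_, len),
        rep(NA_integer_, len), rep(sg, len), rep(FALSE, len))
  }
  add_flank(sample(20:60, 1), "flankN")
  for (d in seq_len(n_domains)) {
    if (d > 1) {
      canonical <- runif(1) < 0.8
      len <- if (canonical) sample(5:12, 1) else
        sample(c(3L, 4L, 13:25), 1)
      link <- rand_aa(len)
      if (canonical && len >= 7 && runif(1) < 0.7) {
        link[1:6] <- c("T", "G", "E", sample(c("K", "R"), 1), "P",
                       sample(c("F", "Y"), 1))
      }
      add(link, rep(if (canonical) "LINKER" else "BACKGROUND", len),
          rep(NA_character_, len), rep(NA_integer_, len),
          rep(sprintf("link%d", d), len), rep(FALSE, len))
    }
    dom_id <- sprintf("%s:d%d", gene, d)
    parts <- make_domain_residues(dom_id)
    add(parts$chars, parts$cls, rep(dom_id, length(parts$chars)),
        parts$hpos, rep(dom_id, length(parts$chars)), parts$protected)
  }
  add_flank(sample(20:60, 1), "flankC")
  list(id = new_ids(length(chars), "r"), char = chars, class = cls,
       domain = dom, hpos = hpos, seg = seg, protected = protected)
}

# one C2H2-ZF domain: C-X(c1)-C-X(c2)-Psi-X(2)-H-X(c3)-H
make_domain_residues <- function(dom_id) {
  c1 <- sample(2:4, 1); c2 <- sample(8:12, 1); c3 <- sample(3:5, 1)
  psi <- sample(c("F", "Y", "W", "L", "I", "V", "M"), 1)
  chars <- c("C", rand_aa(c1), "C", rand_aa(c2), psi, rand_aa(2), "H",
             rand_aa(c3), "H")
  n <- length(chars)
  pos7 <- 1L + c1 + 1L + c2 + 1L + 2L + 1L  # 1-based index of the anchor H
  hpos <- rep(NA_integer_, n)
  hpos[pos7] <- 7L
  hpos[pos7 - 7L] <- -1L
  for (p in 1:6) hpos[pos7 - (7L - p)] <- p
  cls <- rep("C2H2_NONBINDING", n)
  cls[which(hpos %in% BINDING_POSITIONS)] <- "BINDING"
  cls[which(hpos %in% HELIX_EXCLUDED_POSITIONS)] <- "HELIX_EXCLUDED"
  protected <- rep(FALSE, n)
  protected[c(1, 1 + c1 + 1, pos7, n)] <- TRUE      # coordinating C/C/H/H
  protected[which(hpos == 4L)] <- TRUE              # Psi is helix position 4
  cls[protected & is.na(hpos)] <- "C2H2_NONBINDING"
  list(chars = chars, cls = cls, hpos = hpos, protected = protected)
}

new_domain_insert <- function(gene, tag) {
  parts <- make_domain_residues(sprintf("%s:%s", gene, tag))
  len_link <- sample(5:12, 1)
  link <- rand_aa(len_link)
  if (len_link >= 7) {
    link[1:6] <- c("T", "G", "E", sample(c("K", "R"), 1), "P",
                   sample(c("F", "Y"), 1))
  }
  dom_id <- sprintf("%s:%s", gene, tag)
  list(
    id = sprintf("%s:%s:r%d", gene, tag,
                 seq_len(len_link + length(parts$chars))),
    char = c(link, parts$chars),
    class = c(rep("LINKER", len_link), parts$cls),
    domain = c(rep(NA_character_, len_link), rep(dom_id, length(parts$chars))),
    hpos = c(rep(NA_integer_, len_link), parts$hpos),
    seg = c(rep(paste0("link_", dom_id), len_link),
            rep(dom_id, length(parts$chars))),
    protected = c(rep(FALSE, len_link), parts$protected)
  )
}

#' Simulate poly-ZF gene families along the species tree
#'
#' Ancestral poly-ZF proteins (domains matching the structural expression,
#' mostly canonical linkers) are evolved along the tree. Substitution counts
#' per branch are Poisson with mean rate x branch length x eligible sites of
#' each class; BINDING substitutions are redirected onto internal branches
#' with probability `clade_consistent_fraction`, creating clade-support
#' signal. Domain loss and gain events are applied per branch. Every event is
#' recorded in a ground-truth ledger keyed by stable residue and domain ids,
#' sufficient to recompute every expected summary independently of the
#' analysis pipeline. Fully reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @return A `zf_simulation`: `proteins`, `ortholog_pairs`, `species_tree`,
#'   `reference` and `truth` (ancestral/species residue states plus the event
#'   ledger).
#' @export
simulate_families <- function(config = sim_config()) {
  set.seed(config$seed)
  tree <- config$species_tree
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  elen <- tree$edge.length
  node_label <- c(tree$tip.label, sprintf("n%d", (ntip + 1):(ntip + tree$Nnode)))
  is_terminal_edge <- edges[, 2] <= ntip
  # weights steering BINDING substitutions toward internal branches
  len_int <- sum(elen[!is_terminal_edge]); len_ter <- sum(elen[is_terminal_edge])
  f <- config$clade_consistent_fraction
  w_binding <- ifelse(is_terminal_edge,
                      if (len_ter > 0) (1 - f) * (len_int + len_ter) / len_ter else 0,
                      if (len_int > 0) f * (len_int + len_ter) / len_int else 0)

  # nodes on the root -> reference path: domain loss/gain is kept off this
  # path so the reference architecture stays ancestral and reference-anchored
  # loss/gain ground truth is unambiguous
  ref_tip <- match(config$reference, tree$tip.label)
  parent_of <- rep(NA_integer_, ntip + tree$Nnode)
  parent_of[edges[, 2]] <- edges[, 1]
  ref_path <- ref_tip
  while (!is.na(parent_of[ref_path[length(ref_path)]])) {
    ref_path <- c(ref_path, parent_of[ref_path[length(ref_path)]])
  }

  genes <- sprintf("g%03d", seq_len(config$n_genes))
  ancestral <- setNames(map(genes, function(g) {
    build_ancestral_gene(g, sample(config$domain_range[1]:config$domain_range[2], 1))
  }), genes)

  events <- list()
  push_event <- function(...) events[[length(events) + 1L]] <<- list(...)

  # preorder edge traversal; states held per node
  states <- vector("list", ntip + tree$Nnode)
  root <- setdiff(edges[, 1], edges[, 2])[1]
  states[[root]] <- ancestral
  preorder <- rev(ape::postorder(tree))
  for (e in preorder) {
    a <- edges[e, 1]; b <- edges[e, 2]; t_len <- elen[e]
    branch <- node_label[b]
    st <- states[[a]]
    on_ref_path <- b %in% ref_path
    for (g in genes) {
      gs <- st[[g]]
      # domain losses (never below one remaining domain)
      doms <- unique(gs$domain[!is.na(gs$domain)])
      if (!on_ref_path && length(doms) > 1 && config$domain_loss_rate > 0) {
        p_loss <- 1 - exp(-config$domain_loss_rate * t_len)
        lose <- doms[runif(length(doms)) < p_loss]
        if (length(lose) >= length(doms)) lose <- lose[-1]
        for (dm in lose) {
          drop <- gs$seg == dm
          # drop one bordering linker segment with the domain
          segs <- rle(gs$seg)
          pos <- which(segs$values == dm)
          nb <- if (pos < length(segs$values) &&
                      grepl("^link", segs$values[pos + 1])) {
            segs$values[pos + 1]
          } else if (pos > 1 && grepl("^link", segs$values[pos - 1])) {
            segs$values[pos - 1]
          } else NA_character_
          if (!is.na(nb)) drop <- drop | gs$seg == nb
          gs <- map(gs, function(v) v[!drop])
          push_event(event = "domain_loss", branch = branch, gene = g,
                     res_id = NA_character_, domain_id = dm,
                     helix_pos = NA_integer_, class = NA_character_,
                     from = NA_character_, to = NA_character_)
        }
      }
      # domain gains, inserted mid-way into the C-terminal flank so a new
      # domain never occupies the locus of a lost one
      n_gain <- if (on_ref_path) 0L else
        rpois(1, config$domain_gain_rate * t_len)
      for (k in seq_len(n_gain)) {
        tag <- sprintf("gain_%s_%d", branch, k)
        ins <- new_domain_insert(g, tag)
        flank <- which(gs$seg == "flankC")
        at <- flank[ceiling(length(flank) / 2)]
        gs <- map2(gs, ins, function(v, w) append(v, w, after = at))
        push_event(event = "domain_gain", branch = branch, gene = g,
                   res_id = NA_character_, domain_id = sprintf("%s:%s", g, tag),
                   helix_pos = NA_integer_, class = NA_character_,
                   from = NA_character_, to = NA_character_)
      }
      # background deletions (indel noise)
      if (config$indel_rate > 0) {
        eligible_bg <- which(gs$class == "BACKGROUND" & !gs$protected)
        n_del <- rpois(1, config$indel_rate * t_len * length(eligible_bg))
        if (n_del > 0) {
          at <- sample(eligible_bg, min(n_del, length(eligible_bg)))
          for (i in at) {
            push_event(event = "deletion", branch = branch, gene = g,
                       res_id = gs$id[i], domain_id = NA_character_,
                       helix_pos = NA_integer_, class = "BACKGROUND",
                       from = gs$char[i], to = NA_character_)
          }
          keep_idx <- setdiff(seq_along(gs$id), at)
          gs <- map(gs, function(v) v[keep_idx])
        }
      }
      # substitutions per residue class
      for (cl in RESIDUE_CLASSES) {
        eligible <- which(gs$class == cl & !gs$protected)
        if (length(eligible) == 0) next
        rate <- config$rates[[cl]] * t_len
        if (cl == "BINDING") rate <- rate * w_binding[e]
        n_sub <- rpois(1, rate * length(eligible))
        if (n_sub == 0) next
        at <- sample(eligible, n_sub, replace = TRUE)
        for (i in at) {
          old <- gs$char[i]
          new <- sample(setdiff(SAFE_AA, old), 1)
          gs$char[i] <- new
          push_event(event = "substitution", branch = branch, gene = g,
                     res_id = gs$id[i], domain_id = gs$domain[i],
                     helix_pos = gs$hpos[i], class = cl,
                     from = old, to = new)
        }
      }
      st[[g]] <- gs
    }
    states[[b]] <- st
  }
  species_states <- setNames(states[seq_len(ntip)], tree$tip.label)

  proteins <- map(tree$tip.label, function(sp) {
    tibble(species = sp, gene_base = genes,
           gene_id = sprintf("%s_%s", genes, sp),
           protein_id = sprintf("P_%s_%s", genes, sp),
           sequence = map_chr(genes, function(g)
             paste_chars(species_states[[sp]][[g]]$char)))
  }) %>% list_rbind()
  ref <- config$reference
  pairs <- proteins %>%
    filter(.data$species != ref) %>%
    mutate(ref_gene = sprintf("%s_%s", .data$gene_base, ref)) %>%
    select("ref_gene", "species", "gene_id")
  structure(list(
    config = config, species_tree = tree, reference = ref,
    proteins = select(proteins, "protein_id", "gene_id", "species",
                      "sequence", "gene_base"),
    ortholog_pairs = pairs,
    truth = list(ancestral = ancestral, species_states = species_states,
                 events = if (length(events)) {
                   fields <- names(events[[1]])
                   as_tibble(setNames(map(fields, function(f)
                     unlist(map(events, f), use.names = FALSE)), fields))
                 } else {
                   tibble(event = character(), branch = character(),
                          gene = character(), res_id = character(),
                          domain_id = character(), helix_pos = integer(),
                          class = character(), from = character(),
                          to = character())
                 })
  ), class = "zf_simulation")
}

#' @export
print.zf_simulation <- function(x, ...) {
  cat(sprintf("<zf_simulation> %d genes x %d species (seed %d), %d events\n",
              x$config$n_genes, length(x$species_tree$tip.label),
              x$config$seed, nrow(x$truth$events)))
  invisible(x)
}

#' Ledger-derived expected loss / gain / divergence percentages
#'
#' Recomputes, from the simulation's ground-truth residue states alone (no
#' alignment, no domain calling), the per-species percentage of reference
#' domains lost, species domains gained, and shared domains with a divergent
#' DNA-contacting residue - the quantities the pipeline should report on
#' indel-free runs.
#'
#' @param sim A [simulate_families()] result.
#' @param min_domains Poly-ZF threshold applied to the reference gene,
#'   mirroring the pipeline's orthogroup filter.
#' @return Tibble `species`, `metric`, `numerator`, `denominator`, `value`.
#' @export
expected_divergence_from_truth <- function(sim, min_domains = 2L) {
  ref <- sim$reference
  ref_states <- sim$truth$species_states[[ref]]
  others <- setdiff(names(sim$truth$species_states), ref)
  gene_domains <- function(gs) unique(gs$domain[!is.na(gs$domain)])
  polyzf <- names(ref_states)[vapply(ref_states, function(gs)
    length(gene_domains(gs)) >= min_domains, logical(1))]
  ref_states <- ref_states[polyzf]
  rows <- map(others, function(sp) {
    sp_states <- sim$truth$species_states[[sp]]
    lost_n <- 0L; lost_d <- 0L
    gain_n <- 0L; gain_d <- 0L
    div_n <- 0L; div_d <- 0L
    for (g in names(ref_states)) {
      rd <- gene_domains(ref_states[[g]])
      present_somewhere <- unique(unlist(map(
        others, function(s2) gene_domains(sim$truth$species_states[[s2]][[g]]))))
      evaluated <- intersect(rd, present_somewhere)
      sd <- gene_domains(sp_states[[g]])
      shared <- intersect(evaluated, sd)
      lost_d <- lost_d + length(evaluated)
      lost_n <- lost_n + length(setdiff(evaluated, sd))
      gained <- setdiff(sd, rd)
      gain_d <- gain_d + length(shared) + length(gained)
      gain_n <- gain_n + length(gained)
      rgs <- ref_states[[g]]; sgs <- sp_states[[g]]
      for (dm in shared) {
        rmask <- which(rgs$domain %in% dm & rgs$hpos %in% BINDING_POSITIONS)
        rchar <- setNames(rgs$char[rmask], rgs$id[rmask])
        smask <- which(sgs$domain %in% dm & sgs$hpos %in% BINDING_POSITIONS)
        schar <- setNames(sgs$char[smask], sgs$id[smask])
        common <- intersect(names(rchar), names(schar))
        div_d <- div_d + 1L
        if (any(rchar[common] != schar[common])) div_n <- div_n + 1L
      }
    }
    tibble(species = sp,
           metric = c("pct_domains_lost", "pct_domains_gained",
                      "pct_domains_diverged"),
           numerator = c(lost_n, gain_n, div_n),
           denominator = c(lost_d, gain_d, div_d))
  }) %>% list_rbind()
  mutate(rows, value = if_else(.data$denominator > 0,
                               100 * .data$numerator / .data$denominator,
                               NA_real_))
}

#' Simulate a population polymorphism table
#'
#' Reference sites that diverged in at least one species are polymorphic with
#' probability `p_polymorphic_selected` (BINDING class) or
#' `p_polymorphic_neutral` (all other classes); non-divergent sites segregate
#' at `background_poly_density`. Minor-allele counts follow a folded neutral
#' spectrum (probability proportional to 1/i up to n/2).
#'
#' @param sim A [simulate_families()] result.
#' @param seed Optional seed (defaults to `config$seed + 1`).
#' @return List `table` (tibble `gene_id`, `ref_index`, `minor_count`,
#'   `sample_size`) and `truth` (per-site labels).
#' @export
simulate_polymorphisms <- function(sim, seed = NULL) {
  config <- sim$config
  set.seed(seed %||% (config$seed + 1L))
  ref <- sim$reference
  ref_states <- sim$truth$species_states[[ref]]
  others <- setdiff(names(sim$truth$species_states), ref)
  max_minor <- floor(config$sample_size / 2)
  sfs_w <- (1 / seq_len(max_minor))
  sfs_w <- sfs_w / sum(sfs_w)
  rows <- map(names(ref_states), function(g) {
    gs <- ref_states[[g]]
    # divergent site: reference residue differs in >=1 species (by stable id)
    diff_any <- rep(FALSE, length(gs$id))
    for (sp in others) {
      ss <- sim$truth$species_states[[sp]][[g]]
      hit <- match(gs$id, ss$id)
      ok <- !is.na(hit)
      diff_any[ok] <- diff_any[ok] | (gs$char[ok] != ss$char[hit[ok]])
    }
    p <- ifelse(diff_any,
                ifelse(gs$class == "BINDING", config$p_polymorphic_selected,
                       config$p_polymorphic_neutral),
                config$background_poly_density)
    poly <- runif(length(p)) < p
    tibble(gene_id = sprintf("%s_%s", g, ref),
           ref_index = seq_along(gs$id) - 1L,
           class = gs$class, divergent = diff_any, polymorphic = poly)
  }) %>% list_rbind()
  tab <- rows %>%
    filter(.data$polymorphic) %>%
    mutate(minor_count = sample(seq_len(max_minor), n(), replace = TRUE,
                                prob = sfs_w),
           sample_size = config$sample_size) %>%
    select("gene_id", "ref_index", "minor_count", "sample_size")
  list(table = tab, truth = rows)
}

#' Simulate promoters with planted, decaying binding sites
#'
#' Background sequence is i.i.d. from the base composition; planted sites are
#' drawn from each TF's PWM at the configured density in the reference. Along
#' every branch a planted site is destroyed (its bases re-randomized) with
#' the TF-class-specific per-branch loss probability; destruction is
#' inherited by the whole descendant clade. The alignment is gap-free.
#'
#' @param config A [sim_config()].
#' @param tf_classes Tibble `pwm_id`, `tf_class` in conserved/diverged; by
#'   default half of `n_tfs` each.
#' @param background Base composition.
#' @param seed Optional seed (defaults to `config$seed + 2`).
#' @return List `promoters` ([promoter_alignment()]), `pwms` (named list),
#'   `tf_classes`, and `truth` (planted sites and per-species survival).
#' @export
simulate_promoters <- function(config = sim_config(), tf_classes = NULL,
                               background = rep(0.25, 4), seed = NULL) {
  set.seed(seed %||% (config$seed + 2L))
  tree <- config$species_tree
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  node_label <- c(tree$tip.label, sprintf("n%d", (ntip + 1):(ntip + tree$Nnode)))
  if (is.null(tf_classes)) {
    tf_classes <- tibble(
      pwm_id = sprintf("tf%02d", seq_len(config$n_tfs)),
      tf_class = rep(c("conserved", "diverged"), length.out = config$n_tfs))
  }
  w <- 8L
  pwms <- setNames(map(seq_len(nrow(tf_classes)), function(i) {
    repeat {
      cons <- sample(DNA_BASES, w, replace = TRUE)
      if (max(table(cons)) <= 6) break  # keep complexity QC satisfiable
    }
    mat <- vapply(cons, function(b) {
      p <- rep(0.05, 4); p[match(b, DNA_BASES)] <- 0.85; p
    }, numeric(4))
    new_pwm(mat)
  }), tf_classes$pwm_id)
  L <- config$promoter_length
  promoter_ids <- sprintf("prom%04d", seq_len(config$n_promoters))
  ref_seqs <- map(promoter_ids, function(p) {
    sample(DNA_BASES, L, replace = TRUE, prob = background)
  })
  names(ref_seqs) <- promoter_ids
  planted <- list()
  for (i in seq_len(nrow(tf_classes))) {
    id <- tf_classes$pwm_id[i]
    m <- unclass(pwms[[id]])
    for (p in promoter_ids) {
      n_sites <- rbinom(1, L, config$site_density)
      if (n_sites == 0) next
      starts <- sample(0:(L - w), n_sites)
      for (s in starts) {
        word <- map_chr(seq_len(w), function(j)
          sample(DNA_BASES, 1, prob = m[, j]))
        ref_seqs[[p]][(s + 1):(s + w)] <- word
        planted[[length(planted) + 1L]] <-
          tibble(pwm_id = id, tf_class = tf_classes$tf_class[i],
                 promoter_id = p, start = s, word = paste_chars(word))
      }
    }
  }
  planted <- list_rbind(planted) %||%
    tibble(pwm_id = character(), tf_class = character(),
           promoter_id = character(), start = integer(), word = character())
  # per-branch destruction, inherited by descendants; the reference lineage
  # is exempt (a site planted in the reference is present there by
  # construction)
  loss_p <- c(conserved = config$site_loss_conserved,
              diverged = config$site_loss_diverged)
  n_sites <- nrow(planted)
  alive <- matrix(TRUE, nrow = n_sites, ncol = ntip + tree$Nnode)
  fills <- vector("list", n_sites)
  destroyed_at <- rep(NA_character_, n_sites)
  ref_tip <- match(config$reference, tree$tip.label)
  parent_of <- rep(NA_integer_, ntip + tree$Nnode)
  parent_of[edges[, 2]] <- edges[, 1]
  ref_path <- ref_tip
  while (!is.na(parent_of[ref_path[length(ref_path)]])) {
    ref_path <- c(ref_path, parent_of[ref_path[length(ref_path)]])
  }
  for (e in rev(ape::postorder(tree))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    alive[, b] <- alive[, a]
    if (n_sites == 0 || b %in% ref_path) next
    die <- alive[, b] & runif(n_sites) < loss_p[planted$tf_class]
    for (i in which(die)) {
      fills[[i]] <- sample(DNA_BASES, w, replace = TRUE, prob = background)
      destroyed_at[i] <- node_label[b]
    }
    alive[die, b] <- FALSE
  }
  rows <- map(tree$tip.label, function(sp) {
    tipi <- match(sp, tree$tip.label)
    map(promoter_ids, function(p) {
      s <- ref_seqs[[p]]
      idx <- which(planted$promoter_id == p & !alive[, tipi])
      for (i in idx) {
        st <- planted$start[i]
        s[(st + 1):(st + w)] <- fills[[i]]
      }
      tibble(promoter_id = p, species = sp, offset = 0L,
             aligned = paste_chars(s))
    }) %>% list_rbind()
  }) %>% list_rbind()
  survival <- NULL
  if (n_sites > 0) {
    survival <- map(tree$tip.label, function(sp) {
      tipi <- match(sp, tree$tip.label)
      mutate(planted, species = sp, surviving = alive[, tipi])
    }) %>% list_rbind()
  }
  list(promoters = promoter_alignment(rows), pwms = pwms,
       tf_classes = tf_classes,
       truth = list(planted = planted, survival = survival,
                    destroyed_at = destroyed_at))
}

#' Simulate per-class clade-support site outcomes
#'
#' Draws supported/unsupported outcomes for divergent sites of each residue
#' class at the given support probabilities, returning the per-class count
#' table consumed by the clade-support comparison. Used for calibration and
#' power studies of the BINDING-versus-BACKGROUND binomial test.
#'
#' @param n Named integer vector of eligible divergent sites per class.
#' @param p Named support probability per class.
#' @param species Species label for the output rows.
#' @return A `zf_class_comparison` (classes plus the binomial test).
#' @export
simulate_support_sites <- function(n, p, species = "spA") {
  classes <- tibble(
    species = species, class = names(n),
    numerator = map_int(names(n), function(cl)
      rbinom(1, n[[cl]], p[[cl]])),
    denominator = as.integer(unname(n))
  ) %>% mutate(proportion = .data$numerator / .data$denominator)
  binding_vs_background(classes, "clade_support")
}

#' Simulate TF-level binding-conservation fractions
#'
#' Fraction-level model of binding-site turnover: each TF binds a Binomial
#' number of promoters; each bound promoter stays bound in a species with
#' probability `1 - p_loss` of its TF class. Returns the conservation
#' fractions and TF classes consumed by [compare_conserved_vs_diverged()].
#'
#' @param n_tfs,n_promoters Scale (TFs split evenly between classes).
#' @param p_loss_conserved,p_loss_diverged Per-species site-loss probability.
#' @param species Evaluated species labels.
#' @param p_bound Probability a promoter is bound in the reference.
#' @return List `fractions`, `tf_classes`.
#' @export
simulate_site_turnover <- function(n_tfs = 20L, n_promoters = 200L,
                                   p_loss_conserved = 0.1,
                                   p_loss_diverged = 0.5,
                                   species = paste0("sp", 1:7),
                                   p_bound = 0.3) {
  tf_classes <- tibble(
    pwm_id = sprintf("tf%02d", seq_len(n_tfs)),
    tf_class = rep(c("conserved", "diverged"), length.out = n_tfs))
  p_loss <- c(conserved = p_loss_conserved, diverged = p_loss_diverged)
  fractions <- map(species, function(sp) {
    n_bound <- pmax(1L, rbinom(n_tfs, n_promoters, p_bound))
    conserved <- rbinom(n_tfs, n_bound, 1 - p_loss[tf_classes$tf_class])
    tibble(species = sp, pwm_id = tf_classes$pwm_id,
           n_bound_promoters = n_bound,
           n_promoters_conserved = conserved,
           fraction_promoters_conserved = conserved / n_bound)
  }) %>% list_rbind()
  labels <- map(species, function(sp) {
    tibble(pwm_id = tf_classes$pwm_id, species = sp,
           label = if_else(tf_classes$tf_class == "conserved",
                           "conserved_all", "diverged_here"))
  }) %>% list_rbind()
  list(fractions = fractions, tf_classes = labels)
}
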