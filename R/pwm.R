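#' Construct a position weight matrix
#'
#' A PWM is a 4 x L column-stochastic matrix over bases A, C, G, T.
#'
#' @param mat Numeric matrix (4 rows, or coercible) of column probabilities.
#' @return A `zf_pwm` matrix with rownames A, C, G, T.
#' @export
new_pwm <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) abort("a PWM has 4 rows (A, C, G, T)")
  if (ncol(mat) < 1) abort("a PWM has at least one column")
  if (any(mat < 0)) abort("PWM entries must be non-negative")
  sums <- colSums(mat)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("PWM columns must sum to 1 (tolerance 1e-9)")
  }
  dimnames(mat) <- list(DNA_BASES, NULL)
  structure(mat, class = c("zf_pwm", "matrix", "array"))
}

#' @export
print.zf_pwm <- function(x, ...) {
  cat(sprintf("<zf_pwm> %d columns, consensus %s\n", ncol(x),
              paste(pwm_consensus(x), collapse = "")))
  print(unclass(x))
  invisible(x)
}

#' Per-column information content of a PWM
#'
#' IC in bits against a uniform background: `2 + sum(p * log2(p))`.
#'
#' @param pwm A [new_pwm()] matrix.
#' @return Numeric vector of per-column IC values.
#' @export
pwm_ic <- function(pwm) {
  unname(apply(unclass(pwm), 2, function(p) {
    nz <- p[p > 0]
    2 + sum(nz * log2(nz))
  }))
}

#' Consensus base per PWM column ('N' on ties)
#' @param pwm A PWM.
#' @return Character vector of consensus bases.
#' @export
pwm_consensus <- function(pwm) {
  apply(unclass(pwm), 2, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1) "N" else DNA_BASES[top]
  })
}

#' Reverse complement of a PWM
#' @param pwm A PWM.
#' @return The reverse-complement PWM.
#' @export
pwm_reverse_complement <- function(pwm) {
  m <- unclass(pwm)
  new_pwm(m[4:1, rev(seq_len(ncol(m))), drop = FALSE])
}

#' Column-wise Pearson correlation between two PWMs
#'
#' Pearson correlation of the four base probabilities per column, and their
#' average over the requested positions. A zero-variance column pair scores 1
#' when the columns are equal within 1e-9 and 0 otherwise (declared
#' convention for degenerate columns).
#'
#' @param pwm_a,pwm_b PWMs of equal length.
#' @param positions Columns to average over (default all).
#' @return List with `per_position` (numeric vector) and `average`.
#' @export
pwm_pcc <- function(pwm_a, pwm_b, positions = NULL) {
  a <- unclass(pwm_a); b <- unclass(pwm_b)
  if (ncol(a) != ncol(b)) abort("PWMs must have equal length")
  positions <- positions %||% seq_len(ncol(a))
  per <- map_dbl(seq_len(ncol(a)), function(j) {
    x <- a[, j]; y <- b[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(if (max(abs(x - y)) <= 1e-9) 1 else 0)
    }
    stats::cor(x, y)
  })
  list(per_position = per, average = mean(per[positions]))
}

#' Quality-control a PWM
#'
#' Fails motifs with fewer than `min_informative` columns of information
#' content above `ic_cutoff`, low-complexity motifs where more than
#' `max_consensus_frac` of the informative columns share one consensus base,
#' and (when `n_partner_species` is given) TFs whose 1-to-1 orthogroup covers
#' fewer than `min_partner_species` non-reference species.
#'
#' @param pwm A PWM.
#' @param ic_cutoff Informative-column IC threshold (bits).
#' @param min_informative Minimum number of informative columns.
#' @param max_consensus_frac Maximum fraction of informative columns sharing
#'   one consensus base.
#' @param n_partner_species Optional count of non-reference species with a
#'   1-to-1 ortholog of the TF.
#' @param min_partner_species Minimum such species.
#' @return Tibble `pass` plus `reasons` (comma-separated failure reasons).
#' @export
qc_pwm <- function(pwm, ic_cutoff = 0.5, min_informative = 6L,
                   max_consensus_frac = 0.8, n_partner_species = NULL,
                   min_partner_species = 2L) {
  ic <- pwm_ic(pwm)
  informative <- ic > ic_cutoff
  reasons <- character()
  if (sum(informative) < min_informative) reasons <- c(reasons, "low_ic")
  if (sum(informative) > 0) {
    cons <- pwm_consensus(pwm)[informative]
    cons <- cons[cons != "N"]
    if (length(cons) > 0 &&
        max(table(cons)) / sum(informative) > max_consensus_frac) {
      reasons <- c(reasons, "low_complexity")
    }
  }
  if (!is.null(n_partner_species) &&
      n_partner_species < min_partner_species) {
    reasons <- c(reasons, "too_few_orthologs")
  }
  tibble(pass = length(reasons) == 0,
         reasons = paste(reasons, collapse = ","),
         n_informative = sum(informative))
}

#' Read PWMs in MEME minimal motif format
#'
#' @param path File path.
#' @return Named list of `zf_pwm` objects; the background line, when present,
#'   is attached as attribute `background`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  background <- NULL
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at) == 1 && bg_at < length(lines)) {
    f <- strsplit(trimws(lines[bg_at + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(f[seq(2, length(f), by = 2)]))
    names(vals) <- f[seq(1, length(f), by = 2)]
    if (!anyNA(vals)) background <- vals[DNA_BASES]
  }
  motif_at <- grep("^MOTIF\\s+", lines)
  pwms <- map(motif_at, function(i) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    j <- i
    while (j <= length(lines) &&
             !grepl("^letter-probability matrix", lines[j])) j <- j + 1
    if (j > length(lines)) abort(sprintf("motif %s has no probability matrix", id))
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[j])
    w <- as.integer(w)
    rows <- lines[(j + 1):(j + w)]
    mat <- t(vapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(4), USE.NAMES = FALSE))
    # MEME rows are positions; renormalize tiny rounding drift
    mat <- t(mat)
    mat <- sweep(mat, 2, colSums(mat), "/")
    list(id = id, pwm = new_pwm(mat))
  })
  out <- setNames(map(pwms, "pwm"), map_chr(pwms, "id"))
  attr(out, "background") <- background
  out
}

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms Named list of PWMs.
#' @param path Output path.
#' @param background Base frequencies (default uniform).
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""), con)
  for (id in names(pwms)) {
    m <- unclass(pwms[[id]])
    writeLines(sprintf("MOTIF %s", id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", ncol(m)),
      con)
    for (j in seq_len(ncol(m))) {
      writeLines(paste(sprintf("%.6f", m[, j]), collapse = "  "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
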