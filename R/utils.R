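check_aa_sequence <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    abort(sprintf("%s must be a single non-empty string", what))
  }
  chars <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad) > 0) {
    abort(sprintf("%s contains characters outside the amino-acid alphabet: %s",
                  what, paste(bad, collapse = ", ")))
  }
  invisible(sequence)
}

# 0-based half-open [start, end) -> substring
substr0 <- function(x, start, end) substr(x, start + 1L, end)

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' @noRd
paste_chars <- function(x) paste(x, collapse = "")

stopifnot_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required columns: %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# deterministic tab-separated writer used by all stage outputs
write_tsv_plain <- function(df, path, comment_lines = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (line in comment_lines) writeLines(paste0("# ", line), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       comment.char = "#", stringsAsFactors = FALSE,
                       check.names = FALSE))
}
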