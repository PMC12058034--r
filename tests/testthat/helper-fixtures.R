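# Shared test helpers: small random datasets and in-code FASTA fixtures.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequences <- function(n, len_min, len_max) {
  lens <- len_min + sample.int(len_max - len_min + 1L, n, replace = TRUE) - 1L
  vapply(lens, function(L) paste(sample(AA20, L, replace = TRUE),
                                 collapse = ""), "")
}

random_dataset <- function(seed, n_min = 5, n_max = 30,
                           len_min = 20, len_max = 80) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  protein_dataset(sprintf("P%04d", seq_len(n)),
                  random_sequences(n, len_min, len_max),
                  dataset_name = paste0("rand", seed))
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# sorted data.frame view of a pattern_set for set-wise comparison
pattern_view <- function(ps) {
  df <- data.frame(pattern = ps$pattern, support = ps$support_count,
                   stringsAsFactors = FALSE)
  df$accessions <- lapply(ps$accessions, sort)
  df[order(df$pattern), , drop = FALSE]
}

expect_same_patterns <- function(a, b) {
  va <- pattern_view(a)
  vb <- pattern_view(b)
  rownames(va) <- rownames(vb) <- NULL
  expect_equal(va, vb)
}
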