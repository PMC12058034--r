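# Residue classifications used by the class-based schemes. Full scheme
# (Valdar-style): hydrophobic/small/aromatic/positive/negative; reduced
# scheme: tiny/aliphatic/aromatic/positive/negative. Residues outside the
# union of groups are "unclassified" and score as a gap when aligned.
AA_CLASSES_FULL <- list(
  hydrophobic = c("I", "L", "V", "C", "A", "G", "M", "F", "Y", "W", "H", "K", "T"),
  small       = c("V", "C", "A", "G", "D", "N", "S", "T", "P"),
  aromatic    = c("F", "Y", "W", "H"),
  positive    = c("H", "K", "R"),
  negative    = c("E", "D")
)
AA_CLASSES_REDUCED <- list(
  tiny      = c("A", "G", "S"),
  aliphatic = c("I", "L", "V"),
  aromatic  = c("F", "Y", "W"),
  positive  = c("H", "K", "R"),
  negative  = c("E", "D")
)

SCHEME_NAMES <- c("nw_weights", "class_amino_acids",
                  "class_amino_acids_reduced", "blosum")

# Canonical 24-letter BLOSUM62 (20 standard + B, Z, X), taken from the
# matrix shipped with Biostrings.
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <- env$BLOSUM62
      keep <- setdiff(rownames(m), c("J", "*"))
      cache <<- m[keep, keep]
    }
    cache
  }
})

#' Build one of the four pair-scoring schemes
#'
#' All schemes share the default weights: match 3, mismatch 0, gap -1 (per
#' aligned gap position). `"nw_weights"` scores identity only.
#' `"class_amino_acids"` and `"class_amino_acids_reduced"` score a match
#' whenever the two residues share a physicochemical group, a mismatch when
#' both are classified but share no group, and the gap penalty when at
#' least one residue is unclassified (the rule is applied literally, so
#' e.g. Q-Q scores -1 under the full classification). `"blosum"` uses the
#' BLOSUM62 entry when both residues are covered (20 standard letters plus
#' B, Z, X, as shipped with Biostrings: the 20x20 core is the canonical
#' matrix, the ambiguity rows follow Biostrings' convention) and falls back
#' to the identity match/mismatch defaults otherwise (J, O, U).
#'
#' @param name one of `"nw_weights"`, `"class_amino_acids"`,
#'   `"class_amino_acids_reduced"`, `"blosum"`.
#' @param match_default,mismatch_default,gap_penalty default weights.
#' @return A `scoring_scheme` object.
#' @export
build_scheme <- function(name = SCHEME_NAMES, match_default = 3,
                         mismatch_default = 0, gap_penalty = -1) {
  name <- match.arg(name)
  groups <- switch(name,
                   class_amino_acids = AA_CLASSES_FULL,
                   class_amino_acids_reduced = AA_CLASSES_REDUCED,
                   NULL)
  structure(list(name = name, groups = groups,
                 match = match_default, mismatch = mismatch_default,
                 gap = gap_penalty),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring_scheme '", x$name, "': match ", x$match, ", mismatch ",
      x$mismatch, ", gap ", x$gap, "\n", sep = "")
  if (!is.null(x$groups))
    for (g in names(x$groups))
      cat("  ", g, ": ", paste(x$groups[[g]], collapse = " "), "\n", sep = "")
  invisible(x)
}

as_scheme <- function(scheme) {
  if (inherits(scheme, "scoring_scheme")) scheme else build_scheme(scheme)
}

# Symmetric pair-score lookup matrix over a given residue alphabet.
score_matrix <- function(scheme, alphabet) {
  k <- length(alphabet)
  M <- matrix(scheme$mismatch, k, k, dimnames = list(alphabet, alphabet))
  if (scheme$name == "nw_weights") {
    diag(M) <- scheme$match
  } else if (scheme$name == "blosum") {
    B <- blosum62_matrix()
    diag(M) <- scheme$match
    inb <- alphabet[alphabet %in% rownames(B)]
    M[inb, inb] <- B[inb, inb]
  } else {
    membership <- sapply(scheme$groups,
                         function(g) alphabet %in% g)  # k x n_groups
    if (k == 1) membership <- matrix(membership, nrow = 1)
    shared <- membership %*% t(membership)  # >0 iff some shared group
    classified <- rowSums(membership) > 0
    M[shared > 0] <- scheme$match
    M[!classified, ] <- scheme$gap
    M[, !classified] <- scheme$gap
  }
  M
}

#' Score one aligned residue pair
#'
#' @param a,b single residue characters.
#' @param scheme a `scoring_scheme` or scheme name.
#' @return Numeric pair score.
#' @export
pair_score <- function(a, b, scheme) {
  scheme <- as_scheme(scheme)
  alphabet <- unique(c(a, b))
  unname(score_matrix(scheme, alphabet)[a, b])
}

#' Global alignment score (customized Needleman-Wunsch)
#'
#' Fills the standard global-alignment dynamic program
#' `F[i,j] = max(F[i-1,j-1] + s(a_i, b_j), F[i-1,j] + gap, F[i,j-1] + gap)`
#' with `F[0,0] = 0` and cumulative gap penalties along the first row and
#' column (leading/trailing gaps are charged), and returns the final cell.
#' Linear per-position gap penalty; no traceback is computed, so
#' tie-breaking cannot affect the result.
#'
#' @param seq1,seq2 amino-acid strings (may be empty).
#' @param scheme a `scoring_scheme` or scheme name.
#' @return Numeric optimal alignment score; symmetric in its arguments.
#' @export
nw_raw_score <- function(seq1, seq2, scheme) {
  scheme <- as_scheme(scheme)
  g <- scheme$gap
  a <- strsplit(seq1, "")[[1]]
  b <- strsplit(seq2, "")[[1]]
  n <- length(a)
  m <- length(b)
  if (n == 0 || m == 0) return(g * (n + m))
  alphabet <- unique(c(a, b))
  M <- score_matrix(scheme, alphabet)
  ai <- match(a, alphabet)
  bi <- match(b, alphabet)
  gj <- g * (0:m)
  prev <- gj  # row 0: cumulative gap penalties
  for (i in seq_len(n)) {
    subs <- M[ai[i], bi]
    # candidates ignoring the in-row (left) dependency ...
    cand <- pmax(prev[1:m] + subs, prev[2:(m + 1)] + g)
    # ... then fold in horizontal gap moves with a prefix-max scan:
    # F[i,j] = g*j + max_{k<=j}(B[k] - g*k)
    B <- c(prev[1] + g, cand)
    prev <- cummax(B - gj) + gj
  }
  unname(prev[m + 1])
}

#' Exhaustive alignment score (independent oracle)
#'
#' Maximizes the alignment score by enumerating every order-preserving
#' matching of residue positions between the two sequences (each alignment
#' is exactly such a matching; all unmatched residues are gap positions).
#' Exponential; guarded to short sequences.
#'
#' @inheritParams nw_raw_score
#' @param max_total_length guard on `nchar(seq1) + nchar(seq2)`.
#' @return Numeric optimal alignment score.
#' @export
oracle_alignment_score <- function(seq1, seq2, scheme, max_total_length = 14) {
  scheme <- as_scheme(scheme)
  g <- scheme$gap
  a <- strsplit(seq1, "")[[1]]
  b <- strsplit(seq2, "")[[1]]
  n <- length(a)
  m <- length(b)
  if (n + m > max_total_length)
    stop("input exceeds oracle size guard (", max_total_length, " residues)")
  if (n == 0 || m == 0) return(g * (n + m))
  alphabet <- unique(c(a, b))
  M <- score_matrix(scheme, alphabet)
  ai <- match(a, alphabet)
  bi <- match(b, alphabet)
  best <- g * (n + m)  # the all-gap alignment (k = 0)
  for (k in seq_len(min(n, m))) {
    I <- combn(n, k)
    J <- combn(m, k)
    gap_term <- g * (n + m - 2 * k)
    for (ci in seq_len(ncol(I))) {
      ri <- ai[I[, ci]]
      for (cj in seq_len(ncol(J))) {
        sc <- sum(M[cbind(ri, bi[J[, cj]])]) + gap_term
        if (sc > best) best <- sc
      }
    }
  }
  best
}

#' Normalize a raw alignment score to 0-100
#'
#' The denominator is the smaller of the two self-alignment scores, which
#' guarantees identical sequences score 100 (when their self-score is
#' positive) and bounds every score by the best achievable over the shorter
#' sequence. Raw scores are clamped to `[0, S_max]` first; if the
#' denominator is non-positive (possible under the class schemes when a
#' sequence is dominated by unclassified residues) the score is 0.
#'
#' @param raw raw score from [nw_raw_score()] on the same inputs.
#' @inheritParams nw_raw_score
#' @return Numeric score in `[0, 100]`.
#' @export
normalize_score <- function(raw, seq1, seq2, scheme) {
  scheme <- as_scheme(scheme)
  s_max <- min(nw_raw_score(seq1, seq1, scheme),
               nw_raw_score(seq2, seq2, scheme))
  if (s_max <= 0) return(0)
  100 * min(max(raw, 0), s_max) / s_max
}

#' Similarity between two protein records
#'
#' Composition of [build_scheme()], [nw_raw_score()] and
#' [normalize_score()]; symmetric in its arguments.
#'
#' @param rec_a,rec_b one-row record data.frames (see [get_record()]), or
#'   lists with elements `accession` and `sequence`.
#' @param metric scheme name or `scoring_scheme`.
#' @return A `similarity_result`: list with `accession_a`, `accession_b`,
#'   `metric`, `raw_score`, `normalized`.
#' @export
similarity <- function(rec_a, rec_b, metric = "nw_weights") {
  scheme <- as_scheme(metric)
  raw <- nw_raw_score(rec_a$sequence, rec_b$sequence, scheme)
  norm <- normalize_score(raw, rec_a$sequence, rec_b$sequence, scheme)
  structure(list(accession_a = rec_a$accession, accession_b = rec_b$accession,
                 metric = scheme$name, raw_score = raw, normalized = norm),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(x$accession_a, "vs", x$accession_b, "(", x$metric, "): raw",
      x$raw_score, ", normalized", round(x$normalized, 2), "\n")
  invisible(x)
}

#' All pairwise similarities between (or within) datasets
#'
#' Computes every cross pair between `ds_a` and `ds_b`, or every unordered
#' within-set pair (self-pairs excluded) when `ds_b` is `NULL`. Self-
#' alignment scores are cached, so each normalization denominator is
#' computed once per record.
#'
#' @param ds_a,ds_b `protein_dataset`s; leave `ds_b` `NULL` for within-set
#'   pairs.
#' @param metric scheme name or `scoring_scheme`.
#' @return A `pairwise_similarity` data.frame with columns `accession_a`,
#'   `accession_b`, `metric`, `raw`, `normalized`, carrying attributes
#'   `mean`, `sd` (of the normalized scores) and `dataset_pair`.
#' @export
pairwise_similarity <- function(ds_a, ds_b = NULL, metric = "nw_weights") {
  scheme <- as_scheme(metric)
  within <- is.null(ds_b)
  rec_a <- ds_a$records
  rec_b <- if (within) rec_a else ds_b$records
  pair_name <- if (within) ds_a$name else paste(ds_a$name, ds_b$name, sep = " vs ")
  self_a <- vapply(rec_a$sequence,
                   function(s) nw_raw_score(s, s, scheme), 0, USE.NAMES = FALSE)
  self_b <- if (within) self_a else
    vapply(rec_b$sequence, function(s) nw_raw_score(s, s, scheme), 0,
           USE.NAMES = FALSE)
  if (within) {
    idx <- which(upper.tri(matrix(0, nrow(rec_a), nrow(rec_a))), arr.ind = TRUE)
    ia <- idx[, 1]; ib <- idx[, 2]
  } else {
    grid <- expand.grid(a = seq_len(nrow(rec_a)), b = seq_len(nrow(rec_b)))
    ia <- grid$a; ib <- grid$b
  }
  raw <- numeric(length(ia))
  norm <- numeric(length(ia))
  for (p in seq_along(ia)) {
    r <- nw_raw_score(rec_a$sequence[ia[p]], rec_b$sequence[ib[p]], scheme)
    s_max <- min(self_a[ia[p]], self_b[ib[p]])
    raw[p] <- r
    norm[p] <- if (s_max <= 0) 0 else 100 * min(max(r, 0), s_max) / s_max
  }
  out <- data.frame(accession_a = rec_a$accession[ia],
                    accession_b = rec_b$accession[ib],
                    metric = scheme$name, raw = raw, normalized = norm,
                    stringsAsFactors = FALSE)
  structure(out, class = c("pairwise_similarity", "data.frame"),
            mean = mean(norm), sd = sd(norm), dataset_pair = pair_name)
}

#' @export
print.pairwise_similarity <- function(x, ...) {
  cat("pairwise_similarity: ", nrow(x), " pair(s), ", attr(x, "dataset_pair"),
      " [", x$metric[1], "]\n", sep = "")
  cat(sprintf("  normalized similarity: %.2f +/- %.2f\n",
              attr(x, "mean"), attr(x, "sd")))
  invisible(x)
}

#' Mean +/- SD summary rows for similarity tables
#'
#' @param ... one or more `pairwise_similarity` tables.
#' @return data.frame with columns `dataset_pair`, `metric`, `mean`, `sd`.
#' @export
summarize_similarity <- function(...) {
  tabs <- list(...)
  out <- do.call(rbind, lapply(tabs, function(t)
    data.frame(dataset_pair = attr(t, "dataset_pair"), metric = t$metric[1],
               mean = attr(t, "mean"), sd = attr(t, "sd"),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Write a similarity table as TSV
#'
#' TSV layout: `accession_a`, `accession_b`, `metric`, `raw`, `normalized`.
#'
#' @param sim a `pairwise_similarity` table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  df <- data.frame(accession_a = sim$accession_a, accession_b = sim$accession_b,
                   metric = sim$metric,
                   raw = format(sim$raw, digits = 15, trim = TRUE,
                                scientific = FALSE),
                   normalized = format(sim$normalized, digits = 15,
                                       trim = TRUE, scientific = FALSE),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
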