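#' Minimum support count for an occurrence threshold
#'
#' A substring counts as a pattern when it appears in at least a given
#' fraction of the dataset's sequences ("at least" implies rounding up).
#'
#' @param occurrence fraction in (0, 1], e.g. 0.05 or 0.10.
#' @param n dataset size (number of sequences), >= 1.
#' @return Integer minimum number of supporting sequences,
#'   `max(1, ceiling(occurrence * n))`.
#' @export
min_support_count <- function(occurrence, n) {
  if (!is.numeric(occurrence) || length(occurrence) != 1 ||
      is.na(occurrence) || occurrence <= 0 || occurrence > 1)
    stop("occurrence must be a single value in (0, 1]")
  if (n < 1) stop("n must be >= 1")
  # tiny epsilon guards against 0.1 * 30 = 3.0000000000000004
  max(1L, as.integer(ceiling(occurrence * n - 1e-9)))
}

#' Number of distinct sequences containing a substring
#'
#' Multiple occurrences within one sequence count once; position is
#' irrelevant.
#'
#' @param pattern_text non-empty amino-acid string (treated literally).
#' @param ds a `protein_dataset`.
#' @return Integer support count.
#' @export
count_support <- function(pattern_text, ds) {
  if (!nzchar(pattern_text)) stop("pattern must be non-empty")
  sum(grepl(pattern_text, ds$records$sequence, fixed = TRUE))
}

# Support counts for many candidate strings at once.
support_counts <- function(candidates, seqs) {
  vapply(candidates,
         function(p) sum(grepl(p, seqs, fixed = TRUE)),
         integer(1), USE.NAMES = FALSE)
}

# Assemble the pattern_set data.frame for a sorted vector of pattern texts.
build_pattern_set <- function(texts, ds, occurrence, minsup) {
  seqs <- ds$records$sequence
  acc <- ds$records$accession
  texts <- texts[order(-nchar(texts), texts)]
  supp_acc <- lapply(texts, function(p) acc[grepl(p, seqs, fixed = TRUE)])
  out <- data.frame(pattern = texts,
                    length = nchar(texts),
                    support_count = vapply(supp_acc, length, integer(1)),
                    support_fraction = vapply(supp_acc, length, integer(1)) /
                      length(seqs),
                    stringsAsFactors = FALSE)
  out$accessions <- supp_acc
  rownames(out) <- NULL
  structure(out, class = c("pattern_set", "data.frame"),
            occurrence = occurrence, min_support = minsup,
            dataset_name = ds$name, dataset_size = length(seqs))
}

#' @export
print.pattern_set <- function(x, ...) {
  cat("pattern_set: ", nrow(x), " maximal pattern(s) from '",
      attr(x, "dataset_name"), "' (n = ", attr(x, "dataset_size"),
      ", occurrence ", attr(x, "occurrence"),
      ", min support ", attr(x, "min_support"), ")\n", sep = "")
  if (nrow(x) > 0) {
    show <- utils::head(x, 8)
    print.data.frame(data.frame(pattern = show$pattern, length = show$length,
                                support = show$support_count,
                                fraction = round(show$support_fraction, 3)))
    if (nrow(x) > 8) cat("  ... and ", nrow(x) - 8, " more\n", sep = "")
  }
  invisible(x)
}

#' Mine maximal frequent substring patterns
#'
#' Finds every amino-acid substring occurring in at least
#' `min_support_count(occurrence, n)` distinct sequences, then keeps only
#' the maximal ones: frequent substrings that are not contained in any other
#' frequent substring. Mining is level-wise: all frequent single residues
#' are right-extended by every alphabet letter, level by level, which is
#' complete because every frequent (k+1)-mer has a frequent k-prefix.
#' Mining always starts at length 1; apply [filter_by_length()] for the
#' reporting-time minimum-length filter.
#'
#' @param ds a `protein_dataset` with at least one record (deduplicate
#'   first; duplicate sequences inflate support).
#' @param occurrence fraction in (0, 1] of sequences a pattern must appear
#'   in (e.g. 0.05, 0.10).
#' @param max_length optional cap on pattern length (default unlimited).
#' @return A `pattern_set`: data.frame with columns `pattern`, `length`,
#'   `support_count`, `support_fraction` and list-column `accessions`,
#'   sorted by decreasing length then alphabetically. Attributes record the
#'   occurrence threshold, min support and source dataset.
#' @export
mine_maximal_patterns <- function(ds, occurrence, max_length = Inf) {
  seqs <- ds$records$sequence
  if (length(seqs) == 0) stop("cannot mine an empty dataset")
  minsup <- min_support_count(occurrence, length(seqs))
  alphabet <- sort(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]))
  freq1 <- alphabet[support_counts(alphabet, seqs) >= minsup]
  levels <- list()
  current <- freq1
  k <- 1L
  while (length(current) > 0 && k <= max_length) {
    levels[[k]] <- current
    if (k + 1 > max_length) break
    cand <- as.vector(outer(current, alphabet, paste0))
    current <- cand[support_counts(cand, seqs) >= minsup]
    k <- k + 1L
  }
  # A frequent k-string is non-maximal iff it is the prefix or suffix of a
  # frequent (k+1)-string (substring support is anti-monotone, so any longer
  # frequent superstring yields such a window).
  maximal <- character(0)
  for (k in seq_along(levels)) {
    cur <- levels[[k]]
    if (k < length(levels)) {
      nxt <- levels[[k + 1]]
      covered <- c(substr(nxt, 1L, k), substr(nxt, 2L, k + 1L))
      cur <- setdiff(cur, covered)
    }
    maximal <- c(maximal, cur)
  }
  build_pattern_set(maximal, ds, occurrence, minsup)
}

#' Brute-force maximal pattern mining (independent oracle)
#'
#' Enumerates every substring of every sequence, counts per-sequence
#' support directly, filters by the occurrence threshold and removes
#' non-maximal patterns by pairwise substring containment. Exponentially
#' simpler logic than [mine_maximal_patterns()] at polynomially worse cost;
#' guarded to small inputs.
#'
#' @inheritParams mine_maximal_patterns
#' @param max_total_length guard on the summed sequence length.
#' @return A `pattern_set`, identical to [mine_maximal_patterns()] output.
#' @export
brute_force_maximal_patterns <- function(ds, occurrence,
                                         max_total_length = 2000) {
  seqs <- ds$records$sequence
  if (length(seqs) == 0) stop("cannot mine an empty dataset")
  if (sum(nchar(seqs)) > max_total_length)
    stop("input exceeds brute-force size guard (", max_total_length,
         " residues)")
  minsup <- min_support_count(occurrence, length(seqs))
  per_seq <- lapply(seqs, function(s) {
    n <- nchar(s)
    subs <- character(0)
    for (i in seq_len(n))
      subs <- c(subs, substring(s, i, i:n))
    unique(subs)
  })
  supp <- table(unlist(per_seq))
  frequent <- names(supp)[supp >= minsup]
  # Longest-first scan: a frequent string contained in ANY other frequent
  # string is also contained in some already-accepted maximal string, so
  # direct containment against the accepted set suffices.
  frequent <- frequent[order(-nchar(frequent), frequent)]
  maximal <- character(0)
  for (p in frequent) {
    if (!any(grepl(p, maximal, fixed = TRUE)))
      maximal <- c(maximal, p)
  }
  build_pattern_set(maximal, ds, occurrence, minsup)
}

#' Keep patterns of at least a minimum length
#'
#' The reporting-time length filter (default study value: 4 residues,
#' applied after mining rather than during it).
#'
#' @param patterns a `pattern_set`.
#' @param min_len minimum pattern length to keep.
#' @return The filtered `pattern_set`.
#' @export
filter_by_length <- function(patterns, min_len) {
  out <- patterns[patterns$length >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("occurrence", "min_support", "dataset_name", "dataset_size"))
    attr(out, a) <- attr(patterns, a)
  class(out) <- class(patterns)
  out
}

# Accept a pattern_set or a plain character vector of pattern texts.
pattern_texts <- function(patterns) {
  if (is.data.frame(patterns)) patterns$pattern else as.character(patterns)
}

#' Locate patterns in a protein dataset
#'
#' Literal (regex-escaped) substring search; overlapping occurrences are
#' all reported. Start positions are 0-based.
#'
#' @param patterns a `pattern_set` or character vector of pattern texts.
#' @param ds a `protein_dataset` to search in.
#' @return data.frame with columns `pattern`, `accession`, `dataset` and
#'   list-column `positions` (0-based start offsets); one row per
#'   (pattern, protein) pair with at least one occurrence.
#' @export
find_pattern_matches <- function(patterns, ds) {
  texts <- pattern_texts(patterns)
  seqs <- ds$records$sequence
  acc <- ds$records$accession
  rows <- vector("list", length(texts))
  for (i in seq_along(texts)) {
    p <- texts[[i]]
    # lookahead so overlapping occurrences ("AA" in "AAA") are all found
    rx <- paste0("(?=", escape_regex(p), ")")
    hits <- gregexpr(rx, seqs, perl = TRUE)
    found <- vapply(hits, function(h) h[1] != -1L, logical(1))
    if (!any(found)) next
    rows[[i]] <- data.frame(pattern = p, accession = acc[found],
                            dataset = ds$name, stringsAsFactors = FALSE)
    rows[[i]]$positions <- lapply(hits[found],
                                  function(h) as.integer(h) - 1L)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(pattern = character(0), accession = character(0),
                      dataset = character(0),
                      positions = I(list()), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Tabulate pattern presence across datasets
#'
#' @param patterns a `pattern_set` or character vector.
#' @param datasets a list of `protein_dataset`s.
#' @return data.frame with one row per dataset: `dataset`,
#'   `patterns_found` (patterns with >= 1 match), `proteins_matched`
#'   (distinct proteins matched by any pattern) and `pairs`
#'   (pattern-protein combinations).
#' @export
summarize_presence <- function(patterns, datasets) {
  if (inherits(datasets, "protein_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    m <- find_pattern_matches(patterns, ds)
    data.frame(dataset = ds$name,
               patterns_found = length(unique(m$pattern)),
               proteins_matched = length(unique(m$accession)),
               pairs = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a pattern table
#'
#' TSV layout: `pattern`, `length`, `support_count`, `support_fraction`,
#' `accessions` (comma-joined).
#'
#' @param patterns a `pattern_set`.
#' @param path file path.
#' @return `path` invisibly (write); a `pattern_set` (read).
#' @export
write_patterns_tsv <- function(patterns, path) {
  df <- data.frame(pattern = patterns$pattern, length = patterns$length,
                   support_count = patterns$support_count,
                   support_fraction = format(patterns$support_fraction,
                                             digits = 15, trim = TRUE,
                                             scientific = FALSE),
                   accessions = vapply(patterns$accessions, paste,
                                       "", collapse = ","),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_patterns_tsv
#' @export
read_patterns_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(pattern = "character",
                                   accessions = "character"))
  tab$accessions <- strsplit(tab$accessions, ",", fixed = TRUE)
  structure(tab, class = c("pattern_set", "data.frame"))
}

#' Write pattern matches as TSV
#'
#' TSV layout: `pattern`, `accession`, `dataset`, `positions`
#' (comma-joined, 0-based start offsets).
#'
#' @param matches output of [find_pattern_matches()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path) {
  df <- data.frame(pattern = matches$pattern, accession = matches$accession,
                   dataset = matches$dataset,
                   positions = vapply(matches$positions,
                                      function(p) paste(p, collapse = ","),
                                      ""),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
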