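#' Generate drug-repurposing triplets
#'
#' A triplet (target protein - drug - new protein) is emitted for every
#' drug-target link and disease protein that share at least one mined
#' pattern: the pattern must occur as an exact substring of both the
#' target's and the disease protein's sequence. The similarity of the pair
#' is computed under the requested metric. A disease protein associated
#' with several diseases yields one triplet per (drug, target) with all its
#' labels attached, not one per label. Rows are ordered by (drug, target
#' accession, new accession).
#'
#' @param treatment_ds `protein_dataset` of drug-target proteins.
#' @param links drug-target link table (`drug`, `action`,
#'   `target_accession`), e.g. from [read_drug_target_table()]; every
#'   target accession must be present in `treatment_ds`.
#' @param disease_ds `protein_dataset` of disease proteins (apply
#'   [exclude_targets()] first).
#' @param patterns a `pattern_set` mined from `treatment_ds` (or a
#'   character vector of pattern texts).
#' @param metric scheme name or `scoring_scheme` for the similarity column.
#' @param occurrence_level occurrence fraction the patterns were mined at;
#'   defaults to the `pattern_set`'s own attribute when available.
#' @return A `triplet_table` data.frame with columns `pattern_count`,
#'   `shared_patterns` (list-column), `target_accession`, `target_name`,
#'   `drug`, `drug_action`, `new_accession`, `new_name`, `labels`
#'   (list-column), `metric`, `similarity`, `occurrence_level`.
#' @export
generate_triplets <- function(treatment_ds, links, disease_ds, patterns,
                              metric = "nw_weights",
                              occurrence_level = NULL) {
  scheme <- as_scheme(metric)
  if (is.null(occurrence_level))
    occurrence_level <- attr(patterns, "occurrence")
  if (is.null(occurrence_level)) occurrence_level <- NA_real_
  texts <- pattern_texts(patterns)
  trt <- treatment_ds$records
  dis <- disease_ds$records
  missing <- setdiff(unique(links$target_accession), trt$accession)
  if (length(missing) > 0)
    stop("link target(s) absent from treatment dataset: ",
         paste(missing, collapse = ", "))
  # pattern -> containing proteins, on each side
  in_trt <- lapply(texts, function(p) grepl(p, trt$sequence, fixed = TRUE))
  in_dis <- lapply(texts, function(p) grepl(p, dis$sequence, fixed = TRUE))
  self_trt <- new.env(parent = emptyenv())
  self_dis <- new.env(parent = emptyenv())
  sim_for <- function(ti, di) {
    key_t <- trt$accession[ti]
    if (is.null(self_trt[[key_t]]))
      self_trt[[key_t]] <- nw_raw_score(trt$sequence[ti], trt$sequence[ti],
                                        scheme)
    key_d <- dis$accession[di]
    if (is.null(self_dis[[key_d]]))
      self_dis[[key_d]] <- nw_raw_score(dis$sequence[di], dis$sequence[di],
                                        scheme)
    raw <- nw_raw_score(trt$sequence[ti], dis$sequence[di], scheme)
    s_max <- min(self_trt[[key_t]], self_dis[[key_d]])
    if (s_max <= 0) 0 else 100 * min(max(raw, 0), s_max) / s_max
  }
  rows <- list()
  for (li in seq_len(nrow(links))) {
    ti <- match(links$target_accession[li], trt$accession)
    pat_in_target <- vapply(in_trt, `[`, logical(1), ti)
    if (!any(pat_in_target)) next
    # disease proteins sharing >= 1 of the target's patterns
    share <- Reduce(`|`, in_dis[pat_in_target])
    for (di in which(share)) {
      shared <- texts[pat_in_target &
                        vapply(in_dis, `[`, logical(1), di)]
      rows[[length(rows) + 1L]] <- list(
        pattern_count = length(shared),
        shared_patterns = list(sort(shared)),
        target_accession = trt$accession[ti],
        target_name = trt$name[ti],
        drug = links$drug[li],
        drug_action = links$action[li],
        new_accession = dis$accession[di],
        new_name = dis$name[di],
        labels = list(dis$labels[[di]]),
        metric = scheme$name,
        similarity = sim_for(ti, di),
        occurrence_level = occurrence_level)
    }
  }
  out <- empty_triplet_table()
  if (length(rows) > 0) {
    out <- do.call(rbind, lapply(rows, function(r) {
      df <- data.frame(pattern_count = r$pattern_count,
                       target_accession = r$target_accession,
                       target_name = r$target_name, drug = r$drug,
                       drug_action = r$drug_action,
                       new_accession = r$new_accession,
                       new_name = r$new_name, metric = r$metric,
                       similarity = r$similarity,
                       occurrence_level = r$occurrence_level,
                       stringsAsFactors = FALSE)
      df$shared_patterns <- r$shared_patterns
      df$labels <- r$labels
      df
    }))
    out <- out[order(out$drug, out$target_accession, out$new_accession), ]
    rownames(out) <- NULL
    out <- out[, triplet_columns()]
  }
  structure(out, class = c("triplet_table", "data.frame"))
}

triplet_columns <- function() {
  c("pattern_count", "shared_patterns", "target_accession", "target_name",
    "drug", "drug_action", "new_accession", "new_name", "labels", "metric",
    "similarity", "occurrence_level")
}

empty_triplet_table <- function() {
  out <- data.frame(pattern_count = integer(0),
                    target_accession = character(0),
                    target_name = character(0), drug = character(0),
                    drug_action = character(0), new_accession = character(0),
                    new_name = character(0), metric = character(0),
                    similarity = numeric(0), occurrence_level = numeric(0),
                    stringsAsFactors = FALSE)
  out$shared_patterns <- list()
  out$labels <- list()
  out[, triplet_columns()]
}

#' @export
print.triplet_table <- function(x, ...) {
  cat("triplet_table: ", nrow(x), " repurposing triplet(s)\n", sep = "")
  if (nrow(x) > 0) {
    show <- utils::head(x, 8)
    print.data.frame(data.frame(drug = show$drug,
                                target = show$target_accession,
                                new = show$new_accession,
                                patterns = show$pattern_count,
                                similarity = round(show$similarity, 2)))
    if (nrow(x) > 8) cat("  ... and ", nrow(x) - 8, " more\n", sep = "")
  }
  invisible(x)
}

#' Filter triplets by similarity band
#'
#' The high band keeps triplets with similarity strictly above
#' `high_threshold` (default 95); the low band keeps those strictly below
#' `low_threshold` (default 5); `"all"` keeps everything.
#'
#' @param triplets a `triplet_table`.
#' @param band `"high"`, `"low"` or `"all"`.
#' @param high_threshold,low_threshold band cutoffs on the 0-100 scale,
#'   `0 <= low_threshold < high_threshold <= 100`.
#' @return The filtered `triplet_table`.
#' @export
filter_by_similarity_band <- function(triplets, band = c("all", "high", "low"),
                                      high_threshold = 95,
                                      low_threshold = 5) {
  band <- match.arg(band)
  if (!(low_threshold >= 0 && low_threshold < high_threshold &&
        high_threshold <= 100))
    stop("need 0 <= low_threshold < high_threshold <= 100")
  keep <- switch(band,
                 all = rep(TRUE, nrow(triplets)),
                 high = triplets$similarity > high_threshold,
                 low = triplets$similarity < low_threshold)
  out <- triplets[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(triplets)
  out
}

#' Write / read a triplet table
#'
#' TSV layout: `pattern_count`, `shared_patterns` (comma-joined),
#' `target_accession`, `target_name`, `drug`, `drug_action`,
#' `new_accession`, `new_name`, `labels` (comma-joined), `metric`,
#' `similarity`, `occurrence_level`. Round-trips losslessly.
#'
#' @param triplets a `triplet_table`.
#' @param path file path.
#' @return `path` invisibly (write); a `triplet_table` (read).
#' @export
export_triplets <- function(triplets, path) {
  df <- data.frame(
    pattern_count = triplets$pattern_count,
    shared_patterns = vapply(triplets$shared_patterns, paste, "",
                             collapse = ","),
    target_accession = triplets$target_accession,
    target_name = triplets$target_name,
    drug = triplets$drug,
    drug_action = triplets$drug_action,
    new_accession = triplets$new_accession,
    new_name = triplets$new_name,
    labels = vapply(triplets$labels, paste, "", collapse = ","),
    metric = triplets$metric,
    similarity = format(triplets$similarity, digits = 15, trim = TRUE,
                        scientific = FALSE),
    occurrence_level = format(triplets$occurrence_level, digits = 15,
                              trim = TRUE, scientific = FALSE),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname export_triplets
#' @export
read_triplets <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(shared_patterns = "character",
                                   labels = "character",
                                   target_name = "character",
                                   new_name = "character"))
  split_or_empty <- function(v)
    lapply(v, function(s) if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1]]
           else character(0))
  tab$shared_patterns <- split_or_empty(tab$shared_patterns)
  tab$labels <- split_or_empty(tab$labels)
  tab <- tab[, triplet_columns()]
  structure(tab, class = c("triplet_table", "data.frame"))
}

#' Run the full pattern-to-triplet pipeline
#'
#' Convenience wrapper chaining deduplication, target exclusion, mining at
#' one occurrence threshold, the minimum-length filter, pattern search and
#' triplet generation across one or more labeled disease datasets.
#'
#' @param treatment_ds `protein_dataset` of drug-target proteins.
#' @param links drug-target link table.
#' @param disease_list named list of disease `protein_dataset`s.
#' @param occurrence occurrence threshold for mining.
#' @param min_length reporting-time minimum pattern length.
#' @param metric similarity scheme name.
#' @return List with elements `patterns` (length-filtered `pattern_set`),
#'   `matches` (per-disease pattern matches), `presence` (summary table)
#'   and `triplets` (combined `triplet_table` across disease sets).
#' @export
repurpose_pipeline <- function(treatment_ds, links, disease_list,
                               occurrence = 0.10, min_length = 4,
                               metric = "nw_weights") {
  treatment_ds <- deduplicate(treatment_ds)
  disease_list <- lapply(disease_list, function(ds)
    exclude_targets(deduplicate(ds), treatment_ds))
  patterns <- mine_maximal_patterns(treatment_ds, occurrence)
  patterns <- filter_by_length(patterns, min_length)
  matches <- lapply(disease_list, function(ds)
    find_pattern_matches(patterns, ds))
  presence <- summarize_presence(patterns, disease_list)
  triplets <- lapply(disease_list, function(ds)
    generate_triplets(treatment_ds, links, ds, patterns, metric = metric))
  combined <- do.call(rbind, triplets)
  if (is.null(combined)) combined <- empty_triplet_table()
  rownames(combined) <- NULL
  combined <- structure(combined, class = c("triplet_table", "data.frame"))
  list(patterns = patterns, matches = matches, presence = presence,
       triplets = combined)
}
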