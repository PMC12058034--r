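#' Construct a protein dataset
#'
#' A `protein_dataset` is a named, ordered collection of protein records,
#' each with a unique accession, an optional protein/gene name, an
#' upper-case amino-acid sequence and a set of dataset/disease labels.
#'
#' @param accession character vector of unique, non-empty accessions.
#' @param sequence character vector of non-empty amino-acid sequences
#'   (upper-cased on input). The 20 standard residues are expected;
#'   nonstandard letters (B, J, O, U, X, Z) are tolerated but flagged with a
#'   warning. Any other character is an error.
#' @param name optional character vector of protein names ("" if unknown).
#' @param labels either a character vector applied to every record or a list
#'   of character vectors, one per record.
#' @param dataset_name single string naming the dataset.
#' @param warn_nonstandard warn when tolerated nonstandard residues are
#'   present (internal re-constructions disable this to avoid repeats).
#'
#' @return An object of class `protein_dataset`: a list with elements
#'   `name` (string) and `records` (data.frame with columns `accession`,
#'   `name`, `sequence` and list-column `labels`).
#' @export
protein_dataset <- function(accession, sequence, name = NULL, labels = NULL,
                            dataset_name = "dataset",
                            warn_nonstandard = TRUE) {
  accession <- as.character(accession)
  sequence <- toupper(as.character(sequence))
  n <- length(accession)
  if (length(sequence) != n)
    stop("accession and sequence must have equal length")
  if (n > 0) {
    if (any(!nzchar(accession)))
      stop("empty accession at record ", which(!nzchar(accession))[1])
    if (anyDuplicated(accession))
      stop("duplicate accession(s): ",
           paste(unique(accession[duplicated(accession)]), collapse = ", "))
    if (any(!nzchar(sequence)))
      stop("empty sequence for accession ",
           accession[which(!nzchar(sequence))[1]])
    letters_used <- unique(strsplit(paste(sequence, collapse = ""), "")[[1]])
    bad <- setdiff(letters_used, c(AA_STANDARD, AA_NONSTANDARD))
    if (length(bad) > 0)
      stop("invalid sequence character(s): ", paste(bad, collapse = ", "))
    nonstd <- intersect(letters_used, AA_NONSTANDARD)
    if (length(nonstd) > 0 && warn_nonstandard) {
      carriers <- accession[grepl(paste0("[", paste(nonstd, collapse = ""), "]"),
                                  sequence)]
      warning("nonstandard residue(s) ", paste(nonstd, collapse = ", "),
              " in: ", paste(carriers, collapse = ", "))
    }
  }
  if (is.null(name)) name <- rep("", n)
  name <- as.character(name)
  if (length(name) == 1L && n != 1L) name <- rep(name, n)
  if (is.null(labels)) {
    labels <- rep(list(character(0)), n)
  } else if (is.character(labels)) {
    labels <- rep(list(labels), n)
  } else if (length(labels) != n) {
    stop("labels must be a character vector or a list of length ", n)
  }
  labels <- lapply(labels, function(l) sort(unique(as.character(l))))
  records <- data.frame(accession = accession, name = name,
                        sequence = sequence, stringsAsFactors = FALSE)
  records$labels <- labels
  structure(list(name = dataset_name, records = records),
            class = "protein_dataset")
}

#' @export
length.protein_dataset <- function(x) nrow(x$records)

#' @export
print.protein_dataset <- function(x, ...) {
  cat("protein_dataset '", x$name, "': ", nrow(x$records), " record(s)\n",
      sep = "")
  if (nrow(x$records) > 0) {
    lens <- nchar(x$records$sequence)
    cat("  sequence length ", min(lens), "-", max(lens), "\n", sep = "")
    show <- utils::head(x$records$accession, 6)
    cat("  accessions: ", paste(show, collapse = ", "),
        if (nrow(x$records) > 6) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.protein_dataset <- function(x, ...) x$records

#' Look up one record by accession
#'
#' @param ds a `protein_dataset`.
#' @param accession the accession to retrieve.
#' @return A one-row data.frame (accession, name, sequence, labels).
#' @export
get_record <- function(ds, accession) {
  i <- match(accession, ds$records$accession)
  if (is.na(i)) stop("accession not in dataset: ", accession)
  ds$records[i, , drop = FALSE]
}

# UniProt-style accession shape, e.g. P10826, O75469, Q9NQ94, A0A024R161.
is_accession_shaped <- function(x) {
  grepl("^[OPQ][0-9][A-Z0-9]{3}[0-9]$", x) |
    grepl("^[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2}$", x)
}

# Extract (accession, name) from a FASTA header line (without ">").
# `sp|P10826|RARB_HUMAN desc` -> accession from the first |-field that looks
# like an accession; plain headers use the first whitespace token.
parse_fasta_header <- function(header) {
  header <- trimws(header)
  token <- sub("\\s.*$", "", header)
  rest <- trimws(sub("^\\S+", "", header))
  if (grepl("|", token, fixed = TRUE)) {
    fields <- strsplit(token, "|", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    hit <- which(is_accession_shaped(fields))
    if (length(hit) > 0) {
      acc <- fields[hit[1]]
      if (!nzchar(rest) && length(fields) > hit[1]) rest <- fields[hit[1] + 1]
    } else if (length(fields) >= 2) {
      acc <- fields[2]
    } else {
      acc <- fields[1]
    }
  } else {
    acc <- token
  }
  list(accession = acc, name = rest)
}

#' Read a protein dataset from a FASTA file
#'
#' Headers are parsed for a UniProt-style accession: in `|`-delimited headers
#' (e.g. `>sp|P10826|RARB_HUMAN`) the first accession-shaped field is used;
#' plain headers use the first whitespace-delimited token. Multi-line
#' sequences are concatenated and upper-cased.
#'
#' @param path path to a FASTA file.
#' @param dataset_name dataset name; defaults to the file name without
#'   extension.
#' @param labels labels applied to every record (character vector).
#' @return A [protein_dataset()].
#' @export
read_fasta <- function(path, dataset_name = NULL, labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(dataset_name))
    dataset_name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)))
  if (length(meaningful) == 0) {
    warning("empty FASTA file: ", path)
    return(protein_dataset(character(0), character(0),
                           dataset_name = dataset_name))
  }
  first <- meaningful[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA: line ", first, " is not a header ('>' expected)")
  hdr_lines <- which(startsWith(trimws(lines), ">"))
  empty_hdr <- hdr_lines[!nzchar(trimws(sub("^>", "", trimws(lines[hdr_lines]))))]
  if (length(empty_hdr) > 0)
    stop("malformed FASTA: empty header at line ", empty_hdr[1])
  aa <- Biostrings::readAAStringSet(path)
  parsed <- lapply(names(aa), parse_fasta_header)
  acc <- vapply(parsed, `[[`, "", "accession")
  nms <- vapply(parsed, `[[`, "", "name")
  if (anyDuplicated(acc))
    stop("duplicate accession in ", path, ": ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  protein_dataset(acc, as.character(aa), name = nms, labels = labels,
                  dataset_name = dataset_name)
}

#' Write a protein dataset to a FASTA file
#'
#' Headers are `>accession name` (name omitted when empty); sequences are
#' wrapped at 60 columns, UTF-8, LF line endings. Round-trips through
#' [read_fasta()] reproduce accessions and sequences exactly.
#'
#' @param ds a `protein_dataset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  aa <- Biostrings::AAStringSet(ds$records$sequence)
  hdr <- ifelse(nzchar(ds$records$name),
                paste(ds$records$accession, ds$records$name),
                ds$records$accession)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Read an accession-synonym map
#'
#' Two-column TSV `secondary<TAB>primary` (header optional, detected). The
#' map must be acyclic; chains are resolved to their final primary
#' accession.
#'
#' @param path path to the TSV file.
#' @return Named character vector: `names()` are secondary accessions,
#'   values the resolved primary accessions.
#' @export
read_accession_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (nrow(tab) > 0 &&
      tolower(tab[1, 1]) %in% c("secondary", "secondary_accession"))
    tab <- tab[-1, , drop = FALSE]
  if (ncol(tab) < 2) stop("accession map needs two columns")
  map <- stats::setNames(trimws(tab[[2]]), trimws(tab[[1]]))
  map <- map[nzchar(names(map))]
  resolve_accession_map(map)
}

# Resolve secondary->primary chains; error on cycles.
resolve_accession_map <- function(map) {
  if (length(map) == 0) return(map)
  out <- map
  for (i in seq_along(out)) {
    seen <- names(out)[i]
    cur <- out[[i]]
    while (cur %in% names(map) && map[[cur]] != cur) {
      if (cur %in% seen) stop("cyclic accession map at ", cur)
      seen <- c(seen, cur)
      cur <- map[[cur]]
    }
    out[[i]] <- cur
  }
  out
}

#' Deduplicate a protein dataset
#'
#' Rewrites secondary accessions to their primary form, then collapses
#' records that share a primary accession or an identical sequence. Among
#' duplicates the first record in input order is kept; labels of dropped
#' records are merged into the keeper. Idempotent.
#'
#' @param ds a `protein_dataset`.
#' @param acc_map optional named character vector (secondary -> primary),
#'   e.g. from [read_accession_map()].
#' @return The deduplicated `protein_dataset`, with attribute `"dropped"`:
#'   a data.frame (`accession`, `kept_as`, `reason`) describing removals.
#' @export
deduplicate <- function(ds, acc_map = NULL) {
  rec <- ds$records
  if (!is.null(acc_map) && length(acc_map) > 0) {
    acc_map <- resolve_accession_map(acc_map)
    hit <- rec$accession %in% names(acc_map)
    rec$accession[hit] <- unname(acc_map[rec$accession[hit]])
  }
  n <- nrow(rec)
  keep <- rep(TRUE, n)
  kept_as <- character(n)
  reason <- character(n)
  if (n > 1) {
    first_acc <- match(rec$accession, rec$accession)
    first_seq <- match(rec$sequence, rec$sequence)
    for (i in seq_len(n)) {
      if (first_acc[i] < i) {
        keep[i] <- FALSE
        kept_as[i] <- rec$accession[first_acc[i]]
        reason[i] <- "duplicate accession"
      } else if (first_seq[i] < i && keep[first_seq[i]]) {
        keep[i] <- FALSE
        kept_as[i] <- rec$accession[first_seq[i]]
        reason[i] <- "identical sequence"
      } else if (first_seq[i] < i) {
        # earlier identical sequence was itself dropped; follow its keeper
        keep[i] <- FALSE
        kept_as[i] <- kept_as[first_seq[i]]
        reason[i] <- "identical sequence"
      }
    }
    # merge labels of dropped records into their keepers
    for (i in which(!keep)) {
      j <- match(kept_as[i], rec$accession)
      rec$labels[[j]] <- sort(unique(c(rec$labels[[j]], rec$labels[[i]])))
    }
  }
  dropped <- data.frame(accession = ds$records$accession[!keep],
                        kept_as = kept_as[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  out <- protein_dataset(rec$accession[keep], rec$sequence[keep],
                         name = rec$name[keep], labels = rec$labels[keep],
                         dataset_name = ds$name, warn_nonstandard = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Remove treatment targets from a disease dataset
#'
#' Drops every disease record whose accession, or whose exact sequence,
#' occurs in the treatment dataset, so disease sets cannot trivially
#' "rediscover" the drug targets themselves.
#'
#' @param disease_ds,treatment_ds deduplicated `protein_dataset`s.
#' @return Filtered copy of `disease_ds` with attributes `"removed"` (count)
#'   and `"removed_accessions"`.
#' @export
exclude_targets <- function(disease_ds, treatment_ds) {
  rec <- disease_ds$records
  trt <- treatment_ds$records
  drop <- rec$accession %in% trt$accession | rec$sequence %in% trt$sequence
  out <- protein_dataset(rec$accession[!drop], rec$sequence[!drop],
                         name = rec$name[!drop], labels = rec$labels[!drop],
                         dataset_name = disease_ds$name,
                         warn_nonstandard = FALSE)
  attr(out, "removed") <- sum(drop)
  attr(out, "removed_accessions") <- rec$accession[drop]
  out
}

#' Read a drug-target link table
#'
#' TSV with header columns `drug`, `action`, `target_accession`. Duplicate
#' rows are collapsed; empty actions are stored as `"Unknown"`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `drug`, `action`, `target_accession`.
#' @export
read_drug_target_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("drug", "action", "target_accession")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("drug-target table missing column(s): ", paste(miss, collapse = ", "))
  tab <- tab[, need, drop = FALSE]
  for (cn in need) tab[[cn]] <- trimws(tab[[cn]])
  tab$action[is.na(tab$action) | !nzchar(tab$action)] <- "Unknown"
  tab <- unique(tab)
  rownames(tab) <- NULL
  tab
}

#' Write a drug-target link table
#'
#' @param links data.frame with columns `drug`, `action`, `target_accession`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drug_target_table <- function(links, path) {
  write_tsv(links[, c("drug", "action", "target_accession")], path)
}

# Minimal TSV writer: UTF-8, LF, no quoting (fields never contain tabs).
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df) > 0)
               do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
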