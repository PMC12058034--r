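#' Specification for a synthetic protein dataset
#'
#' @param n_proteins number of sequences to generate.
#' @param length_range integer pair `(min, max)`; sequence lengths are
#'   drawn uniformly from this range.
#' @param residue_frequencies named numeric vector of per-residue
#'   probabilities over the 20 standard amino acids (default uniform);
#'   must sum to 1 within 1e-9.
#' @param planted list of planted motifs, each a list/vector with elements
#'   `motif` (string over the standard alphabet) and `prevalence` (fraction
#'   in (0, 1]).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_proteins, length_range = c(80, 160),
                           residue_frequencies = NULL, planted = list(),
                           seed = 1) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2 || length_range[1] < 1 ||
      length_range[1] > length_range[2])
    stop("length_range must be (min, max) with 1 <= min <= max")
  if (is.null(residue_frequencies))
    residue_frequencies <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  if (is.null(names(residue_frequencies)) ||
      !setequal(names(residue_frequencies), AA_STANDARD))
    stop("residue_frequencies must be named by the 20 standard residues")
  if (any(residue_frequencies < 0) ||
      abs(sum(residue_frequencies) - 1) > 1e-9)
    stop("residue frequencies must be non-negative and sum to 1")
  planted <- lapply(planted, function(p) {
    p <- as.list(p)
    motif <- toupper(as.character(p$motif))
    prevalence <- as.numeric(p$prevalence)
    if (!nzchar(motif) ||
        !all(strsplit(motif, "")[[1]] %in% AA_STANDARD))
      stop("planted motifs must be non-empty strings over the standard alphabet")
    if (is.na(prevalence) || prevalence <= 0 || prevalence > 1)
      stop("motif prevalence must be in (0, 1]")
    list(motif = motif, prevalence = prevalence)
  })
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = length_range,
                 residue_frequencies = residue_frequencies[AA_STANDARD],
                 planted = planted, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate an i.i.d. background protein dataset
#'
#' Sequences have lengths uniform in the spec's range and residues drawn
#' i.i.d. from the spec's frequency table. Accessions are `SYN000001`, ...
#' (configurable prefix). Deterministic given the spec's seed; motifs in
#' `spec$planted` are then inserted by [plant_motifs()] using `seed + 1`.
#'
#' @param spec a [synthetic_spec()].
#' @param accession_prefix prefix for generated accessions.
#' @param dataset_name dataset name.
#' @param labels labels applied to every record.
#' @return A `protein_dataset`; if motifs were planted, attribute
#'   `"carriers"` names the carrier accessions per motif.
#' @export
generate_background <- function(spec, accession_prefix = "SYN",
                                dataset_name = "synthetic", labels = NULL) {
  n <- spec$n_proteins
  ds <- with_seed(spec$seed, {
    span <- spec$length_range[2] - spec$length_range[1] + 1L
    lens <- spec$length_range[1] + sample.int(span, n, replace = TRUE) - 1L
    seqs <- vapply(lens, function(L)
      paste(sample(AA_STANDARD, L, replace = TRUE,
                   prob = spec$residue_frequencies), collapse = ""),
      "")
    protein_dataset(sprintf("%s%06d", accession_prefix, seq_len(n)), seqs,
                    labels = labels, dataset_name = dataset_name)
  })
  if (length(spec$planted) > 0)
    ds <- plant_motifs(ds, spec$planted, seed = spec$seed + 1L)
  ds
}

#' Plant motifs into a protein dataset
#'
#' For each motif, exactly `round_half_up(prevalence * n)` distinct records
#' are chosen (seeded) and the motif overwrites the sequence at a random
#' valid offset, keeping lengths unchanged. With `distinct_flanks = TRUE`
#' the residues immediately flanking each planted occurrence are set to
#' letters distinct across carriers, so no extension of the motif is shared
#' by two carriers and the motif itself is the maximal frequent pattern at
#' thresholds up to its prevalence.
#'
#' @param ds a `protein_dataset`.
#' @param planted list of `list(motif =, prevalence =)` entries.
#' @param seed integer seed.
#' @param distinct_flanks force carrier-distinct flanking residues
#'   (requires no more than 20 carriers per motif).
#' @return The dataset with planted motifs; attribute `"carriers"` is a
#'   named list of carrier accessions per motif.
#' @export
plant_motifs <- function(ds, planted, seed = 1, distinct_flanks = FALSE) {
  rec <- ds$records
  n <- nrow(rec)
  carriers <- list()
  rec$sequence <- with_seed(seed, {
    seqs <- rec$sequence
    for (p in planted) {
      motif <- p$motif
      m <- nchar(motif)
      if (m >= min(nchar(seqs)))
        stop("motif '", motif, "' is not shorter than the shortest sequence")
      k <- round_half_up(p$prevalence * n)
      if (k < 1)
        stop("prevalence ", p$prevalence, " rounds to zero carriers")
      chosen <- sort(sample.int(n, k))
      if (distinct_flanks && k > length(AA_STANDARD))
        stop("distinct_flanks supports at most 20 carriers per motif")
      left_fl <- if (distinct_flanks) sample(AA_STANDARD, k) else NULL
      right_fl <- if (distinct_flanks) sample(AA_STANDARD, k) else NULL
      for (j in seq_along(chosen)) {
        i <- chosen[j]
        L <- nchar(seqs[i])
        off <- sample.int(L - m + 1L, 1L)
        substr(seqs[i], off, off + m - 1L) <- motif
        if (distinct_flanks) {
          if (off > 1L)
            substr(seqs[i], off - 1L, off - 1L) <- left_fl[j]
          if (off + m <= L)
            substr(seqs[i], off + m, off + m) <- right_fl[j]
        }
      }
      carriers[[motif]] <- rec$accession[chosen]
    }
    seqs
  })
  out <- protein_dataset(rec$accession, rec$sequence, name = rec$name,
                         labels = rec$labels, dataset_name = ds$name,
                         warn_nonstandard = FALSE)
  attr(out, "carriers") <- carriers
  out
}

# Motifs shared between the synthetic treatment and disease sets. The
# texts are arbitrary standard-alphabet strings in the 4-10 residue range
# typical of reported patterns.
STUDY_MOTIFS <- list(
  list(motif = "CEGCKGFF", prevalence = 0.20),
  list(motif = "AALET",    prevalence = 0.20),
  list(motif = "WQDKR",    prevalence = 0.12)
)

#' Build a complete seeded study fixture
#'
#' Emulates the shapes of a pattern-based repurposing study at desk scale:
#' a small treatment set of drug-target proteins (default 25), a drug-target
#' link table with 1-3 drugs per target, and two labeled disease sets (a
#' same-disease set and a multi-cancer set whose records can carry several
#' cancer labels). Motifs from a fixed panel are planted in the treatment
#' set (with carrier-distinct flanks, so each motif is itself a maximal
#' frequent pattern at thresholds up to its prevalence) and at 10%
#' prevalence in each disease set. Two disease records duplicate treatment
#' sequences so that target exclusion has work to do. Fully deterministic
#' given `seed`.
#'
#' @param seed integer seed.
#' @param n_treatment treatment-set size.
#' @param n_disease named integer vector: sizes of the two disease sets.
#' @return List with elements `treatment` (`protein_dataset`), `links`
#'   (drug-target table) and `disease` (named list of `protein_dataset`s).
#' @export
make_study_fixture <- function(seed = 1, n_treatment = 25,
                               n_disease = c(disease_lung = 40,
                                             cancers = 50)) {
  trt_spec <- synthetic_spec(n_treatment, length_range = c(60, 120),
                             seed = seed)
  treatment <- generate_background(trt_spec, accession_prefix = "TRT",
                                   dataset_name = "treatment_lung",
                                   labels = "treatment_lung")
  treatment <- plant_motifs(treatment, STUDY_MOTIFS, seed = seed + 1L,
                            distinct_flanks = TRUE)
  links <- with_seed(seed + 2L, {
    drug_pool <- sprintf("DRG%03d", 1:15)
    actions <- c("Inhibitor", "Inducer", "Agonist", "Antagonist", "Unknown")
    rows <- lapply(seq_len(n_treatment), function(i) {
      k <- sample(1:3, 1)
      data.frame(drug = sample(drug_pool, k),
                 action = sample(actions, k, replace = TRUE),
                 target_accession = treatment$records$accession[i],
                 stringsAsFactors = FALSE)
    })
    unique(do.call(rbind, rows))
  })
  disease_planted <- lapply(STUDY_MOTIFS, function(p)
    list(motif = p$motif, prevalence = 0.10))
  disease <- list()
  for (d in seq_along(n_disease)) {
    dname <- names(n_disease)[d]
    spec <- synthetic_spec(n_disease[[d]], length_range = c(60, 120),
                           seed = seed + 10L * d)
    prefix <- toupper(substr(dname, 1, 3))
    ds <- generate_background(spec, accession_prefix = prefix,
                              dataset_name = dname, labels = dname)
    ds <- plant_motifs(ds, disease_planted, seed = seed + 10L * d + 1L)
    if (dname == "cancers") {
      # multi-cancer membership: each record gets one cancer label, some two
      ds <- with_seed(seed + 99L, {
        cancer_labels <- c("breast", "colon", "pancreas", "head_neck")
        labs <- lapply(seq_len(length(ds)), function(i) {
          k <- if (runif(1) < 0.2) 2L else 1L
          sort(sample(cancer_labels, k))
        })
        protein_dataset(ds$records$accession, ds$records$sequence,
                        name = ds$records$name, labels = labs,
                        dataset_name = ds$name, warn_nonstandard = FALSE)
      })
    }
    disease[[dname]] <- ds
  }
  # two disease_lung records duplicate treatment sequences, so the
  # target-exclusion filter is exercised end to end
  dl <- disease[[1]]$records
  dl$sequence[1:2] <- treatment$records$sequence[1:2]
  # plus one near-identical paralog of a motif-carrying target (three point
  # substitutions outside the motif), so the >95% similarity band is
  # populated the way real repurposing hits are
  carrier_acc <- attr(treatment, "carriers")[[1]][1]
  carrier_seq <- get_record(treatment, carrier_acc)$sequence
  mimic <- with_seed(seed + 5L, {
    s <- carrier_seq
    motif <- STUDY_MOTIFS[[1]]$motif
    m_at <- as.integer(regexpr(motif, s, fixed = TRUE))
    protected <- seq(m_at, m_at + nchar(motif) - 1L)
    sites <- sample(setdiff(seq_len(nchar(s)), protected), 3)
    for (i in sites) {
      old <- substr(s, i, i)
      substr(s, i, i) <- sample(setdiff(AA_STANDARD, old), 1)
    }
    s
  })
  dl <- rbind(dl, data.frame(accession = sprintf("DIS%06d", nrow(dl) + 1L),
                             name = "", sequence = mimic,
                             labels = I(list("disease_lung")),
                             stringsAsFactors = FALSE))
  disease[[1]] <- protein_dataset(dl$accession, dl$sequence, name = dl$name,
                                  labels = dl$labels,
                                  dataset_name = disease[[1]]$name,
                                  warn_nonstandard = FALSE)
  list(treatment = treatment, links = links, disease = disease)
}
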