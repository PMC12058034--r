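# Small constructed fixture: one motif shared between a target and one
# disease protein.
toy_triplet_inputs <- function() {
  treatment <- protein_dataset(
    c("T1", "T2"),
    c("MKLVWWWWWACDG", "MKLVACDGMKLV"),
    name = c("TGT1", "TGT2"), dataset_name = "treatment")
  disease <- protein_dataset(
    c("D1", "D2"),
    c("CCWWWWWGG", "MMMMMMMM"),
    name = c("NEW1", "NEW2"), labels = list("lung", "lung"),
    dataset_name = "disease")
  links <- data.frame(drug = "DrugA", action = "Inhibitor",
                      target_accession = "T1", stringsAsFactors = FALSE)
  list(treatment = treatment, disease = disease, links = links)
}

test_that("triplets join targets and disease proteins through shared patterns", {
  fx <- toy_triplet_inputs()
  tr <- generate_triplets(fx$treatment, fx$links, fx$disease,
                          patterns = "WWWWW", metric = "nw_weights",
                          occurrence_level = 0.10)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$target_accession, "T1")
  expect_equal(tr$drug, "DrugA")
  expect_equal(tr$new_accession, "D1")
  expect_equal(tr$shared_patterns[[1]], "WWWWW")
  expect_equal(tr$labels[[1]], "lung")
  expect_equal(tr$occurrence_level, 0.10)
  # D2 shares nothing and contributes no triplet
  expect_false("D2" %in% tr$new_accession)
  # a link to a target absent from the treatment set is an error
  bad <- data.frame(drug = "X", action = "Unknown",
                    target_accession = "NOPE")
  expect_error(generate_triplets(fx$treatment, bad, fx$disease, "WWWWW"),
               "NOPE")
})

test_that("triplet schema carries the drug-target table fields through", {
  # Table-style schema: (target, drug, action, new protein, disease label)
  treatment <- protein_dataset("O75469", "MKCEGCKGFFRRS", name = "NR1I2")
  disease <- protein_dataset("P10826", "GGCEGCKGFFAAA", name = "RARB",
                             labels = "Lung")
  links <- data.frame(drug = "Paclitaxel", action = "Inducer",
                      target_accession = "O75469")
  tr <- generate_triplets(treatment, links, disease, "CEGCKGFF")
  expect_equal(tr$target_name, "NR1I2")
  expect_equal(tr$drug_action, "Inducer")
  expect_equal(tr$new_name, "RARB")
  expect_equal(tr$labels[[1]], "Lung")
})

test_that("every emitted shared pattern verifies by substring check", {
  fx <- make_study_fixture(seed = 31)
  res <- repurpose_pipeline(fx$treatment, fx$links, fx$disease,
                            occurrence = 0.10, min_length = 4)
  tr <- res$triplets
  expect_gt(nrow(tr), 0)
  trt <- deduplicate(fx$treatment)
  dis_all <- do.call(rbind, lapply(fx$disease, function(d) d$records))
  for (i in seq_len(nrow(tr))) {
    tseq <- trt$records$sequence[match(tr$target_accession[i],
                                       trt$records$accession)]
    nseq <- dis_all$sequence[match(tr$new_accession[i], dis_all$accession)]
    for (p in tr$shared_patterns[[i]]) {
      expect_true(grepl(p, tseq, fixed = TRUE))
      expect_true(grepl(p, nseq, fixed = TRUE))
    }
    expect_equal(tr$pattern_count[i], length(tr$shared_patterns[[i]]))
  }
})

test_that("triplet count grows monotonically with the pattern set", {
  fx <- make_study_fixture(seed = 13)
  trt <- deduplicate(fx$treatment)
  dis <- exclude_targets(deduplicate(fx$disease$disease_lung), trt)
  pats <- filter_by_length(mine_maximal_patterns(trt, 0.10), 4)
  all_p <- pats$pattern
  n_prev <- 0
  for (k in seq_along(all_p)) {
    n_now <- nrow(generate_triplets(trt, fx$links, dis, all_p[1:k]))
    expect_gte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("similarity bands use strict thresholds and partition the table", {
  tr <- structure(
    data.frame(pattern_count = 1L, target_accession = "T",
               target_name = "", drug = "D", drug_action = "Unknown",
               new_accession = c("A", "B", "C", "E", "F"),
               new_name = "", metric = "nw_weights",
               similarity = c(96, 95, 50, 5, 0.8),
               occurrence_level = 0.1, stringsAsFactors = FALSE),
    class = c("triplet_table", "data.frame"))
  tr$shared_patterns <- rep(list("WWWW"), 5)
  tr$labels <- rep(list("lung"), 5)
  tr <- tr[, patrep:::triplet_columns()]
  hi <- filter_by_similarity_band(tr, "high")
  lo <- filter_by_similarity_band(tr, "low")
  expect_equal(hi$new_accession, "A")    # 96 kept, 95 is not > 95
  expect_equal(lo$new_accession, "F")    # 0.8 kept, 5 is not < 5
  expect_equal(nrow(filter_by_similarity_band(tr, "all")), 5L)
  # partition: high + low + middle == all
  mid <- tr$similarity >= 5 & tr$similarity <= 95
  expect_equal(nrow(hi) + nrow(lo) + sum(mid), nrow(tr))
  expect_error(filter_by_similarity_band(tr, "high", high_threshold = 4,
                                         low_threshold = 5), "threshold")
})

test_that("triplet tables round-trip through TSV, including empty tables", {
  fx <- toy_triplet_inputs()
  tr <- generate_triplets(fx$treatment, fx$links, fx$disease, "WWWWW",
                          occurrence_level = 0.05)
  path <- tempfile(fileext = ".tsv")
  export_triplets(tr, path)
  back <- read_triplets(path)
  expect_equal(as.data.frame(back), as.data.frame(tr))

  empty <- filter_by_similarity_band(tr, "high", high_threshold = 99.9)
  path2 <- tempfile(fileext = ".tsv")
  export_triplets(empty, path2)
  expect_equal(nrow(read_triplets(path2)), 0L)
  expect_equal(length(readLines(path2)), 1L)  # header only
})
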