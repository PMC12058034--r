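test_that("pair scores follow each scheme's rules", {
  # identity weights
  expect_equal(pair_score("A", "A", "nw_weights"), 3)
  expect_equal(pair_score("A", "C", "nw_weights"), 0)
  # full classification: shared group / no shared group / unclassified
  expect_equal(pair_score("I", "L", "class_amino_acids"), 3)
  expect_equal(pair_score("E", "K", "class_amino_acids"), 0)
  expect_equal(pair_score("Q", "A", "class_amino_acids"), -1)
  expect_equal(pair_score("Q", "Q", "class_amino_acids"), -1)
  # reduced classification is stricter
  expect_equal(pair_score("A", "G", "class_amino_acids_reduced"), 3)
  expect_equal(pair_score("C", "C", "class_amino_acids_reduced"), -1)
  # BLOSUM62 entries, with identity fallback outside the 24-letter matrix
  expect_equal(pair_score("W", "W", "blosum"), 11)
  expect_equal(pair_score("A", "A", "blosum"), 4)
  expect_equal(pair_score("B", "N", "blosum"), 4)  # Biostrings ambiguity row
  expect_equal(pair_score("U", "U", "blosum"), 3)
  expect_equal(pair_score("U", "A", "blosum"), 0)
  expect_error(build_scheme("unknown_scheme"))
})

test_that("pair scores are symmetric under every scheme", {
  letters24 <- c(AA20, "B", "X", "Z", "U")
  for (nm in c("nw_weights", "class_amino_acids",
               "class_amino_acids_reduced", "blosum")) {
    M <- patrep:::score_matrix(build_scheme(nm), letters24)
    expect_equal(M, t(M), info = nm)
  }
})

test_that("global alignment scores match hand-checked cases", {
  expect_equal(nw_raw_score("ACD", "ACD", "nw_weights"), 9)
  expect_equal(nw_raw_score("ACD", "AD", "nw_weights"), 5)
  expect_equal(nw_raw_score("", "AC", "nw_weights"), -2)
  expect_equal(nw_raw_score("", "", "nw_weights"), 0)
  expect_equal(oracle_alignment_score("ACD", "AD", "nw_weights"), 5)
  expect_equal(oracle_alignment_score("A", "A", "blosum"), 4)
  expect_equal(oracle_alignment_score("", "", "nw_weights"), 0)
  expect_error(oracle_alignment_score(strrep("A", 10), strrep("C", 10),
                                      "nw_weights"), "guard")
})

test_that("DP alignment equals exhaustive enumeration on random short pairs", {
  set.seed(41)
  schemes <- lapply(c("nw_weights", "class_amino_acids",
                      "class_amino_acids_reduced", "blosum"), build_scheme)
  for (rep in 1:60) {
    s1 <- paste(sample(AA20, sample(0:6, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(AA20, sample(0:6, 1), replace = TRUE), collapse = "")
    for (sc in schemes) {
      expect_equal(nw_raw_score(s1, s2, sc),
                   oracle_alignment_score(s1, s2, sc),
                   info = paste(sc$name, s1, s2))
    }
  }
})

test_that("alignment score is symmetric and responds boundedly to extension", {
  set.seed(17)
  sc <- build_scheme("blosum")
  for (rep in 1:25) {
    s1 <- paste(sample(AA20, 12, replace = TRUE), collapse = "")
    s2 <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    expect_equal(nw_raw_score(s1, s2, sc), nw_raw_score(s2, s1, sc))
    # appending one residue moves the score by [gap, max pair score]
    ext <- paste0(s1, sample(AA20, 1))
    delta <- nw_raw_score(ext, s2, sc) - nw_raw_score(s1, s2, sc)
    expect_gte(delta, sc$gap)
    expect_lte(delta, 11)  # max BLOSUM62 entry (W,W)
  }
})

test_that("normalization lands in [0,100] with the documented denominator", {
  expect_equal(normalize_score(5, "ACD", "AD", "nw_weights"), 100 * 5 / 6)
  # identical classified sequences score 100 under every scheme
  for (nm in c("nw_weights", "class_amino_acids",
               "class_amino_acids_reduced", "blosum")) {
    r <- similarity(list(accession = "a", sequence = "MKLVAG"),
                    list(accession = "a", sequence = "MKLVAG"), nm)
    expect_equal(r$normalized, 100, info = nm)
  }
  # negative raw clamps to 0; non-positive self-score gives 0
  expect_equal(normalize_score(-3, "ACD", "AD", "nw_weights"), 0)
  r <- similarity(list(accession = "x", sequence = "QQQQ"),
                  list(accession = "y", sequence = "QQQQ"),
                  "class_amino_acids")
  expect_equal(r$normalized, 0)
})

test_that("similarity is symmetric and bounded on random record pairs", {
  set.seed(29)
  for (rep in 1:10) {
    a <- list(accession = "A", sequence = paste(
      sample(AA20, 30, replace = TRUE), collapse = ""))
    b <- list(accession = "B", sequence = paste(
      sample(AA20, 45, replace = TRUE), collapse = ""))
    nm <- sample(c("nw_weights", "class_amino_acids",
                   "class_amino_acids_reduced", "blosum"), 1)
    r1 <- similarity(a, b, nm)
    r2 <- similarity(b, a, nm)
    expect_equal(r1$raw_score, r2$raw_score)
    expect_equal(r1$normalized, r2$normalized)
    expect_gte(r1$normalized, 0)
    expect_lte(r1$normalized, 100)
  }
})

test_that("pairwise similarity enumerates the right pairs with a summary", {
  set.seed(55)
  ds3 <- protein_dataset(c("A1", "A2", "A3"), random_sequences(3, 20, 30))
  within <- pairwise_similarity(ds3, metric = "nw_weights")
  expect_equal(nrow(within), 3L)  # C(3,2)
  expect_false(any(within$accession_a == within$accession_b))

  ds2 <- protein_dataset(c("B1", "B2"), random_sequences(2, 20, 30))
  cross <- pairwise_similarity(ds3, ds2, metric = "nw_weights")
  expect_equal(nrow(cross), 6L)  # 3 x 2

  # the mean +/- SD summary matches its own table
  expect_equal(attr(within, "mean"), mean(within$normalized))
  expect_equal(attr(within, "sd"), sd(within$normalized))
  stab <- summarize_similarity(within, cross)
  expect_equal(stab$mean, c(attr(within, "mean"), attr(cross, "mean")))
})

test_that("pairwise similarity agrees with the single-pair route", {
  set.seed(71)
  ds <- protein_dataset(c("C1", "C2", "C3"), random_sequences(3, 25, 40))
  tab <- pairwise_similarity(ds, metric = "blosum")
  for (i in seq_len(nrow(tab))) {
    r <- similarity(get_record(ds, tab$accession_a[i]),
                    get_record(ds, tab$accession_b[i]), "blosum")
    expect_equal(tab$raw[i], r$raw_score)
    expect_equal(tab$normalized[i], r$normalized)
  }
})
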