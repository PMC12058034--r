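test_that("minimum support count rounds up and guards its domain", {
  expect_equal(min_support_count(0.05, 52), 3L)
  expect_equal(min_support_count(0.10, 52), 6L)
  expect_equal(min_support_count(1.0, 10), 10L)
  expect_equal(min_support_count(0.1, 30), 3L)  # floating-point 3.0000000004
  expect_equal(min_support_count(0.01, 5), 1L)  # floor of 1
  expect_error(min_support_count(0, 10), "occurrence")
  expect_error(min_support_count(1.5, 10), "occurrence")
})

test_that("support counts distinct sequences, not occurrences", {
  ds <- protein_dataset(c("a", "b", "c"), c("MAEAK", "GAEA", "CCCC"))
  expect_equal(count_support("AEA", ds), 2L)
  expect_equal(count_support("AA", protein_dataset("a", "AAAA")), 1L)
  expect_equal(count_support("W", protein_dataset("a", "ACD")), 0L)
  expect_error(count_support("", ds), "non-empty")
})

test_that("miner returns exactly the maximal frequent substrings", {
  ds <- protein_dataset(c("a", "b", "c"), c("ACDG", "ACDG", "WWWW"))
  expect_equal(mine_maximal_patterns(ds, 0.6)$pattern, "ACDG")

  ds2 <- protein_dataset(c("a", "b", "c"), c("MKLV", "MKLV", "MKLV"))
  expect_equal(mine_maximal_patterns(ds2, 1.0)$pattern, "MKLV")

  # "CF" is shared; "A" survives as the only other maximal frequent string
  ds3 <- protein_dataset(c("a", "b"), c("ACF", "CFA"))
  expect_setequal(mine_maximal_patterns(ds3, 1.0)$pattern, c("CF", "A"))
  expect_setequal(brute_force_maximal_patterns(ds3, 1.0)$pattern,
                  c("CF", "A"))

  expect_error(mine_maximal_patterns(
    protein_dataset(character(0), character(0)), 0.5), "empty")
})

test_that("miner agrees with the brute-force oracle on random datasets", {
  for (seed in 1:40) {
    ds <- random_dataset(seed, n_min = 4, n_max = 12,
                         len_min = 10, len_max = 40)
    occ <- sample(c(0.1, 0.25, 0.5, 0.75, 1.0), 1)
    expect_same_patterns(mine_maximal_patterns(ds, occ),
                         brute_force_maximal_patterns(ds, occ))
  }
})

test_that("mined patterns satisfy support, maximality and anti-monotonicity", {
  ds <- random_dataset(99, n_min = 10, n_max = 10, len_min = 30, len_max = 60)
  occ <- 0.3
  ps <- mine_maximal_patterns(ds, occ)
  minsup <- min_support_count(occ, length(ds))
  expect_true(all(ps$support_count >= minsup))
  expect_equal(ps$support_count,
               vapply(ps$pattern, count_support, integer(1), ds = ds,
                      USE.NAMES = FALSE))
  expect_equal(ps$support_fraction, ps$support_count / length(ds))
  # no pattern is a substring of another returned pattern
  for (i in seq_len(nrow(ps))) {
    others <- ps$pattern[-i]
    expect_false(any(grepl(ps$pattern[i], others, fixed = TRUE)))
  }
  # one-residue extensions drop below threshold
  for (p in ps$pattern) {
    for (a in AA20) {
      expect_lt(count_support(paste0(p, a), ds), minsup)
      expect_lt(count_support(paste0(a, p), ds), minsup)
    }
  }
  # anti-monotonicity: every substring of a frequent pattern is frequent
  for (p in ps$pattern[ps$length > 1]) {
    subs <- unique(c(substring(p, 1, 1:(nchar(p) - 1)),
                     substring(p, 2:nchar(p), nchar(p))))
    expect_true(all(vapply(subs, count_support, integer(1), ds = ds)
                    >= minsup))
  }
})

test_that("mining result is independent of record order", {
  ds <- random_dataset(5, n_min = 8, n_max = 8, len_min = 20, len_max = 40)
  set.seed(1)
  perm <- sample(length(ds))
  shuffled <- protein_dataset(ds$records$accession[perm],
                              ds$records$sequence[perm],
                              dataset_name = ds$name)
  expect_same_patterns(mine_maximal_patterns(ds, 0.25),
                       mine_maximal_patterns(shuffled, 0.25))
})

test_that("the length filter keeps only patterns of the minimum reported length", {
  ds <- protein_dataset(c("a", "b"), c("AEAMCEGCKGFF", "AEAWCEGCKGFF"))
  ps <- mine_maximal_patterns(ds, 1.0)
  filtered <- filter_by_length(ps, 4)
  expect_true(all(filtered$length >= 4))
  expect_true("CEGCKGFF" %in% filtered$pattern)
  expect_false("AEA" %in% filtered$pattern)
  # min_len 1 is the identity; empty set stays empty
  expect_equal(nrow(filter_by_length(ps, 1)), nrow(ps))
  expect_equal(nrow(filter_by_length(ps[0, ], 4)), 0L)
})

test_that("pattern search reports literal, overlapping, 0-based matches", {
  ds <- protein_dataset(c("x", "y"), c("MMCEGCKGFFKK", "AAA"))
  m <- find_pattern_matches(c("CEGCKGFF", "AA", "QQQ"), ds)
  expect_equal(m$positions[[which(m$pattern == "CEGCKGFF")]], 2L)
  expect_equal(m$positions[[which(m$pattern == "AA" & m$accession == "y")]],
               c(0L, 1L))
  expect_false("QQQ" %in% m$pattern)
  # every reported position is an exact substring occurrence
  for (i in seq_len(nrow(m))) {
    s <- get_record(ds, m$accession[i])$sequence
    for (pos in m$positions[[i]])
      expect_equal(substr(s, pos + 1, pos + nchar(m$pattern[i])),
                   m$pattern[i])
  }
})

test_that("presence summaries count patterns, proteins and pairs per dataset", {
  set.seed(3)
  ds <- protein_dataset(sprintf("S%02d", 1:50),
                        random_sequences(50, 60, 100),
                        dataset_name = "synthetic")
  planted <- plant_motifs(ds, list(list(motif = "WCEGKW", prevalence = 0.1)),
                          seed = 4)
  tab <- summarize_presence("WCEGKW", list(planted))
  expect_equal(tab$patterns_found, 1L)
  expect_equal(tab$proteins_matched, 5L)
  expect_equal(tab$pairs, 5L)

  none <- summarize_presence(character(0), list(planted))
  expect_equal(none$pairs, 0L)
})

test_that("pattern tables round-trip through TSV", {
  ds <- random_dataset(12, n_min = 6, n_max = 6, len_min = 20, len_max = 40)
  ps <- mine_maximal_patterns(ds, 0.3)
  path <- tempfile(fileext = ".tsv")
  write_patterns_tsv(ps, path)
  back <- read_patterns_tsv(path)
  expect_equal(back$pattern, ps$pattern)
  expect_equal(back$support_count, ps$support_count)
  expect_equal(back$accessions, ps$accessions)
})
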