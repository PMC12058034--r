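---
title: "Pattern-based drug repurposing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-based drug repurposing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrep)
```

## The problem

Drugs bind target proteins, and proteins that look alike at the sequence
level may bind the same drugs. `patrep` operationalizes one version of this
idea for drug repurposing: starting from the set of target proteins of the
approved treatments for one disease (the *treatment set*), it

1. mines the amino-acid substrings ("patterns") that recur across a minimum
   fraction of the treatment proteins,
2. searches those patterns in protein sets associated with other diseases,
3. scores the global-alignment similarity of each (target, disease protein)
   pair on a normalized 0-100 scale under four different residue-pairing
   rules, and
4. emits candidate repurposing triplets (target protein, drug, new protein)
   for pairs that share at least one pattern, stratified into high- and
   low-similarity bands.

The package also contains the statistical layer used to compare similarity
distributions between datasets, and a seeded synthetic-data generator so
that every stage is testable without any external database.

## Pattern mining

A *pattern* is a contiguous substring over the 20-letter amino-acid
alphabet that occurs, anywhere in the sequence, in at least a threshold
fraction of the dataset's proteins. Support is counted per protein:
multiple occurrences inside one sequence count once. The two study
thresholds are 5% and 10% occurrence; with `n` proteins the minimum support
is `max(1, ceiling(occurrence * n))` — "at least a minimum number" implies
rounding up, since rounding down would admit patterns below the stated
percentage. (The product `occurrence * n` is computed with a `1e-9` slack
before the ceiling: in floating point `0.1 * 30` is fractionally above 3
and would otherwise round up to 4.)

Mining is level-wise. All frequent single residues are found first, then
every frequent k-mer is extended on the right by every alphabet letter and
the frequent (k+1)-mers are kept, and so on until no candidate survives.
This is complete because support is anti-monotone: every frequent
(k+1)-mer has a frequent k-prefix. Extending only the *longest* patterns of
the previous level — a literal reading of a narrower description of this
family of algorithms — would be incomplete, which is why all frequent
k-mers are extended.

Patterns contained within other frequent patterns carry no extra
information and are excluded; the reported set is the *maximal* frequent
substrings. The filter exploits a one-step property: a frequent k-string is
non-maximal exactly when it is the prefix or suffix of a frequent
(k+1)-string, because any longer frequent superstring contains a frequent
window one residue wider than the pattern. An independent brute-force
implementation (`brute_force_maximal_patterns()`) enumerates every
substring of every sequence, tabulates support directly and removes
contained patterns by literal containment checks against the accepted
maximal set; the test suite requires exact agreement between the two routes
on hundreds of random datasets.

Two reporting conventions follow the study design: mining always starts at
length 1 and the minimum-length filter (default 4 residues, intended to
curb chance matches) is applied at reporting time via `filter_by_length()`;
and pattern search in other datasets (`find_pattern_matches()`) treats
patterns as literal strings — the implementation escapes them before
handing them to the regex engine, and reports all overlapping occurrences
at 0-based offsets.

## Similarity scoring

Protein pairs are scored with a global (Needleman-Wunsch) alignment under
a linear, per-position gap penalty, with leading and trailing gaps charged
(the first row and column of the dynamic-programming matrix accumulate gap
penalties). Only the optimal score is needed, never an alignment string, so
no traceback is computed and tie-breaking cannot affect results. Four
pair-scoring schemes share the same default weights — match 3, mismatch 0,
gap -1:

* **`nw_weights`** — identity: 3 if the residues are equal, else 0.
* **`class_amino_acids`** — residues are grouped into hydrophobic
  (I, L, V, C, A, G, M, F, Y, W, H, K, T), small (V, C, A, G, D, N, S, T,
  P), aromatic (F, Y, W, H), positive (H, K, R) and negative (E, D). Two
  residues sharing at least one group score a match; two classified
  residues sharing no group score a mismatch; a pair with at least one
  *unclassified* residue scores the gap penalty. The rule is applied
  literally: glutamine (Q) belongs to no group above, so even Q-Q scores
  -1. A consequence surfaced in the tests is that a sequence dominated by
  unclassified residues can have a non-positive self-alignment score.
* **`class_amino_acids_reduced`** — a stricter grouping: tiny (A, G, S),
  aliphatic (I, L, V), aromatic (F, Y, W), positive (H, K, R), negative
  (E, D), with the same match/mismatch/gap rule.
* **`blosum`** — BLOSUM62 entries for all residue pairs covered by the
  24-letter matrix shipped with Biostrings (the 20 standard residues plus
  B, Z, X; the 20x20 core is the canonical matrix). Letters outside it
  (J, O, U) fall back to the identity match/mismatch defaults.

Raw scores depend on sequence length, so they are normalized to 0-100.
The denominator is the smaller of the two self-alignment scores,
`S_max = min(score(a,a), score(b,b))`: this guarantees that identical
sequences score 100 whenever their self-score is positive, and bounds every
score by the best achievable over the shorter (or weaker) sequence. Raw
scores are clamped to `[0, S_max]` before scaling; if `S_max <= 0`
(possible only under the class schemes, see above) the normalized score is
defined as 0. The normalization denominator is a design choice of this
package — only the 0-100 range is externally fixed — so normalized values
from other implementations of the same idea need not be numerically
comparable.

Correctness of the dynamic program is checked against an independent
oracle that enumerates every order-preserving matching of residue
positions between the two sequences (each global alignment is exactly such
a matching, with all unmatched residues charged as gaps) and takes the
maximum score.

## Statistical comparison

Similarity distributions are compared in two steps. Each group is first
screened with the Lilliefors normality test — a Kolmogorov-Smirnov-type
test with mean and SD estimated from the sample. Because the estimated
parameters invalidate the standard KS null distribution, the p-value is
obtained by Monte Carlo: the D statistic is recomputed on `n_mc` (default
1000) Gaussian samples of the same size under a fixed seed, and the p-value
is the fraction of null statistics exceeding the observed one. This is
reproducible, exact at any sample size up to Monte-Carlo noise, and
testable (the suite verifies the D statistic against `nortest`'s
implementation and the test's type-I error by simulation).

If either group rejects normality at `alpha` (default 0.05), the groups are
compared with the Mann-Whitney U test; if both pass, the package falls back
to Welch's t-test and records that choice in the result — there is no
silent switch. The U statistic is computed from midranks; the p-value is
exact (full enumeration of rank assignments) for tie-free samples of
combined size at most 12, and otherwise uses the normal approximation with
tie correction and continuity correction (numerically identical to
`stats::wilcox.test`). Comparison p-values are annotated with the usual
star bands: `ns` above 0.05, `*` to 0.01, `**` to 0.001, `***` to 1e-4,
and `****` below. Two-sided alternatives are the default; no
multiple-testing correction is applied across metrics, which is a
documented limitation.

One numerical caveat surfaced during development: at the smallest sizes the
continuity-corrected normal approximation differs from the exact
enumeration by up to ~0.03 near the center of the null distribution (where
p is ~0.3-0.7 and nothing is decided); in the decision-relevant tail the
two agree to better than 0.004.

## Triplet generation

Repurposing triplets join a drug-target link to a disease protein through
at least one shared mined pattern, verified by exact substring containment
in both sequences. Disease datasets are first deduplicated and stripped of
the treatment targets themselves (`exclude_targets()` removes records
matching a target by accession or by exact sequence), so a triplet can
never trivially rediscover a known target. A disease protein carrying
several disease labels yields one triplet with all labels attached rather
than one row per label, avoiding the duplicate rows that multi-disease
membership would otherwise create. Bands use strict inequalities —
similarity strictly above 95 ("exceeding 95%") or strictly below 5 ("less
than 5%") — and both thresholds are configurable, since reported uses of
the low band range down to 1%.

## The synthetic-data generator

`generate_background()` draws i.i.d. sequences with uniform residue
frequencies by default and lengths uniform in a configurable range;
`plant_motifs()` overwrites a motif into an exactly-rounded number of
carrier records (`round_half_up(prevalence * n)`; overwriting rather than
inserting keeps lengths fixed, which keeps length-distribution assertions
exact). The generator emulates the *shapes* of a real study — a small
treatment set, larger labeled disease sets, motif prevalences in the
5-30% range, motif lengths 4-10 — at desk scale.

`make_study_fixture()` assembles the full study: 25 treatment proteins of
length 60-120 with three planted motifs (8, 5 and 5 residues at
prevalences 0.20, 0.20 and 0.12), a link table giving every target 1-3
drugs, a same-disease set of 40 proteins and a multi-cancer set of 50
proteins (each carrying one or two cancer labels), with the same motifs
planted at 10% prevalence. Two disease records duplicate treatment
sequences so target exclusion is exercised, and one disease record is a
near-identical mutated copy of a motif-carrying target so the >95%
similarity band is populated the way real repurposing hits are. The sizes
are a deliberate reduction of a realistic study (tens of targets, hundreds
of disease proteins) chosen so the full pipeline runs in seconds while
every stage still has non-trivial work.

In the treatment set, motifs are planted with *carrier-distinct flanking
residues* (`distinct_flanks = TRUE`): the residue on each side of the
planted occurrence differs across carriers. Without this, two or more
carriers can share a random flanking letter, making the motif-plus-flank
string itself frequent; maximality would then absorb the planted motif
into a longer pattern that is absent from the disease sets, and the triplet
table could be empty for unlucky seeds. With distinct flanks the planted
motif itself is the maximal frequent pattern at any threshold up to its
prevalence, making fixture behavior deterministic in structure, not just
in values. `plant_motifs()` defaults to plain overwriting; the flank
decollision is opt-in.

What passing tests on this generator do *not* show: real proteomes are not
i.i.d. — they contain low-complexity regions, repeats and homologous
families, so real pattern counts are far larger and real similarity
distributions are heavier-tailed than the synthetic ones. The generator
validates the machinery (correctness, determinism, calibration), not the
biological yield of any particular dataset.

## Numerical and degenerate-input conventions

* Occurrence thresholds are fractions in (0, 1], never percentages, in all
  interfaces.
* Empty sequences are legal in alignment (`nw_raw_score("", s)` is the
  cumulative gap penalty); empty datasets error in mining.
* Duplicate handling is keep-first in input order, deterministic; labels
  of dropped records are merged into the keeper. Accession synonyms are
  resolved before sequence comparison (the keeper is the same either way;
  only the dropped-id report could differ).
* Tolerated nonstandard residues (B, J, O, U, X, Z) are accepted in I/O
  with a warning; they participate in mining alphabets only if present.
* Constant samples and n < 4 are errors in the normality test; empty
  samples are errors in the U test.
* Pattern coordinates are 0-based start offsets; all TSV outputs are
  UTF-8 with LF line endings.

## Known limitations

* Exact substring patterns only: no gapped or degenerate motifs, no
  position weight matrices, no statistical significance of motif
  discovery.
* Global alignment only, linear gap penalty, no affine gaps, no local
  (Smith-Waterman) mode.
* The normalization denominator is package-specific (see above).
* No multiple-testing correction across similarity metrics.
* Pattern mining scales with the frequent-substring count; it is designed
  for datasets of tens to hundreds of proteins, not whole proteomes.

## A minimal run

```{r pipeline}
fx <- make_study_fixture(seed = 1)
treatment <- deduplicate(fx$treatment)
res <- repurpose_pipeline(fx$treatment, fx$links, fx$disease,
                          occurrence = 0.10, min_length = 4,
                          metric = "nw_weights")
res$patterns
res$presence
res$triplets
filter_by_similarity_band(res$triplets, "high")
```
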