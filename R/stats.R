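# Lilliefors D statistic: sup distance between the empirical CDF and the
# Gaussian CDF with mean/SD estimated from the sample itself.
lilliefors_D <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

#' Lilliefors normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov-type normality test with mean and SD estimated from
#' the sample. The p-value is the fraction of `n_mc` Gaussian samples of
#' the same size whose D statistic exceeds the observed one, under a fixed
#' seed (reproducible, exact at any sample size up to Monte-Carlo noise).
#'
#' @param sample numeric vector, length >= 4, non-constant.
#' @param n_mc number of Monte-Carlo null samples.
#' @param seed integer seed for the null simulation.
#' @return A `patrep_test` list: `statistic` (D), `p_value`, `method`, `n`.
#' @export
lilliefors_test <- function(sample, n_mc = 1000, seed = 1) {
  sample <- as.numeric(sample)
  if (length(sample) < 4) stop("Lilliefors test needs n >= 4")
  if (sd(sample) == 0) stop("zero variance: constant sample")
  n <- length(sample)
  D <- lilliefors_D(sample)
  D_null <- with_seed(seed, {
    sims <- matrix(rnorm(n * n_mc), nrow = n)
    # column-wise sort via a single order() pass, then vectorized D
    sims <- matrix(sims[order(col(sims), sims)], nrow = n)
    mu <- colMeans(sims)
    s <- sqrt((colSums(sims^2) - n * mu^2) / (n - 1))
    P <- pnorm((sims - rep(mu, each = n)) / rep(s, each = n))
    Dm <- pmax((1:n) / n - P, P - (0:(n - 1)) / n)
    apply(Dm, 2, max)
  })
  structure(list(statistic = D, p_value = mean(D_null > D),
                 method = "Lilliefors (Monte Carlo)", n = n),
            class = "patrep_test")
}

#' @export
print.patrep_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4),
      ", n = ", paste(x$n, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U is computed from midranks. With no ties and a combined sample size of
#' at most `exact_limit`, the p-value is exact, by enumeration of all
#' assignments of ranks to the first group; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x`
#'   relative to `y`).
#' @param method `"auto"` (default), `"exact"` (error if ties) or
#'   `"normal"`.
#' @param exact_limit maximum `length(x) + length(y)` for the exact path.
#' @return A `patrep_test` list: `statistic` (U of `x`), `p_value`,
#'   `method`, `n` (both sizes), `alternative`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           method = c("auto", "exact", "normal"),
                           exact_limit = 12) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(all_v) > 0
  if (method == "exact" && has_ties)
    stop("exact Mann-Whitney p-value is unavailable with ties")
  use_exact <- method == "exact" ||
    (method == "auto" && !has_ties && n1 + n2 <= exact_limit)
  if (use_exact) {
    # enumerate every assignment of n1 of the N distinct ranks to x
    combos <- combn(n1 + n2, n1)
    U_null <- colSums(combos) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
                less = mean(U_null <= U),
                greater = mean(U_null >= U),
                two.sided = min(1, 2 * min(mean(U_null <= U),
                                           mean(U_null >= U))))
    meth <- "Mann-Whitney U (exact)"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(all_v)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) stop("zero variance: all values tied")
    sigma <- sqrt(sigma2)
    p <- switch(alternative,
                greater = pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE),
                less = pnorm((U - mu + 0.5) / sigma),
                two.sided = {
                  z <- (U - mu - sign(U - mu) * 0.5) / sigma
                  min(1, 2 * pnorm(-abs(z)))
                })
    meth <- "Mann-Whitney U (normal approximation)"
  }
  structure(list(statistic = U, p_value = p, method = meth,
                 n = c(n1, n2), alternative = alternative),
            class = "patrep_test")
}

# Fig-style significance stars: ns above 0.05, then one star per decade,
# capped at four stars below 1e-4.
p_stars <- function(p) {
  if (p > 0.05) "ns"
  else if (p > 0.01) "*"
  else if (p > 0.001) "**"
  else if (p > 1e-4) "***"
  else "****"
}

#' Compare two similarity-score distributions
#'
#' Screens both groups with the Lilliefors normality test; if either group
#' rejects normality at `alpha`, the groups are compared with the
#' Mann-Whitney U test, otherwise with Welch's t-test (recorded in the
#' result, never silent). The comparison p-value is annotated with stars:
#' `ns` (p > 0.05), `*` (0.01 < p <= 0.05), `**` (0.001 < p <= 0.01),
#' `***` (1e-4 < p <= 0.001), `****` (p <= 1e-4).
#'
#' @param scores_a,scores_b numeric samples (>= 4 values each).
#' @param alpha significance level for the normality screen (and the star
#'   bands' outermost cut).
#' @param seed seed for the Monte-Carlo normality p-values.
#' @param n_mc Monte-Carlo replicates per normality test.
#' @param alternative passed to [mann_whitney_u()] / [stats::t.test()].
#' @param group_names optional pair of labels for the two groups.
#' @return A `distribution_comparison` list: `group_names`, `normality`
#'   (two `patrep_test`s), `comparison` (`patrep_test`), `alpha`, `stars`.
#' @export
compare_groups <- function(scores_a, scores_b, alpha = 0.05, seed = 1,
                           n_mc = 1000,
                           alternative = c("two.sided", "less", "greater"),
                           group_names = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(group_names))
    group_names <- c(deparse(substitute(scores_a)),
                     deparse(substitute(scores_b)))
  norm_a <- lilliefors_test(scores_a, n_mc = n_mc, seed = seed)
  norm_b <- lilliefors_test(scores_b, n_mc = n_mc, seed = seed + 1L)
  nonnormal <- norm_a$p_value <= alpha || norm_b$p_value <= alpha
  if (nonnormal) {
    comparison <- mann_whitney_u(scores_a, scores_b,
                                 alternative = alternative)
  } else {
    tt <- t.test(scores_a, scores_b, alternative = alternative,
                 var.equal = FALSE)
    comparison <- structure(list(statistic = unname(tt$statistic),
                                 p_value = tt$p.value,
                                 method = "Welch t-test (both groups normal)",
                                 n = c(length(scores_a), length(scores_b)),
                                 alternative = alternative),
                            class = "patrep_test")
  }
  structure(list(group_names = group_names,
                 normality = list(norm_a, norm_b),
                 comparison = comparison, alpha = alpha,
                 stars = p_stars(comparison$p_value)),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat("distribution_comparison (alpha = ", x$alpha, ")\n", sep = "")
  cat("  normality A: p = ", format(x$normality[[1]]$p_value, digits = 4),
      "; normality B: p = ", format(x$normality[[2]]$p_value, digits = 4),
      "\n", sep = "")
  cat("  ", x$comparison$method, ": statistic = ",
      format(x$comparison$statistic, digits = 6), ", p = ",
      format(x$comparison$p_value, digits = 4), "  [", x$stars, "]\n",
      sep = "")
  invisible(x)
}

#' Write comparison results as a TSV report
#'
#' TSV layout: `group_a`, `group_b`, `metric`, `method`, `statistic`, `p`,
#' `stars`.
#'
#' @param comparisons a list of `distribution_comparison` objects.
#' @param metric metric label(s) for the report rows.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparisons, metric, path) {
  if (inherits(comparisons, "distribution_comparison"))
    comparisons <- list(comparisons)
  metric <- rep_len(metric, length(comparisons))
  df <- do.call(rbind, lapply(seq_along(comparisons), function(i) {
    cmp <- comparisons[[i]]
    data.frame(group_a = cmp$group_names[1], group_b = cmp$group_names[2],
               metric = metric[i], method = cmp$comparison$method,
               statistic = format(cmp$comparison$statistic, digits = 15,
                                  trim = TRUE, scientific = FALSE),
               p = format(cmp$comparison$p_value, digits = 15, trim = TRUE),
               stars = cmp$stars, stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
}
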