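#' Storer-Kim exact unconditional test for two binomial proportions
#'
#' Tests `H0: p1 = p2` from `x1` successes in `n1` trials and `x2` in `n2`.
#' The pooled estimate is `phat = (x1 + x2) / (n1 + n2)`; the score
#' statistic for an outcome pair `(y1, y2)` is
#' `z = (y1/n1 - y2/n2) / sqrt(p(1-p)(1/n1 + 1/n2))` at that pair's own
#' pooled `p` (zero when the pooled estimate is 0 or 1). The p-value sums
#' `Bin(y1; n1, phat) * Bin(y2; n2, phat)` over every outcome pair at least
#' as extreme as the observed one: `|z| >= |z_obs|` two-sided, or
#' `z >= z_obs` for the one-sided alternative `p1 > p2`. Unlike Fisher's
#' conditional test, the sum runs over the full outcome grid rather than a
#' fixed table margin.
#'
#' @param x1,n1,x2,n2 Successes and trials in the two samples
#'   (`0 <= x <= n`, `n >= 1`).
#' @param alternative `"two_sided"` (default) or `"greater"` (`p1 > p2`).
#' @return The p-value, in `(0, 1]`.
#' @examples
#' storer_kim_test(9, 10, 2, 10)          # strong difference
#' storer_kim_test(4, 7, 4, 7)            # identical proportions: p = 1
#' @export
storer_kim_test <- function(x1, n1, x2, n2,
                            alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  if (n1 < 1 || n2 < 1) abort("n1 and n2 must be >= 1")
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) abort("require 0 <= x <= n in both samples")
  if (any(c(x1, n1, x2, n2) != floor(c(x1, n1, x2, n2)))) abort("counts must be integers")

  zstat <- function(y1, y2) {
    p <- (y1 + y2) / (n1 + n2)
    denom <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
    z <- (y1 / n1 - y2 / n2) / denom
    z[!is.finite(z)] <- 0  # pooled estimate 0 or 1
    z
  }
  z_obs <- zstat(x1, x2)
  phat <- (x1 + x2) / (n1 + n2)

  y1 <- 0:n1
  y2 <- 0:n2
  z <- outer(y1, y2, zstat)
  w <- outer(dbinom(y1, n1, phat), dbinom(y2, n2, phat))
  eps <- 1e-12
  extreme <- if (alternative == "two_sided") abs(z) >= abs(z_obs) - eps
             else z >= z_obs - eps
  min(sum(w[extreme]), 1)
}

#' Hypergeometric test for the overlap of two gene lists
#'
#' Upper-tail (inclusive) probability that two lists of sizes `k1` and
#' `k2`, drawn from a universe of `N` tested genes, share at least the
#' observed number of members. Symmetric in the two lists.
#'
#' @param N Universe size (genes tested in both conditions).
#' @param k1,k2 List sizes (each `<= N`).
#' @param o Observed overlap (`<= min(k1, k2)`).
#' @return `P[X >= o]` for `X ~ Hypergeometric(N, k1, k2)`, in `(0, 1]`.
#' @export
hypergeom_overlap_test <- function(N, k1, k2, o) {
  if (k1 > N || k2 > N) abort("list sizes cannot exceed the universe size")
  if (o > min(k1, k2)) abort("overlap cannot exceed the smaller list")
  if (o < 0 || N < 0) abort("counts must be non-negative")
  phyper(o - 1, m = k1, n = N - k1, k = k2, lower.tail = FALSE)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' @param table A 2x2 matrix of non-negative counts with positive margins.
#' @param correct Apply the Yates continuity correction (default `FALSE`,
#'   matching the package's no-correction convention; the flag is exposed).
#' @return A one-row tibble with `statistic`, `p_value` (chi-square with
#'   1 df) and `min_expected`. Warns when any expected count is below 5.
#' @export
chisq_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2")
  if (any(table < 0)) abort("cell counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("both margins must be positive")
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    warn(sprintf("chi-square approximation may be poor: minimum expected count %.2f < 5",
                 min(expected)))
  }
  dev <- abs(table - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  tibble::tibble(statistic = stat,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 min_expected = min(expected))
}

#' Pairwise list overlap across sample groups
#'
#' For each pair of sample groups, restricts both gene lists to the shared
#' universe (transcripts tested in both groups), counts the overlap and
#' computes the hypergeometric upper-tail p-value.
#'
#' @param lists Named list of character vectors: the biased transcripts per
#'   sample group.
#' @param universes Named list of character vectors: the transcripts tested
#'   per sample group; names must cover those of `lists`.
#' @return One row per unordered pair with `n_universe`, per-list sizes
#'   within the shared universe, `overlap` and `p_value`.
#' @export
overlap_matrix <- function(lists, universes) {
  groups <- names(lists)
  if (is.null(groups) || !all(groups %in% names(universes))) {
    abort("`lists` and `universes` must be named by sample group, with universes covering lists")
  }
  if (length(groups) < 2) {
    return(tibble::tibble(group1 = character(), group2 = character(),
                          n_universe = integer(), k1 = integer(),
                          k2 = integer(), overlap = integer(),
                          p_value = double()))
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    shared <- intersect(universes[[pr[1]]], universes[[pr[2]]])
    l1 <- intersect(lists[[pr[1]]], shared)
    l2 <- intersect(lists[[pr[2]]], shared)
    o <- length(intersect(l1, l2))
    tibble::tibble(
      group1 = pr[1], group2 = pr[2],
      n_universe = length(shared),
      k1 = length(l1), k2 = length(l2), overlap = o,
      p_value = if (length(shared) == 0) 1 else
        hypergeom_overlap_test(length(shared), length(l1), length(l2), o)
    )
  })
}

#' Read a gene-membership list (one identifier per line)
#'
#' @param path Plain-text file, one transcript/gene identifier per line;
#'   blank lines and lines starting with `#` are skipped.
#' @return Character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  x <- readr::read_lines(path)
  x <- trimws(x)
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
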