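# Set-level evaluation statistics: hypergeometric overlap with a reference
# gene list, Fisher's exact comparison of two candidate sets, and the
# per-term hypergeometric enrichment statistic used by functional profiles.

check_overlap_args <- function(n, k, K, N) {
  n <- check_count(n, "n"); k <- check_count(k, "k")
  K <- check_count(K, "K"); N <- check_count(N, "N")
  if (k > min(n, K)) abort("`k` must not exceed min(n, K).")
  if (n > N || K > N) abort("`n` and `K` must not exceed the background `N`.")
  list(n = n, k = k, K = K, N = N)
}

#' Hypergeometric overlap p-value of a gene set against a reference list
#'
#' Probability that a random size-`n` draw from an `N`-gene background shares
#' more than `k` genes with a size-`K` reference list. The default tail is
#' STRICTLY greater, `P(X > k)` — the convention that reproduces the printed
#' overlap statistics of the original analysis (see the methods vignette);
#' the inclusive tail `P(X >= k)` is also exposed.
#'
#' @param n Candidate set size.
#' @param k Observed overlap with the reference list.
#' @param K Reference list size (e.g. 742 known cancer genes).
#' @param N Background size; defaults to 20000 protein-coding genes.
#' @param tail `"greater"` for `P(X > k)` (default) or `"at_least"` for
#'   `P(X >= k)`.
#' @return The upper-tail p-value.
#' @examples
#' hypergeom_overlap_pvalue(25, 6, 742, 20000)   # 2.518e-05
#' @export
hypergeom_overlap_pvalue <- function(n, k, K, N = 20000,
                                     tail = c("greater", "at_least")) {
  a <- check_overlap_args(n, k, K, N)
  tail <- match.arg(tail)
  q <- if (tail == "greater") a$k else a$k - 1L
  phyper(q, a$K, a$N - a$K, a$n, lower.tail = FALSE)
}

#' Two-sided Fisher's exact test on a 2x2 contingency table
#'
#' Exact test of association conditional on the margins; the two-sided
#' p-value sums the hypergeometric point probabilities of all tables no more
#' probable than the observed one (the minimum-likelihood convention of
#' `stats::fisher.test`).
#'
#' @param table A 2x2 matrix of non-negative counts, or the first of four
#'   scalar cell counts given row-wise (`a`, `b` top row; `c`, `d` bottom).
#' @param b,c,d Remaining cells when scalars are given.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(93, 1825, 6, 25), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (!is.matrix(table)) {
    stopifnot(!is.null(b), !is.null(c), !is.null(d))
    table <- matrix(c(table, b, c, d), 2, 2, byrow = TRUE)
  }
  if (!all(dim(table) == 2L) || any(table < 0) || any(table != trunc(table)))
    abort("`table` must be a 2x2 matrix of non-negative integer counts.")
  if (sum(table) == 0) abort("all-zero contingency table")
  fisher.test(table, alternative = "two.sided")$p.value
}

#' Compare the reference-list overlap of two candidate gene sets
#'
#' Fisher's exact comparison of how strongly two gene sets overlap a common
#' reference list. With `cells = "size"` (default) the 2x2 cells are the
#' per-set (overlap, set size) pairs as printed in comparison tables of this
#' kind — the construction used by the original analysis; `cells =
#' "complement"` uses the statistically orthodox (overlap, non-overlap)
#' cells. See the methods vignette for why both are exposed.
#'
#' @param n1,k1 Size of the first set and its overlap with the reference.
#' @param n2,k2 Same for the second set.
#' @param cells `"size"` or `"complement"` (see above).
#' @return A one-row tibble: `n1`, `k1`, `n2`, `k2`, `p_value`.
#' @examples
#' compare_sets_fisher(1825, 93, 25, 6)  # p ~ 3.858e-03
#' @export
compare_sets_fisher <- function(n1, k1, n2, k2,
                                cells = c("size", "complement")) {
  cells <- match.arg(cells)
  n1 <- check_count(n1, "n1"); k1 <- check_count(k1, "k1")
  n2 <- check_count(n2, "n2"); k2 <- check_count(k2, "k2")
  if (k1 > n1 || k2 > n2) abort("overlap cannot exceed set size")
  m <- if (cells == "size")
    matrix(c(k1, n1, k2, n2), 2, 2, byrow = TRUE)
  else
    matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2, byrow = TRUE)
  tibble(n1 = n1, k1 = k1, n2 = n2, k2 = k2,
         p_value = fisher_exact_2x2(m))
}

#' Per-term hypergeometric enrichment p-value
#'
#' Inclusive upper tail `P(X >= k)` for a term annotating `term_size` of
#' `background_size` genes when `term_hits` of a `set_size`-gene set carry
#' it. The inclusive tail is the enrichment convention: a fully contained
#' term then has a finite `-log10` p-value, which the functional profiles
#' require.
#'
#' @param set_size Number of (background-annotated) genes in the query set.
#' @param term_hits Number of query genes annotated with the term.
#' @param term_size Number of background genes annotated with the term.
#' @param background_size Number of annotated background genes.
#' @return The enrichment p-value, `P(X >= term_hits)`.
#' @examples
#' term_enrichment_pvalue(5, 5, 5, 100)   # 1 / choose(100, 5)
#' @export
term_enrichment_pvalue <- function(set_size, term_hits, term_size,
                                   background_size) {
  a <- check_overlap_args(set_size, term_hits, term_size, background_size)
  phyper(a$k - 1L, a$K, a$N - a$K, a$n, lower.tail = FALSE)
}

#' Overlap-test report for candidate gene sets
#'
#' Tabulates, for each candidate set, its size, overlap with the reference
#' list, and the hypergeometric overlap p-value — the layout of a
#' candidate-versus-reference comparison table.
#'
#' @param sets Named list of character vectors (candidate gene sets).
#' @param reference Character vector: the reference gene list.
#' @param background_n Background gene count (default 20000).
#' @param tail Tail convention passed to [hypergeom_overlap_pvalue()].
#' @return A tibble with columns `set`, `n`, `overlap`, `p_value`.
#' @export
overlap_test <- function(sets, reference, background_n = 20000,
                         tail = "greater") {
  stopifnot(is.list(sets), !is.null(names(sets)), is.character(reference))
  reference <- unique(reference)
  purrr::map2_dfr(sets, names(sets), function(s, nm) {
    s <- unique(s)
    tibble(set = nm, n = length(s), overlap = length(intersect(s, reference)),
           p_value = hypergeom_overlap_pvalue(length(s),
                                              length(intersect(s, reference)),
                                              length(reference), background_n,
                                              tail = tail))
  })
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments ignored.
#'
#' @param file Path, connection, or literal text wrapped in [I()].
#' @return Character vector of unique identifiers in file order.
#' @export
read_gene_list <- function(file) {
  x <- trimws(readr::read_lines(file))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}
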