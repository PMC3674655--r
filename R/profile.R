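# GO functional profiles: -log10 per-term enrichment p-values over a term
# universe, compared by Pearson correlation.

#' Read a gene-to-term annotation table
#'
#' Two-column tab-separated text (gene, term), one row per annotation, or
#' GAF-style tab-separated lines from which the gene (column 3) and term
#' (column 5) are extracted. An optional third `aspect` column is kept when
#' present in the two-column dialect.
#'
#' @param file Path, connection, or literal text wrapped in [I()].
#' @param gaf Set `TRUE` to parse GAF-style columns instead.
#' @return A tibble with columns `gene`, `term` (and `aspect` if present).
#' @export
read_annotation <- function(file, gaf = FALSE) {
  if (gaf) {
    lines <- readr::read_lines(file)
    lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 5L)) abort("GAF rows need at least 5 columns")
    return(distinct(tibble(gene = vapply(parts, `[[`, "", 3L),
                           term = vapply(parts, `[[`, "", 5L))))
  }
  ann <- readr::read_tsv(file, col_names = FALSE, col_types = readr::cols(.default = "c"))
  if (ncol(ann) < 2L) abort("annotation needs at least gene and term columns")
  names(ann)[1:2] <- c("gene", "term")
  if (ncol(ann) >= 3L) names(ann)[3] <- "aspect"
  if (tolower(ann$gene[1]) %in% c("gene", "symbol")) ann <- ann[-1L, ]
  distinct(ann[, intersect(c("gene", "term", "aspect"), names(ann))])
}

#' Build the GO functional profile of a gene set
#'
#' For every term in the universe, computes the hypergeometric enrichment
#' p-value of the gene set (inclusive upper tail, via
#' [term_enrichment_pvalue()]) against the annotation background — all genes
#' carrying at least one term — and stores `-log10 p`. A term annotating no
#' member of the set has p = 1 and profile value 0. Values are capped (300
#' by default, the `-log10` of the smallest positive normal double) so fully
#' determined terms stay finite.
#'
#' @param gene_set Character vector of gene identifiers.
#' @param annotation Tibble with columns `gene`, `term` (and optionally
#'   `aspect`), as from [read_annotation()] or [generate_annotation()].
#' @param term_universe Ordered character vector of terms to profile over;
#'   defaults to all terms annotating at least one background gene, sorted.
#' @param aspect Optional aspect filter applied when the annotation carries
#'   an `aspect` column.
#' @param cap Upper bound for profile values.
#' @return A `functional_profile` tibble: `term`, `value` (>= 0), in
#'   universe order, with attributes `set_size` and `background_size`.
#' @export
build_profile <- function(gene_set, annotation, term_universe = NULL,
                          aspect = NULL, cap = 300) {
  stopifnot(is.character(gene_set), is.data.frame(annotation))
  if (!is.null(aspect) && "aspect" %in% names(annotation))
    annotation <- filter(annotation, .data$aspect %in% !!aspect)
  background <- unique(annotation$gene)
  eff <- intersect(unique(gene_set), background)
  if (length(eff) == 0L)
    abort("no gene of the set is annotated (empty effective gene set)")
  term_universe <- term_universe %||% sort(unique(annotation$term))
  if (length(term_universe) == 0L) abort("empty term universe")

  ann <- filter(annotation, .data$term %in% term_universe)
  term_size <- table(factor(ann$term, levels = term_universe))
  in_set <- filter(ann, .data$gene %in% eff)
  hits <- table(factor(in_set$term, levels = term_universe))

  N <- length(background); n <- length(eff)
  K <- as.integer(term_size); k <- as.integer(hits)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  value <- pmin(-log10(p), cap)
  new_tbl_subclass(tibble(term = term_universe, value = value),
                   "functional_profile",
                   set_size = n, background_size = N, cap = cap)
}

#' Pearson similarity of two functional profiles
#'
#' Sample Pearson correlation of the `-log10` enrichment vectors of two gene
#' sets over the same ordered term universe — the profile-similarity
#' statistic used to compare candidate sets with known cancer genes.
#'
#' @param p1,p2 `functional_profile` tibbles over identical term universes.
#' @return Correlation in `[-1, 1]`.
#' @export
profile_similarity <- function(p1, p2) {
  stopifnot(is.data.frame(p1), is.data.frame(p2))
  if (nrow(p1) != nrow(p2) || !identical(p1$term, p2$term))
    abort("profiles must share the same ordered term universe")
  if (stats::sd(p1$value) == 0 || stats::sd(p2$value) == 0)
    abort("zero-variance profile: correlation undefined")
  cor(p1$value, p2$value, method = "pearson")
}

#' Write a functional profile as tab-separated text
#'
#' @param profile A `functional_profile`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_profile <- function(profile, file) {
  readr::write_tsv(as_tibble(profile), file)
  invisible(file)
}

#' @rdname build_profile
#' @param object A `functional_profile`.
#' @param top_n Number of top-valued terms shown.
#' @param ... Unused.
#' @export
autoplot.functional_profile <- function(object, top_n = 25, ...) {
  df <- head(arrange(as_tibble(object), desc(.data$value)), top_n)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$term, .data$value),
                                   y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "enrichment p"),
                  title = "Functional profile")
}

#' Scatter comparison of two functional profiles
#'
#' Plots the paired `-log10` enrichment values of two profiles with their
#' Pearson correlation in the title.
#'
#' @param p1,p2 `functional_profile` tibbles over the same term universe.
#' @param labels Length-2 axis labels.
#' @return A ggplot object.
#' @export
plot_profile_comparison <- function(p1, p2, labels = c("set 1", "set 2")) {
  r <- profile_similarity(p1, p2)
  df <- tibble(x = p1$value, y = p2$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = labels[1], y = labels[2],
                  title = sprintf("Profile similarity r = %.3f", r))
}
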