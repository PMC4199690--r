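# Between-genome comparison of per-gene codon bias over an ortholog map:
# scatter about the identity diagonal, signed difference ranking, and a
# count-based asymmetry summary.

#' Read a two-column ortholog map
#'
#' @param path Path to a headerless two-column TSV (gene id in species A,
#'   gene id in species B). Duplicate rows are removed with a warning.
#' @return A tibble with columns `gene_a`, `gene_b`.
#' @export
read_ortholog_map <- function(path) {
  tbl <- utils::read.table(
    path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    colClasses = "character"
  )
  if (ncol(tbl) < 2) stop("ortholog map must have two columns: ", path)
  out <- tibble::tibble(gene_a = tbl[[1]], gene_b = tbl[[2]])
  if (anyDuplicated(out)) {
    warning("duplicate ortholog map rows removed")
    out <- dplyr::distinct(out)
  }
  out
}

#' Pair per-gene CUB scores across two genomes
#'
#' Joins differential-entropy results for two species over an ortholog map
#' and computes, per pair, the signed difference `delta = D_a - D_b`
#' (negative = more biased in species A) and the perpendicular distance of
#' the scatter point from the identity diagonal, `|delta| / sqrt(2)`.
#' Scores computed under different estimators are not comparable and are
#' refused. Unpaired genes on either side are counted in a message and in
#' attributes `unpaired_a` / `unpaired_b`.
#'
#' @param results_a,results_b CUB score tibbles from [cub_score()] for the
#'   two species.
#' @param ortholog_map A tibble with columns `gene_a`, `gene_b` (see
#'   [read_ortholog_map()]), or `NULL` for the identity map over shared
#'   gene ids.
#' @return A tibble with columns `gene_id` (species A symbol), `gene_b`,
#'   `D_a`, `D_b`, `delta`, `diag_dist`.
#' @export
pair_orthologs <- function(results_a, results_b, ortholog_map = NULL) {
  stopifnot(
    all(c("gene_id", "D") %in% names(results_a)),
    all(c("gene_id", "D") %in% names(results_b))
  )
  est_a <- unique(results_a$estimator)
  est_b <- unique(results_b$estimator)
  if (length(est_a) == 1 && length(est_b) == 1 && !identical(est_a, est_b)) {
    stop(
      "estimator mismatch between species: '", est_a, "' vs '", est_b,
      "'; D values are only comparable under one estimator"
    )
  }
  if (is.null(ortholog_map)) {
    shared <- intersect(results_a$gene_id, results_b$gene_id)
    ortholog_map <- tibble::tibble(gene_a = shared, gene_b = shared)
  }
  stopifnot(all(c("gene_a", "gene_b") %in% names(ortholog_map)))
  if (anyDuplicated(ortholog_map)) {
    warning("duplicate ortholog map rows removed")
    ortholog_map <- dplyr::distinct(ortholog_map)
  }
  unknown <- sum(
    !(ortholog_map$gene_a %in% results_a$gene_id) |
      !(ortholog_map$gene_b %in% results_b$gene_id)
  )
  if (unknown > 0) {
    message(unknown, " map row(s) referencing unscored genes skipped")
  }
  pairs <- ortholog_map |>
    dplyr::inner_join(
      dplyr::select(results_a, gene_a = "gene_id", D_a = "D"), by = "gene_a"
    ) |>
    dplyr::inner_join(
      dplyr::select(results_b, gene_b = "gene_id", D_b = "D"), by = "gene_b"
    ) |>
    dplyr::filter(!is.na(.data$D_a), !is.na(.data$D_b)) |>
    dplyr::mutate(
      delta = .data$D_a - .data$D_b,
      diag_dist = abs(.data$delta) / sqrt(2)
    ) |>
    dplyr::rename(gene_id = "gene_a") |>
    dplyr::relocate("gene_id", "gene_b")
  unpaired_a <- sum(!(results_a$gene_id %in% ortholog_map$gene_a[ortholog_map$gene_b %in% results_b$gene_id]))
  unpaired_b <- sum(!(results_b$gene_id %in% ortholog_map$gene_b[ortholog_map$gene_a %in% results_a$gene_id]))
  if (nrow(pairs) == 0) warning("no ortholog pairs scored in both species")
  message(
    nrow(pairs), " ortholog pair(s); unpaired: ", unpaired_a,
    " in A, ", unpaired_b, " in B"
  )
  attr(pairs, "unpaired_a") <- unpaired_a
  attr(pairs, "unpaired_b") <- unpaired_b
  pairs
}

#' Rank ortholog pairs by differential bias
#'
#' @param pairs A tibble from [pair_orthologs()].
#' @param direction `"a_more_biased"` sorts by ascending signed `delta`
#'   (most negative first), `"b_more_biased"` by descending `delta`,
#'   `"either"` by descending distance from the diagonal.
#' @return The sorted tibble with a `rank` column.
#' @export
rank_pairs <- function(pairs,
                       direction = c("a_more_biased", "b_more_biased", "either")) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "delta", "diag_dist") %in% names(pairs)))
  out <- switch(direction,
    a_more_biased = dplyr::arrange(pairs, .data$delta, .data$gene_id),
    b_more_biased = dplyr::arrange(pairs, dplyr::desc(.data$delta), .data$gene_id),
    either = dplyr::arrange(pairs, dplyr::desc(.data$diag_dist), .data$gene_id)
  )
  dplyr::mutate(out, rank = dplyr::row_number())
}

#' Asymmetry of the between-genome bias distribution
#'
#' Counts orthologs whose signed difference exceeds a threshold in either
#' direction and tests the symmetry of the two counts with an exact sign
#' (binomial) test, the distribution-free analogue of asking whether one
#' species carries more strongly biased orthologs than the other.
#'
#' @param pairs A tibble from [pair_orthologs()].
#' @param threshold Positive threshold on `|delta|`; default
#'   `2 * mad(delta)`.
#' @return An object of class `ortholog_asymmetry` with counts, the sign
#'   test p-value (`NA` when no pair exceeds the threshold), the median
#'   delta, and the threshold used; has `tidy()` and `glance()` methods.
#' @export
asymmetry <- function(pairs, threshold = NULL) {
  stopifnot("delta" %in% names(pairs))
  delta <- pairs$delta
  if (is.null(threshold)) {
    threshold <- 2 * stats::mad(delta)
    # degenerate spread (e.g. identical score tables): keep t positive so
    # the no-exceedance path below reports cleanly
    if (threshold == 0) threshold <- .Machine$double.eps
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be a positive number")
  }
  n_a <- sum(delta < -threshold) # more biased in species A
  n_b <- sum(delta > threshold)  # more biased in species B
  p <- if (n_a + n_b == 0) {
    warning("no pair exceeds the threshold; sign test undefined")
    NA_real_
  } else {
    stats::binom.test(n_a, n_a + n_b)$p.value
  }
  structure(
    list(
      n_a_more = n_a, n_b_more = n_b, sign_test_p = p,
      median_delta = stats::median(delta), threshold = threshold,
      n_pairs = length(delta)
    ),
    class = "ortholog_asymmetry"
  )
}

#' @export
print.ortholog_asymmetry <- function(x, ...) {
  cat(
    "Ortholog bias asymmetry over", x$n_pairs, "pairs (|delta| >",
    formatC(x$threshold, digits = 3, format = "f"), "):\n",
    " more biased in A:", x$n_a_more, "| more biased in B:", x$n_b_more,
    "| sign-test p =", formatC(x$sign_test_p, digits = 3, format = "g"),
    "| median delta =", formatC(x$median_delta, digits = 3, format = "f"), "\n"
  )
  invisible(x)
}

#' @export
tidy.ortholog_asymmetry <- function(x, ...) {
  tibble::tibble(
    direction = c("a_more_biased", "b_more_biased"),
    n = c(x$n_a_more, x$n_b_more)
  )
}

#' @export
glance.ortholog_asymmetry <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs, n_a_more = x$n_a_more, n_b_more = x$n_b_more,
    sign_test_p = x$sign_test_p, median_delta = x$median_delta,
    threshold = x$threshold
  )
}

#' Scatter plot of between-genome codon bias
#'
#' Fig.-style ortholog scatter: per-gene differential entropy in species A
#' against species B, with the identity diagonal; distance from the diagonal
#' is the differential-bias signal.
#'
#' @param pairs A tibble from [pair_orthologs()].
#' @param highlight Optional character vector of gene ids to emphasise.
#' @return A ggplot object.
#' @export
plot_ortholog_scatter <- function(pairs, highlight = NULL) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$D_a, y = .data$D_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(
      x = "differential entropy D, species A",
      y = "differential entropy D, species B"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(pairs, .data$gene_id %in% highlight),
      colour = "red"
    )
  }
  p
}
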