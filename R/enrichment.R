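# Ranked-list functional enrichment via the minimum-hypergeometric (mHG)
# statistic: scan every prefix of the ranked gene list, take the minimal
# hypergeometric tail, and correct exactly for the threshold optimisation
# with a dynamic program over label arrangements.

#' Read gene sets from a GMT file
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `term_id`, `name`, and list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: ", which(bad)[1])
  tibble::tibble(
    term_id = vapply(parts, `[[`, "", 1L),
    name = vapply(parts, `[[`, "", 2L),
    genes = lapply(parts, function(x) unique(x[-(1:2)]))
  )
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets A tibble as returned by [read_gmt()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(all(c("term_id", "name", "genes") %in% names(gene_sets)))
  lines <- purrr::pmap_chr(
    list(gene_sets$term_id, gene_sets$name, gene_sets$genes),
    function(id, nm, g) paste(c(id, nm, g), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Remove duplicate symbols from a ranked list
#'
#' Keeps only the best-ranked (first) occurrence of each symbol, as isoform
#' collapse requires before enrichment; the number removed is reported.
#'
#' @param ranked Character vector of gene symbols, best rank first.
#' @return The deduplicated character vector.
#' @examples
#' dedup_ranked(c("A", "B", "A", "C"))
#' @export
dedup_ranked <- function(ranked) {
  ranked <- as.character(ranked)
  keep <- !duplicated(ranked)
  n_rm <- sum(!keep)
  if (n_rm > 0) message(n_rm, " duplicate(s) removed from ranked list")
  ranked[keep]
}

#' Hypergeometric upper tail
#'
#' `P(X >= b)` for `X ~ Hypergeometric(N, B, n)`: drawing `n` genes without
#' replacement from a universe of `N` containing `B` term genes.
#'
#' @param b Number of term genes observed in the draw.
#' @param N Universe size.
#' @param B Term size within the universe.
#' @param n Draw (threshold) size.
#' @return The tail probability.
#' @examples
#' hypergeom_tail(2, 4, 2, 2) # 1/6
#' @export
hypergeom_tail <- function(b, N, B, n) {
  if (any(b < 0) || any(b > pmin(n, B)) || any(B > N) || any(n > N)) {
    stop("require 0 <= b <= min(n, B) <= N")
  }
  stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

#' Minimum-hypergeometric scan of a ranked list
#'
#' Evaluates the hypergeometric tail at every prefix threshold
#' `n = 1..N` of the ranked list and returns the minimum, together with the
#' optimal threshold `n_star` (smallest on ties) and the term count `b_star`
#' above it.
#'
#' @param ranked Deduplicated character vector of gene symbols, best first.
#' @param term_set Character vector of term gene symbols.
#' @return A list with `mhg_score`, `n_star`, `b_star`, `N`, `B`.
#' @export
mhg <- function(ranked, term_set) {
  ranked <- as.character(ranked)
  if (anyDuplicated(ranked)) stop("ranked list contains duplicates; dedup first")
  N <- length(ranked)
  lambda <- ranked %in% term_set
  B <- sum(lambda)
  if (B == 0) stop("term is empty after intersection with the ranked list")
  b <- cumsum(lambda)
  n <- seq_len(N)
  tails <- stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
  n_star <- which.min(tails)
  list(
    mhg_score = tails[n_star], n_star = n_star, b_star = b[n_star],
    N = N, B = B
  )
}

#' Exact p-value for the mHG statistic
#'
#' The probability, under a uniform random arrangement of the `B` term genes
#' among `N` list positions, that the minimal hypergeometric tail over all
#' thresholds is at most the observed `mhg_score`. Computed exactly by a
#' dynamic program that counts label arrangements whose prefix path never
#' enters the rejection region; satisfies `p <= min(1, N * mhg_score)`.
#'
#' @param mhg_score Observed minimal tail from [mhg()].
#' @param N Universe size.
#' @param B Term size.
#' @return The exact p-value in `(0, 1]`.
#' @export
mhg_pvalue <- function(mhg_score, N, B) {
  stopifnot(N >= 1, B >= 0, B <= N)
  if (B == 0 || B == N || mhg_score >= 1) return(1) # single labeling cases
  thresh <- mhg_score * (1 + 1e-9)
  # s[b+1] = (#allowed arrangements of b term genes in the first n slots
  #           whose prefix path avoids the rejection region) / choose(n, b)
  s <- c(1, rep(0, B))
  bs <- 0:B
  for (n in seq_len(N)) {
    s_new <- s * (n - bs) / n
    s_new[-1] <- s_new[-1] + s[-length(s)] * bs[-1] / n
    # rejection region at this threshold: tail prob <= observed minimum
    bb <- 0:min(n, B)
    reject <- stats::phyper(bb - 1, B, N - B, n, lower.tail = FALSE) <= thresh
    s_new[bb[reject] + 1] <- 0
    if (B > n) s_new[(n + 2):(B + 1)] <- 0
    s <- s_new
  }
  p <- 1 - s[B + 1]
  # 1 - s cannot resolve below machine epsilon; floor keeps p a probability
  min(max(p, .Machine$double.eps), 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' a thin wrapper around [stats::p.adjust()] that validates its input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Ranked-list enrichment over a gene-set collection
#'
#' Runs the full flexible-threshold enrichment procedure on a ranked gene
#' list: duplicate symbols are collapsed to their best rank, the universe is
#' restricted to ranked genes carrying at least one annotation, each term of
#' acceptable size is scored by [mhg()], p-values are computed exactly with
#' [mhg_pvalue()], and q-values by Benjamini-Hochberg across all tested
#' terms.
#'
#' @param ranked Character vector of gene symbols in rank order (most biased
#'   first), or a data frame with a `gene_id` column already sorted by rank
#'   (e.g. from [rank_cub()]).
#' @param gene_sets A gene-set tibble from [read_gmt()] (columns `term_id`,
#'   `name`, `genes`) or a named list of character vectors.
#' @param min_size,max_size Terms whose intersection with the universe falls
#'   outside `[min_size, max_size]` are skipped (defaults 3 and 2000).
#' @return A tibble with one row per tested term: `term_id`, `name`, `N`,
#'   `B`, `n_star`, `b_star`, `mhg_score`, `p_value`, `q_value`,
#'   `leading_genes` (semicolon-joined genes above the optimal threshold),
#'   sorted by `p_value`.
#' @export
enrich_ranked <- function(ranked, gene_sets, min_size = 3, max_size = 2000) {
  if (is.data.frame(ranked)) ranked <- ranked$gene_id
  ranked <- dedup_ranked(ranked)
  if (is.list(gene_sets) && !is.data.frame(gene_sets)) {
    gene_sets <- tibble::tibble(
      term_id = names(gene_sets), name = names(gene_sets),
      genes = unname(gene_sets)
    )
  }
  stopifnot(all(c("term_id", "name", "genes") %in% names(gene_sets)))
  annotated <- unique(unlist(gene_sets$genes, use.names = FALSE))
  universe <- ranked[ranked %in% annotated]
  n_drop <- length(ranked) - length(universe)
  if (n_drop > 0) message(n_drop, " unannotated gene(s) dropped from universe")
  if (length(universe) == 0) stop("no ranked genes carry an annotation")

  rows <- purrr::pmap(
    list(gene_sets$term_id, gene_sets$name, gene_sets$genes),
    function(id, nm, genes) {
      term <- intersect(genes, universe)
      B <- length(term)
      if (B < min_size || B > max_size) return(NULL)
      m <- mhg(universe, term)
      lead <- universe[seq_len(m$n_star)]
      lead <- lead[lead %in% term]
      tibble::tibble(
        term_id = id, name = nm, N = m$N, B = m$B,
        n_star = m$n_star, b_star = m$b_star,
        mhg_score = m$mhg_score,
        p_value = mhg_pvalue(m$mhg_score, m$N, m$B),
        leading_genes = paste(lead, collapse = ";")
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) stop("no terms within the size bounds")
  out$q_value <- bh_fdr(out$p_value)
  dplyr::arrange(
    dplyr::relocate(out, "q_value", .after = "p_value"),
    .data$p_value, .data$term_id
  )
}
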