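# Wright's effective number of codons (ENC), the independent codon-bias
# measure used to cross-validate the entropy statistic. ENC runs from 20
# (one codon used exclusively per amino acid) to 61 (all synonyms used
# equally).

#' Synonymous-family homozygosity
#'
#' Wright's unbiased estimator of the probability that two randomly drawn
#' codons of one amino acid are identical:
#' `F = (n * sum(p^2) - 1) / (n - 1)` with `p` the within-family codon
#' frequencies and `n` the family total. Undefined (NA) for `n < 2`.
#'
#' @param counts Non-negative integer counts over one amino acid's synonyms.
#' @return The homozygosity estimate, or `NA` when `n < 2`.
#' @examples
#' family_homozygosity(c(3, 1)) # 0.5
#' @export
family_homozygosity <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

# per-gene ENC from an integer codon vector (sense codons only)
enc_one <- function(idx) {
  counts <- tabulate(idx, nbins = 64L)
  f_by_fold <- list(`2` = numeric(0), `3` = numeric(0),
                    `4` = numeric(0), `6` = numeric(0))
  used <- 0L
  for (aa in names(.AA_FOLD)) {
    fold <- .AA_FOLD[[aa]]
    if (fold == 1) next
    fam_counts <- counts[.AA_SYN[[aa]]]
    f <- family_homozygosity(fam_counts)
    if (!is.na(f)) {
      f_by_fold[[as.character(fold)]] <- c(f_by_fold[[as.character(fold)]], f)
      used <- used + 1L
    }
  }
  fbar <- vapply(f_by_fold, function(x) if (length(x)) mean(x) else NA_real_, numeric(1))
  # a missing 3-fold class (Ile absent or singleton) is imputed from the
  # neighbouring classes; any other empty class leaves ENC undefined
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- mean(c(fbar[["2"]], fbar[["4"]]))
  }
  if (anyNA(fbar)) {
    return(list(enc = NA_real_, fbar = fbar, used = used))
  }
  enc <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] + 3 / fbar[["6"]]
  enc <- min(max(enc, 20), 61)
  list(enc = enc, fbar = fbar, used = used)
}

#' Effective number of codons per gene
#'
#' Computes Wright's ENC for each gene:
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where `Fk` is the mean
#' homozygosity ([family_homozygosity()]) over the k-fold degenerate amino
#' acid families observed at least twice in the gene. A missing 3-fold class
#' is imputed as the mean of `F2` and `F4`; if any other class is entirely
#' absent the gene is flagged (`enc = NA`). Results are capped to the
#' theoretical range `[20, 61]`. Stop codons and N-containing codons are
#' excluded.
#'
#' @param cds A data frame with `gene_id` and `seq` columns (e.g. from
#'   [validate_cds()]).
#' @return A tibble with columns `gene_id`, `enc`, `F2`, `F3`, `F4`, `F6`,
#'   `families_used`.
#' @export
enc_score <- function(cds) {
  stopifnot(is.data.frame(cds), all(c("gene_id", "seq") %in% names(cds)))
  if (nrow(cds) == 0) stop("no genes supplied")
  one <- function(gid, seq) {
    idx <- usable_codons(seq)
    r <- enc_one(idx)
    tibble::tibble(
      gene_id = gid, enc = r$enc,
      F2 = r$fbar[["2"]], F3 = r$fbar[["3"]],
      F4 = r$fbar[["4"]], F6 = r$fbar[["6"]],
      families_used = r$used
    )
  }
  dplyr::bind_rows(
    purrr::map2(as.character(cds$gene_id), as.character(cds$seq), one)
  )
}

#' Correlate ENC with differential entropy
#'
#' Joins per-gene ENC and differential-entropy results on `gene_id` and
#' computes their Pearson correlation. Both statistics decrease with
#' increasing codon bias, so a positive correlation is the expected
#' cross-validation signal.
#'
#' @param enc_results A tibble from [enc_score()].
#' @param cub_results A tibble from [cub_score()].
#' @return An object of class `cub_validation` with elements `pairs` (tibble
#'   `gene_id`, `enc`, `D`), `r`, and `n`; has [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @export
enc_vs_entropy <- function(enc_results, cub_results) {
  stopifnot("enc" %in% names(enc_results), "D" %in% names(cub_results))
  pairs <- dplyr::inner_join(
    dplyr::select(enc_results, "gene_id", "enc"),
    dplyr::select(cub_results, "gene_id", "D"),
    by = "gene_id"
  )
  pairs <- dplyr::filter(pairs, !is.na(.data$enc), !is.na(.data$D))
  if (nrow(pairs) < 3) {
    stop("fewer than 3 genes shared between ENC and CUB results")
  }
  r <- stats::cor(pairs$enc, pairs$D)
  structure(
    list(pairs = pairs, r = r, n = nrow(pairs)),
    class = "cub_validation"
  )
}

#' @export
print.cub_validation <- function(x, ...) {
  cat("ENC vs differential entropy:", x$n, "genes, Pearson r =",
      formatC(x$r, digits = 3, format = "f"), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cub_validation <- function(x, ...) x$pairs

#' @export
glance.cub_validation <- function(x, ...) {
  tibble::tibble(pearson_r = x$r, n_genes = x$n)
}

#' @export
autoplot.cub_validation <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$enc, y = .data$D)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = "effective number of codons (ENC)",
      y = "differential entropy D (bits/codon)",
      title = sprintf("ENC vs entropy CUB (r = %.3f, n = %d)", object$r, object$n)
    ) +
    ggplot2::theme_minimal()
}
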