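# End-to-end orchestration of the two analysis arms: within-genome ranking
# plus enrichment, between-genome ortholog comparison, and the ENC
# cross-validation. Each writer stamps a provenance header so identical
# configurations yield byte-identical artifacts.

pkg_version <- function() {
  as.character(utils::packageVersion("cubscan"))
}

# write a tibble as TSV with provenance comment lines; on failure leave a
# `.failed` marker instead of a partial file
write_stage_tsv <- function(tbl, path, config) {
  hdr <- c(
    paste0("# cubscan ", pkg_version()),
    paste0("# config: ", paste(names(config), unlist(lapply(config, paste, collapse = ",")),
                               sep = "=", collapse = "; "))
  )
  tryCatch({
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(hdr, con)
    utils::write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }, error = function(e) {
    file.create(paste0(path, ".failed"))
    stop("failed writing ", path, ": ", conditionMessage(e))
  })
  invisible(path)
}

#' Within-genome CUB arm: score, rank, enrich
#'
#' Runs the hypothesis-free arm end to end on one genome: per-gene
#' differential entropy ([cub_score()]), ranking ([rank_cub()]), ranked-list
#' enrichment ([enrich_ranked()]), and the genome-wide usage table
#' ([count_codons()]). When `gene_sets` is `NULL` the enrichment stage is
#' skipped with a warning and scores are still produced.
#'
#' @param cds Validated CDS tibble (see [validate_cds()]).
#' @param gene_sets Gene-set tibble or named list, or `NULL`.
#' @param n_random,estimator,null_model,usage,master_seed Passed to
#'   [cub_score()].
#' @param min_size,max_size Passed to [enrich_ranked()].
#' @param out_dir Optional directory; when given, `scores.tsv`,
#'   `enrichment.tsv` and `usage.tsv` are written with provenance headers.
#' @return A list with `scores`, `ranked`, `enrichment` (or `NULL`), and
#'   `usage`.
#' @export
run_within_genome <- function(cds, gene_sets = NULL, n_random = 20,
                              estimator = "codon_shannon",
                              null_model = "uniform_synonymous", usage = NULL,
                              master_seed = 1, min_size = 3, max_size = 2000,
                              out_dir = NULL) {
  config <- list(
    stage = "within_genome", n_random = n_random, estimator = estimator,
    null_model = null_model, master_seed = master_seed,
    min_size = min_size, max_size = max_size
  )
  scores <- cub_score(
    cds, n_random = n_random, estimator = estimator,
    null_model = null_model, usage = usage, master_seed = master_seed
  )
  ranked <- rank_cub(scores)
  usage_tbl <- count_codons(cds)
  enr <- NULL
  if (is.null(gene_sets)) {
    warning("no gene sets supplied; enrichment stage skipped")
  } else {
    enr <- enrich_ranked(ranked, gene_sets, min_size = min_size,
                         max_size = max_size)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage_tsv(ranked, file.path(out_dir, "scores.tsv"), config)
    write_stage_tsv(usage_tbl, file.path(out_dir, "usage.tsv"), config)
    if (!is.null(enr)) {
      write_stage_tsv(enr, file.path(out_dir, "enrichment.tsv"), config)
    }
  }
  list(scores = scores, ranked = ranked, enrichment = enr, usage = usage_tbl)
}

#' Between-genome arm: ortholog pairing and asymmetry
#'
#' Pairs per-gene scores of two species over an ortholog map, ranks pairs by
#' signed difference, and summarises the distribution asymmetry. Refuses
#' score tables produced under different estimators.
#'
#' @param results_a,results_b CUB score tibbles from [cub_score()].
#' @param ortholog_map Tibble with `gene_a`, `gene_b`, or `NULL` for the
#'   identity map.
#' @param threshold Passed to [asymmetry()].
#' @param out_dir Optional output directory for `pairs.tsv` and
#'   `asymmetry.tsv`.
#' @return A list with `pairs`, `ranked_pairs`, and `asymmetry`.
#' @export
run_between_genomes <- function(results_a, results_b, ortholog_map = NULL,
                                threshold = NULL, out_dir = NULL) {
  pairs <- pair_orthologs(results_a, results_b, ortholog_map)
  ranked_pairs <- rank_pairs(pairs, "a_more_biased")
  asym <- asymmetry(pairs, threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    config <- list(stage = "between_genomes", threshold = asym$threshold)
    write_stage_tsv(ranked_pairs, file.path(out_dir, "pairs.tsv"), config)
    write_stage_tsv(glance(asym), file.path(out_dir, "asymmetry.tsv"), config)
  }
  list(pairs = pairs, ranked_pairs = ranked_pairs, asymmetry = asym)
}

#' Validation arm: ENC and its correlation with differential entropy
#'
#' @param cds Validated CDS tibble.
#' @param cub_results CUB score tibble from [cub_score()] on the same genes.
#' @param out_dir Optional output directory for `enc.tsv` and
#'   `validation.tsv`.
#' @return A list with `enc` (per-gene ENC tibble) and `validation` (a
#'   `cub_validation` object; see [enc_vs_entropy()]).
#' @export
run_validation <- function(cds, cub_results, out_dir = NULL) {
  enc_tbl <- enc_score(cds)
  val <- enc_vs_entropy(enc_tbl, cub_results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    config <- list(stage = "validation")
    write_stage_tsv(enc_tbl, file.path(out_dir, "enc.tsv"), config)
    write_stage_tsv(glance(val), file.path(out_dir, "validation.tsv"), config)
  }
  list(enc = enc_tbl, validation = val)
}

#' Differential entropy against gene length
#'
#' Diagnostic scatter for the length-independence of the CUB statistic: the
#' bulk of an unbiased genome should follow a horizontal band around
#' `D = 0` across all lengths.
#'
#' @param results A CUB score tibble from [cub_score()].
#' @return A ggplot object.
#' @export
plot_cub_length <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$n_codons, y = .data$D)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "gene length (codons)",
      y = "differential entropy D (bits/codon)"
    ) +
    ggplot2::theme_minimal()
}
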