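# Pseudogene lesion screen: frameshifts (indels of length not divisible by
# 3) and premature stop codons read off a pairwise alignment of an intact
# reference CDS against a candidate target locus, followed by the three
# artifact filters (reference self-alignment, splice adjacency, read
# coverage / heterozygosity).

#' Construct a validated aligned pair
#'
#' @param gene_id Gene identifier.
#' @param ref_seq,target_seq Gapped (`-`) nucleotide strings of equal
#'   length; the reference ungapped length must be a multiple of 3 (frame
#'   anchored at the alignment start).
#' @return A one-row tibble with columns `gene_id`, `ref_seq`, `target_seq`.
#' @export
aligned_pair <- function(gene_id, ref_seq, target_seq) {
  ref_seq <- toupper(ref_seq); target_seq <- toupper(target_seq)
  if (nchar(ref_seq) != nchar(target_seq)) {
    stop("aligned sequences must have equal (gapped) lengths")
  }
  r <- strsplit(ref_seq, "")[[1]]
  t <- strsplit(target_seq, "")[[1]]
  if (any(r == "-" & t == "-")) stop("gap-vs-gap alignment column")
  if (sum(r != "-") %% 3 != 0) {
    stop("reference ungapped length is not a multiple of 3")
  }
  tibble::tibble(gene_id = gene_id, ref_seq = ref_seq, target_seq = target_seq)
}

#' Read an aligned-FASTA pair
#'
#' Reads a two-record aligned FASTA (reference first, target second). The
#' target header's first token names the gene.
#'
#' @param path Path to an aligned FASTA file with exactly two records.
#' @return A one-row tibble as from [aligned_pair()].
#' @export
read_aligned_pair <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2) stop("aligned pair FASTA must contain exactly 2 records")
  gid <- strsplit(names(ss)[2], "\\s+")[[1]][1]
  aligned_pair(gid, as.character(ss[[1]]), as.character(ss[[2]]))
}

#' Detect pseudogene lesions in an aligned pair
#'
#' Walks the alignment left to right. Every target indel whose length is not
#' a multiple of 3 is called a frameshift (cumulative frame is tracked, so
#' compensating indels restore frame downstream while each non-triplet indel
#' is still recorded). The target's ungapped sequence is then read
#' contiguously in codons from the alignment start — i.e. in the current
#' reading frame after upstream indels — and every stop codon mapping
#' strictly before the reference terminal stop is called a premature stop.
#'
#' @param pair A one-row tibble (or list) with `gene_id`, `ref_seq`,
#'   `target_seq`; see [aligned_pair()].
#' @return A tibble of calls ordered by position: `gene_id`, `lesion_type`
#'   (`"frameshift"` or `"premature_stop"`), `ref_codon_index`, `detail`
#'   (e.g. `"del31"`, `"ins2"`, or the stop codon), `aln_col` (alignment
#'   column of the lesion), `filters_failed` (empty; filled by the filter
#'   functions). Zero rows when the target is intact.
#' @export
detect_lesions <- function(pair) {
  pair <- aligned_pair(pair$gene_id, pair$ref_seq, pair$target_seq)
  r <- strsplit(pair$ref_seq, "")[[1]]
  t <- strsplit(pair$target_seq, "")[[1]]
  ref_pos <- cumsum(r != "-")      # ref base count up to each column
  n_ref_codons <- ref_pos[length(ref_pos)] %/% 3L

  calls <- list()
  # indel runs: D = deletion from target, I = insertion in target
  cls <- ifelse(t == "-", "D", ifelse(r == "-", "I", "M"))
  runs <- rle(cls)
  col <- 1L
  for (j in seq_along(runs$lengths)) {
    L <- runs$lengths[j]
    if (runs$values[j] != "M" && L %% 3L != 0L) {
      if (runs$values[j] == "D") {
        ref_start <- ref_pos[col] # first deleted ref base
        detail <- paste0("del", L)
      } else {
        ref_start <- ref_pos[col] + 1L # next ref base after the insertion
        detail <- paste0("ins", L)
      }
      calls[[length(calls) + 1L]] <- tibble::tibble(
        gene_id = pair$gene_id, lesion_type = "frameshift",
        ref_codon_index = as.integer((max(ref_start, 1L) - 1L) %/% 3L + 1L),
        detail = detail, aln_col = col
      )
    }
    col <- col + L
  }

  # premature stops in the target's running reading frame
  tgt_cols <- which(t != "-")
  tgt <- t[tgt_cols]
  n_tgt_codons <- length(tgt) %/% 3L
  if (n_tgt_codons > 0) {
    for (j in seq_len(n_tgt_codons)) {
      codon <- paste(tgt[(3L * j - 2L):(3L * j)], collapse = "")
      if (codon %in% c("TAA", "TAG", "TGA")) {
        start_col <- tgt_cols[3L * j - 2L]
        ref_codon <- as.integer((max(ref_pos[start_col], 1L) - 1L) %/% 3L + 1L)
        if (ref_codon < n_ref_codons) {
          calls[[length(calls) + 1L]] <- tibble::tibble(
            gene_id = pair$gene_id, lesion_type = "premature_stop",
            ref_codon_index = ref_codon, detail = codon, aln_col = start_col
          )
        }
      }
    }
  }

  out <- if (length(calls)) dplyr::bind_rows(calls) else tibble::tibble(
    gene_id = character(0), lesion_type = character(0),
    ref_codon_index = integer(0), detail = character(0), aln_col = integer(0)
  )
  out <- dplyr::arrange(out, .data$aln_col, .data$lesion_type)
  out$filters_failed <- rep("", nrow(out))
  out
}

# append a filter label to filters_failed for the rows in `hit`
add_filter <- function(calls, hit, label) {
  ff <- calls$filters_failed
  ff[hit] <- ifelse(nzchar(ff[hit]), paste(ff[hit], label, sep = ";"), label)
  calls$filters_failed <- ff
  calls
}

#' Filter lesions also present in the reference self-alignment
#'
#' A candidate gene whose reference self-alignment itself shows lesions is
#' an alignment-tool artifact: all its calls are flagged
#' `self_alignment`.
#'
#' @param calls Lesion calls from [detect_lesions()] (possibly several
#'   genes).
#' @param ref_self_calls Lesion calls obtained by aligning the reference to
#'   itself / its own genome.
#' @return `calls` with updated `filters_failed`.
#' @export
filter_self_alignment <- function(calls, ref_self_calls) {
  if (nrow(calls) == 0) return(calls)
  bad_genes <- unique(ref_self_calls$gene_id)
  add_filter(calls, calls$gene_id %in% bad_genes, "self_alignment")
}

#' Filter lesions adjacent to splice boundaries
#'
#' Lesions within `window` nucleotides of an annotated exon boundary are
#' likely mis-splicing artifacts and are flagged `splice_adjacent`.
#'
#' @param calls Lesion calls from [detect_lesions()].
#' @param boundaries Sorted exon boundary positions in reference nucleotide
#'   coordinates (1-based). If `NULL` or empty the filter is skipped with a
#'   warning.
#' @param window Flagging window in nucleotides (default 10).
#' @return `calls` with updated `filters_failed`.
#' @export
filter_splice_adjacent <- function(calls, boundaries, window = 10) {
  if (is.null(boundaries) || length(boundaries) == 0) {
    warning("no exon boundaries supplied; splice-adjacency filter skipped")
    return(calls)
  }
  if (is.unsorted(boundaries)) stop("exon boundaries must be sorted")
  if (nrow(calls) == 0) return(calls)
  lesion_nt <- 3 * (calls$ref_codon_index - 1) + 1
  near <- vapply(lesion_nt, function(p) {
    min(abs(boundaries - p), abs(boundaries - (p + 2))) <= window
  }, logical(1))
  add_filter(calls, near, "splice_adjacent")
}

#' Filter lesions with low or heterozygous read support
#'
#' Lesion sites with read depth below `min_cov` are treated as assembly
#' errors (`low_coverage`); sites whose alternate-allele fraction falls
#' inside `het_band` are treated as heterozygous polymorphisms
#' (`heterozygous`). A lesion codon absent from the coverage table is
#' flagged `low_coverage` by convention.
#'
#' @param calls Lesion calls from [detect_lesions()].
#' @param coverage A data frame with columns `position` (reference
#'   nucleotide, 1-based), `depth`, `alt_fraction`.
#' @param min_cov Minimum read depth (default 5).
#' @param het_band Two-element alternate-fraction band treated as
#'   heterozygous (default `c(0.2, 0.8)`).
#' @return `calls` with updated `filters_failed`.
#' @export
filter_coverage <- function(calls, coverage, min_cov = 5,
                            het_band = c(0.2, 0.8)) {
  stopifnot(all(c("position", "depth", "alt_fraction") %in% names(coverage)))
  if (nrow(calls) == 0) return(calls)
  low <- logical(nrow(calls)); het <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    nt <- 3 * (calls$ref_codon_index[i] - 1) + 1:3
    site <- coverage[coverage$position %in% nt, , drop = FALSE]
    if (nrow(site) == 0) {
      message(
        "lesion site (gene ", calls$gene_id[i], ", codon ",
        calls$ref_codon_index[i], ") absent from coverage table; ",
        "flagged low_coverage"
      )
      low[i] <- TRUE
    } else {
      if (min(site$depth) < min_cov) low[i] <- TRUE
      if (any(site$alt_fraction >= het_band[1] & site$alt_fraction <= het_band[2])) {
        het[i] <- TRUE
      }
    }
  }
  calls <- add_filter(calls, low, "low_coverage")
  add_filter(calls, het, "heterozygous")
}

#' Summarise lesion calls into per-gene pseudogene verdicts
#'
#' A gene is a candidate pseudogene when it retains at least one lesion call
#' that failed no filter.
#'
#' @param calls Filtered lesion calls.
#' @return A tibble with one row per gene: `gene_id`, `n_lesions`,
#'   `n_passing`, `lesions` (semicolon-joined `type@codon` strings),
#'   `verdict` (`"candidate_pseudogene"` or `"filtered"`).
#' @export
pseudogene_report <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(
      gene_id = character(0), n_lesions = integer(0), n_passing = integer(0),
      lesions = character(0), verdict = character(0)
    ))
  }
  calls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_lesions = dplyr::n(),
      n_passing = sum(!nzchar(.data$filters_failed)),
      lesions = paste(
        paste0(.data$lesion_type, "@", .data$ref_codon_index),
        collapse = ";"
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      verdict = ifelse(.data$n_passing > 0, "candidate_pseudogene", "filtered")
    )
}

#' Local alignment excerpt around a lesion
#'
#' @param pair The aligned pair the call came from.
#' @param call A one-row lesion call (needs `aln_col`).
#' @param width Alignment columns shown on each side (default 15).
#' @return A list with `ref` and `target` excerpt strings and the excerpt
#'   start column.
#' @export
lesion_context <- function(pair, call, width = 15) {
  n <- nchar(pair$ref_seq)
  lo <- max(1, call$aln_col - width)
  hi <- min(n, call$aln_col + width)
  list(
    ref = substr(pair$ref_seq, lo, hi),
    target = substr(pair$target_seq, lo, hi),
    start_col = lo
  )
}
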