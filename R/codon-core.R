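#' Genome-wide codon usage table
#'
#' Pools codon counts over all supplied genes and reports the classic codon
#' usage table: count and frequency per thousand codons for each of the 64
#' codons. Stop codons are counted whenever the input sequences retain them
#' (i.e. validated with `trim_stop = FALSE`); codons containing N are
#' excluded.
#'
#' @param cds A data frame with a `seq` column of coding sequences (lengths
#'   multiples of 3), e.g. from [validate_cds()].
#' @return A tibble with columns `codon`, `aa`, `count`, `per_thousand`,
#'   ordered by codon. `per_thousand` sums to 1000 up to rounding.
#' @examples
#' count_codons(data.frame(gene_id = "g", seq = "ATGATG"))
#' @export
count_codons <- function(cds) {
  stopifnot(is.data.frame(cds), "seq" %in% names(cds))
  if (nrow(cds) == 0) stop("no genes supplied")
  idx <- unlist(lapply(as.character(cds$seq), codons_to_int), use.names = FALSE)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) stop("no usable codons in input")
  counts <- tabulate(idx, nbins = 64L)
  tibble::tibble(
    codon = .CODONS,
    aa = .CODON_AA,
    count = counts,
    per_thousand = 1000 * counts / sum(counts)
  )
}

#' Call preferred codons from a usage table
#'
#' For each amino acid the preferred codon is the synonym with the highest
#' usage; ties are broken lexicographically and flagged. Amino acids with
#' zero total count are dropped from the result with a message. Stop codons
#' are not assigned a preference.
#'
#' @param usage A codon usage table from [count_codons()].
#' @return A tibble with columns `aa`, `codon`, `per_thousand`, `tie`.
#' @export
preferred_codons <- function(usage) {
  stopifnot(all(c("codon", "aa", "count") %in% names(usage)))
  sense <- dplyr::filter(usage, .data$aa != "*")
  out <- sense |>
    dplyr::group_by(.data$aa) |>
    dplyr::summarise(
      total = sum(.data$count),
      codon = .data$codon[order(-.data$count, .data$codon)][1],
      per_thousand = max(.data$per_thousand),
      tie = sum(.data$count == max(.data$count)) > 1,
      .groups = "drop"
    )
  absent <- out$aa[out$total == 0]
  if (length(absent) > 0) {
    message(
      "no codons observed for amino acid(s): ",
      paste(absent, collapse = ", ")
    )
    out <- dplyr::filter(out, .data$total > 0)
  }
  dplyr::select(out, "aa", "codon", "per_thousand", "tie")
}

#' GC content of nucleotide sequences
#'
#' Computes `100 * (G + C) / (A + C + G + T)` for each sequence; N and other
#' ambiguity codes are excluded from both numerator and denominator.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Numeric vector of GC percentages in `[0, 100]`.
#' @examples
#' gc_percent(c("GGCC", "ATAT", "ATGNG"))
#' @export
gc_percent <- function(seq) {
  seq <- toupper(as.character(seq))
  lf <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(seq), c("A", "C", "G", "T")
  )
  denom <- rowSums(lf)
  if (any(denom == 0)) {
    stop("sequence with no unambiguous A/C/G/T bases: cannot compute GC")
  }
  unname(100 * (lf[, "G"] + lf[, "C"]) / denom)
}

#' GC content of genes and their genomic flanks
#'
#' For each locus, computes GC over the gene body and over windows of up to
#' `flank` bp upstream of the start codon and downstream of the stop codon.
#' Upstream/downstream are defined on the transcribed strand, so for a minus
#' strand gene the upstream window lies at higher genomic coordinates
#' (GC itself is strand-invariant). Windows are clipped at contig boundaries
#' and the achieved lengths are reported; a fully clipped window gives `NA`.
#'
#' @param loci A data frame of gene loci as returned by [read_bed()]
#'   (0-based half-open `start`/`end`, `strand` in `+`/`-`).
#' @param genome A named character vector of contig sequences, a
#'   `Biostrings::DNAStringSet`, or the path to a genome FASTA file.
#' @param flank Requested flank length in bp on each side (default 10000).
#' @return A tibble with columns `gene_id`, `gc_gene`, `gc_up`, `gc_down`,
#'   `up_len`, `down_len`.
#' @export
flank_gc <- function(loci, genome, flank = 10000) {
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in% names(loci)))
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- vapply(strsplit(names(genome), "\\s+"), `[[`, "", 1L)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))

  missing_contig <- setdiff(unique(loci$contig), names(genome))
  if (length(missing_contig) > 0) {
    stop("contig(s) absent from genome: ", paste(missing_contig, collapse = ", "))
  }

  one <- function(gid, contig, start, end, strand) {
    cs <- genome[[contig]]
    clen <- nchar(cs)
    if (end > clen) stop("locus ", gid, " extends beyond contig ", contig)
    gene <- substr(cs, start + 1, end)
    # genomic windows on either side of the gene, clipped at contig edges
    left_lo <- max(0, start - flank); left <- substr(cs, left_lo + 1, start)
    right_hi <- min(clen, end + flank); right <- substr(cs, end + 1, right_hi)
    if (strand == "+") {
      up <- left; down <- right
    } else {
      up <- right; down <- left
    }
    gc_of <- function(s) {
      if (nchar(s) == 0) return(NA_real_)
      gc_percent(s)
    }
    tibble::tibble(
      gene_id = gid,
      gc_gene = gc_of(gene),
      gc_up = gc_of(up),
      gc_down = gc_of(down),
      up_len = nchar(up),
      down_len = nchar(down)
    )
  }
  purrr::pmap(
    list(loci$gene_id, loci$contig, loci$start, loci$end, loci$strand), one
  ) |>
    dplyr::bind_rows()
}
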