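#' Validate a table of coding sequences
#'
#' Applies the package's CDS validation policy to a table of raw sequences:
#' checks the alphabet, enforces unique gene ids, resolves lengths that are
#' not a multiple of 3 according to `policy`, optionally strips the terminal
#' stop codon, and flags genes that are ineligible for per-gene codon-bias
#' scoring (internal stop codons, or more than `max_n_frac` of codons
#' containing N from masked assembly gaps).
#'
#' @param cds A data frame with columns `gene_id` and `seq` (nucleotides over
#'   A/C/G/T/N), and optionally `species`.
#' @param policy How to treat records whose length is not a multiple of 3:
#'   `"strict"` raises an error, `"trim"` drops the trailing 1-2 nt with a
#'   warning, `"skip"` drops the whole record with a warning.
#' @param trim_stop If `TRUE` (default), a terminal stop codon is removed and
#'   recorded in `trimmed_stop`.
#' @param max_n_frac Maximum tolerated fraction of codons containing N before
#'   a gene is flagged ineligible for codon-bias ranking (default 0.10).
#' @return A tibble with columns `gene_id`, `species`, `seq`, `trimmed_stop`,
#'   `n_codons` (usable, N-free, stop-free codons), `cub_eligible`, `note`.
#' @examples
#' validate_cds(data.frame(gene_id = "g1", seq = "ATGAAATAA"))
#' @export
validate_cds <- function(cds, policy = c("trim", "strict", "skip"),
                         trim_stop = TRUE, max_n_frac = 0.10) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(cds), all(c("gene_id", "seq") %in% names(cds)))
  if (nrow(cds) == 0) stop("no coding sequences supplied")

  gene_id <- as.character(cds$gene_id)
  seq <- toupper(as.character(cds$seq))
  species <- if ("species" %in% names(cds)) as.character(cds$species) else NA_character_
  species <- rep_len(species, length(seq))

  dup <- gene_id[duplicated(gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  }
  bad <- !grepl("^[ACGTN]*$", seq)
  if (any(bad)) {
    stop(
      "non-nucleotide characters (other than N) in: ",
      paste(gene_id[bad], collapse = ", ")
    )
  }

  rem <- nchar(seq) %% 3L
  if (any(rem != 0)) {
    offenders <- gene_id[rem != 0]
    if (policy == "strict") {
      stop(
        "sequence length not a multiple of 3 for: ",
        paste(offenders, collapse = ", ")
      )
    } else if (policy == "trim") {
      warning(
        "trimmed trailing bases from ", length(offenders), " record(s): ",
        paste(offenders, collapse = ", ")
      )
      seq <- substr(seq, 1L, nchar(seq) - rem)
    } else {
      warning(
        "skipped ", length(offenders), " record(s) with length not a ",
        "multiple of 3: ", paste(offenders, collapse = ", ")
      )
      keep <- rem == 0
      gene_id <- gene_id[keep]; seq <- seq[keep]; species <- species[keep]
    }
  }
  if (length(seq) == 0) stop("no coding sequences left after validation")

  out <- purrr::pmap(
    list(gene_id, species, seq),
    function(gid, sp, s) {
      idx <- codons_to_int(s)
      trimmed <- FALSE
      if (trim_stop && length(idx) > 0 && !is.na(idx[length(idx)]) &&
          idx[length(idx)] %in% .STOP_IDX) {
        idx <- idx[-length(idx)]
        s <- substr(s, 1L, nchar(s) - 3L)
        trimmed <- TRUE
      }
      n_total <- length(idx)
      n_codon_na <- sum(is.na(idx))
      usable <- idx[!is.na(idx)]
      internal_stop <- any(usable %in% .STOP_IDX)
      usable <- usable[!(usable %in% .STOP_IDX)]
      note <- character(0)
      eligible <- TRUE
      if (internal_stop) {
        eligible <- FALSE
        note <- c(note, "internal_stop")
      }
      if (n_total > 0 && n_codon_na / n_total > max_n_frac) {
        eligible <- FALSE
        note <- c(note, "excess_N")
      }
      if (n_total == 0) {
        eligible <- FALSE
        note <- c(note, "empty")
      }
      tibble::tibble(
        gene_id = gid, species = sp, seq = s, trimmed_stop = trimmed,
        n_codons = length(usable), cub_eligible = eligible,
        note = paste(note, collapse = ";")
      )
    }
  )
  dplyr::bind_rows(out)
}

#' Read coding sequences from a FASTA file
#'
#' Reads one record per gene. The first whitespace-delimited token of each
#' header is the gene id; a second token, when present, is taken as the
#' species tag (overridden by the `species` argument). Records are then
#' passed through [validate_cds()].
#'
#' @param path Path to a FASTA file of coding sequences.
#' @param policy,trim_stop,max_n_frac Passed to [validate_cds()].
#' @param species Optional species label applied to every record.
#' @return A validated CDS tibble (see [validate_cds()]).
#' @export
read_cds_fasta <- function(path, policy = c("trim", "strict", "skip"),
                           trim_stop = TRUE, max_n_frac = 0.10,
                           species = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  hdr <- strsplit(names(ss), "\\s+")
  tbl <- tibble::tibble(
    gene_id = vapply(hdr, `[[`, "", 1L),
    species = vapply(hdr, function(x) if (length(x) >= 2) x[[2]] else NA_character_, ""),
    seq = as.character(ss)
  )
  if (!is.null(species)) tbl$species <- species
  validate_cds(tbl, policy = policy, trim_stop = trim_stop, max_n_frac = max_n_frac)
}

#' Write coding sequences to FASTA
#'
#' Headers are `gene_id species` (the species tag is omitted when `NA`), so
#' that [read_cds_fasta()] round-trips `gene_id` and `seq` exactly.
#'
#' @param cds A data frame with columns `gene_id` and `seq` (and optionally
#'   `species`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path) {
  stopifnot(all(c("gene_id", "seq") %in% names(cds)))
  sp <- if ("species" %in% names(cds)) as.character(cds$species) else NA_character_
  sp <- rep_len(sp, nrow(cds))
  hdr <- ifelse(is.na(sp), cds$gene_id, paste(cds$gene_id, sp))
  ss <- Biostrings::DNAStringSet(as.character(cds$seq))
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene loci from a BED6 file
#'
#' Coordinates are kept in BED's native 0-based half-open convention; the
#' strand column is required.
#'
#' @param path Path to a 6-column BED file.
#' @return A tibble with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  tbl <- utils::read.table(
    path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
    colClasses = "character", fill = TRUE
  )
  if (ncol(tbl) < 6) stop("BED file must have 6 columns (strand required): ", path)
  out <- tibble::tibble(
    gene_id = tbl[[4]],
    contig = tbl[[1]],
    start = as.numeric(tbl[[2]]),
    end = as.numeric(tbl[[3]]),
    strand = tbl[[6]]
  )
  if (any(is.na(out$start)) || any(is.na(out$end))) {
    stop("non-numeric coordinates in BED file")
  }
  bad <- out$start >= out$end
  if (any(bad)) {
    stop(
      "start >= end (empty or inverted interval) for: ",
      paste(out$gene_id[bad], collapse = ", ")
    )
  }
  if (!all(out$strand %in% c("+", "-"))) {
    stop(
      "unknown strand symbol: ",
      paste(unique(setdiff(out$strand, c("+", "-"))), collapse = ", ")
    )
  }
  out
}
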