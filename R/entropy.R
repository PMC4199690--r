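# Differential-entropy codon usage bias.
#
# Each gene's entropy is compared against the mean entropy of synonymous
# re-encodings of the same protein; the difference D = H_obs - H_null_mean
# measures the regularity attributable to codon usage bias (more negative =
# more biased).

# Shannon entropy (bits per codon) of an integer codon vector
entropy_int <- function(idx) {
  counts <- tabulate(idx, nbins = 64L)
  counts <- counts[counts > 0L]
  n <- sum(counts)
  p <- counts / n
  -sum(p * log2(p))
}

# strip NA (N-containing) and stop codons, leaving the scored codons
usable_codons <- function(seq) {
  idx <- codons_to_int(seq)
  idx <- idx[!is.na(idx)]
  idx[!(idx %in% .STOP_IDX)]
}

#' Shannon entropy of a gene's codon usage
#'
#' Entropy (bits per codon) of the empirical distribution of codons in a
#' coding sequence: `-sum(f * log2(f))` over observed codon frequencies.
#' Stop codons and codons containing N are excluded.
#'
#' @param seq A coding sequence (length a multiple of 3).
#' @return Entropy in bits per codon.
#' @examples
#' codon_entropy("ATGATGATG") # 0: a single codon type
#' codon_entropy("GCTGCC")    # 1: uniform over two codons
#' @export
codon_entropy <- function(seq) {
  if (nchar(seq) %% 3 != 0) stop("sequence length is not a multiple of 3")
  idx <- usable_codons(seq)
  if (length(idx) == 0) stop("no usable codons (all N or stop)")
  entropy_int(idx)
}

#' Lempel-Ziv (LZ76) sequence complexity
#'
#' Counts the phrases of the LZ76 exhaustive-history parse of the nucleotide
#' string and normalises by `n / log4(n)`, the asymptotic phrase count of a
#' random sequence over a 4-letter alphabet, giving a complexity close to 1
#' for incompressible sequences and lower for regular ones. Order-sensitive,
#' unlike [codon_entropy()].
#'
#' @param seq A nucleotide string of length >= 4.
#' @return Normalised complexity per symbol (positive real).
#' @export
lz76_complexity <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (n < 4) stop("sequence too short for LZ76 complexity (need >= 4)")
  # Kaspar-Schuster formulation of the LZ76 exhaustive parse
  c_n <- 1L; l <- 1L; i <- 0L; k <- 1L; k_max <- 1L
  repeat {
    if (s[i + k] == s[l + k]) {
      k <- k + 1L
      if (l + k > n) {
        c_n <- c_n + 1L
        break
      }
    } else {
      if (k > k_max) k_max <- k
      i <- i + 1L
      if (i == l) {
        c_n <- c_n + 1L
        l <- l + k_max
        if (l + 1L > n) break
        i <- 0L; k <- 1L; k_max <- 1L
      } else {
        k <- 1L
      }
    }
  }
  c_n / (n / log(n, base = 4))
}

# Build, for genome-frequency nulls, a 64 x 6 cumulative-weight matrix over
# each codon's synonym family from a usage table; families with zero total
# fall back to uniform.
syn_cum_weights <- function(usage) {
  counts <- numeric(64)
  counts[match(usage$codon, .CODONS)] <- usage$count
  cw <- matrix(1, nrow = 64, ncol = 6)
  for (i in seq_len(64)) {
    fam <- .SYN_MAT[i, !is.na(.SYN_MAT[i, ])]
    w <- counts[fam]
    if (sum(w) == 0) w <- rep(1, length(fam))
    cw[i, seq_along(fam)] <- cumsum(w) / sum(w)
  }
  cw
}

# One synonymous re-encoding of an integer codon vector. cum_w is NULL for
# the uniform null or a matrix from syn_cum_weights() for genome-frequency.
randomize_int <- function(idx, cum_w = NULL) {
  L <- length(idx)
  if (L == 0) return(idx)
  if (is.null(cum_w)) {
    k <- .N_SYN[idx]
    r <- 1L + as.integer(floor(stats::runif(L) * k))
    r[r > k] <- k[r > k] # guard against runif returning exactly 1
  } else {
    u <- stats::runif(L)
    r <- 1L + as.integer(rowSums(u > cum_w[idx, , drop = FALSE]))
  }
  .SYN_MAT[cbind(idx, r)]
}

#' Random synonymous re-encoding of a coding sequence
#'
#' Replaces every codon with a random synonym so that the translation is
#' preserved codon-for-codon. Under the default `"uniform_synonymous"` null
#' each synonym is equally likely; under `"genome_frequency"` synonyms are
#' drawn proportionally to their genome-wide counts in `usage`. Codons
#' containing N are left unchanged.
#'
#' @param seq A coding sequence (length a multiple of 3).
#' @param null_model `"uniform_synonymous"` or `"genome_frequency"`.
#' @param usage A usage table from [count_codons()]; required for the
#'   genome-frequency null.
#' @return A nucleotide string encoding the same protein.
#' @export
synonymous_randomize <- function(seq,
                                 null_model = c("uniform_synonymous", "genome_frequency"),
                                 usage = NULL) {
  null_model <- match.arg(null_model)
  if (nchar(seq) %% 3 != 0) stop("sequence length is not a multiple of 3")
  cum_w <- NULL
  if (null_model == "genome_frequency") {
    if (is.null(usage)) stop("genome_frequency null requires a usage table")
    cum_w <- syn_cum_weights(usage)
  }
  idx <- codons_to_int(seq)
  ok <- !is.na(idx)
  idx[ok] <- randomize_int(idx[ok], cum_w)
  out <- character(length(idx))
  out[ok] <- .CODONS[idx[ok]]
  if (any(!ok)) {
    orig <- substring(seq, 3 * (which(!ok)) - 2, 3 * which(!ok))
    out[!ok] <- orig
  }
  paste(out, collapse = "")
}

# entropy of one gene under the chosen estimator, from integer codons
estimate_H <- function(idx, estimator) {
  if (estimator == "codon_shannon") {
    entropy_int(idx)
  } else {
    lz76_complexity(paste(.CODONS[idx], collapse = ""))
  }
}

#' Differential-entropy CUB score per gene
#'
#' For each eligible gene, computes the observed entropy `H_obs`, the mean
#' and sd of the entropy of `n_random` random synonymous re-encodings
#' (`H_null_mean`, `H_null_sd`), and the differential entropy
#' `D = H_obs - H_null_mean`. More negative `D` means more codon usage bias.
#' Each gene's RNG stream is seeded by a stable hash of
#' `(master_seed, gene_id)`, so results are independent of gene order.
#'
#' @param cds A validated CDS tibble from [validate_cds()] or
#'   [read_cds_fasta()] (genes with `cub_eligible = FALSE` are excluded with
#'   a message), or any data frame with `gene_id` and `seq`.
#' @param n_random Number of random re-encodings per gene (default 20).
#' @param estimator `"codon_shannon"` (default; proportion-sensitive Shannon
#'   entropy over the gene's codon distribution) or `"lz76"`
#'   (order-sensitive Lempel-Ziv complexity).
#' @param null_model `"uniform_synonymous"` (default) or
#'   `"genome_frequency"` (see [synonymous_randomize()]).
#' @param usage Usage table for the genome-frequency null.
#' @param master_seed Integer master seed (default 1).
#' @return A tibble with columns `gene_id`, `n_codons`, `H_obs`,
#'   `H_null_mean`, `H_null_sd`, `D`, `estimator`, `seed`, carrying the
#'   scoring configuration in attribute `"cub_config"`.
#' @examples
#' cds <- validate_cds(data.frame(gene_id = "g1", seq = "AAAAAAAAA"))
#' cub_score(cds, n_random = 50, master_seed = 7)
#' @export
cub_score <- function(cds, n_random = 20,
                      estimator = c("codon_shannon", "lz76"),
                      null_model = c("uniform_synonymous", "genome_frequency"),
                      usage = NULL, master_seed = 1) {
  estimator <- match.arg(estimator)
  null_model <- match.arg(null_model)
  stopifnot(n_random >= 1)
  stopifnot(is.data.frame(cds), all(c("gene_id", "seq") %in% names(cds)))
  if ("cub_eligible" %in% names(cds)) {
    n_excl <- sum(!cds$cub_eligible)
    if (n_excl > 0) {
      message("excluding ", n_excl, " ineligible gene(s) from CUB scoring")
      cds <- dplyr::filter(cds, .data$cub_eligible)
    }
  }
  if (nrow(cds) == 0) stop("no eligible genes to score")
  cum_w <- NULL
  if (null_model == "genome_frequency") {
    if (is.null(usage)) stop("genome_frequency null requires a usage table")
    cum_w <- syn_cum_weights(usage)
  }

  score_one <- function(gid, seq) {
    idx <- usable_codons(seq)
    if (length(idx) == 0) {
      return(tibble::tibble(
        gene_id = gid, n_codons = 0L, H_obs = NA_real_,
        H_null_mean = NA_real_, H_null_sd = NA_real_, D = NA_real_,
        estimator = estimator, seed = NA_integer_
      ))
    }
    seed <- gene_seed(master_seed, gid)
    h_obs <- estimate_H(idx, estimator)
    h_null <- with_seed(seed, {
      vapply(seq_len(n_random), function(i) {
        estimate_H(randomize_int(idx, cum_w), estimator)
      }, numeric(1))
    })
    mu <- mean(h_null)
    tibble::tibble(
      gene_id = gid, n_codons = length(idx), H_obs = h_obs,
      H_null_mean = mu,
      H_null_sd = if (n_random > 1) stats::sd(h_null) else 0,
      D = h_obs - mu, estimator = estimator, seed = seed
    )
  }
  out <- dplyr::bind_rows(
    purrr::map2(as.character(cds$gene_id), as.character(cds$seq), score_one)
  )
  attr(out, "cub_config") <- list(
    n_random = n_random, estimator = estimator, null_model = null_model,
    master_seed = master_seed
  )
  out
}

#' Rank genes by codon usage bias
#'
#' Orders a CUB score table by ascending differential entropy `D` (most
#' negative, i.e. most biased, first = rank 1). Ties on `D` are broken by
#' `gene_id` and flagged.
#'
#' @param results A tibble from [cub_score()].
#' @return The table sorted with new columns `rank` and `tie`.
#' @export
rank_cub <- function(results) {
  stopifnot(all(c("gene_id", "D") %in% names(results)))
  if (anyDuplicated(results$gene_id)) {
    stop(
      "duplicate gene_id in results: ",
      paste(unique(results$gene_id[duplicated(results$gene_id)]), collapse = ", ")
    )
  }
  scored <- dplyr::filter(results, !is.na(.data$D))
  scored <- dplyr::arrange(scored, .data$D, .data$gene_id)
  if (nrow(scored) == 0) {
    return(dplyr::mutate(scored, rank = integer(0), tie = logical(0)))
  }
  dplyr::mutate(
    scored,
    rank = dplyr::row_number(),
    tie = duplicated(.data$D) | duplicated(.data$D, fromLast = TRUE)
  )
}
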