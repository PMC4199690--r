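# Synthetic genomes with known truth. The bias model is a preferred-codon
# mixture: each codon is the family's preferred synonym with probability
# beta + (1 - beta)/k and any fixed synonym with probability (1 - beta)/k,
# k the family degeneracy. beta = 0 reproduces the uniform synonymous null
# exactly; beta = 1 is maximal bias (one codon per amino acid, ENC = 20 on
# a fully covered gene).

#' Default preferred-codon map
#'
#' The arbitrary-but-fixed map used by the simulator: the lexicographically
#' first synonym of every amino acid. A realistic map derived from a usage
#' table via [preferred_codons()] can be supplied wherever this default is
#' accepted.
#'
#' @return Named character vector, amino acid -> codon.
#' @export
default_preferred_map <- function() {
  aas <- names(.AA_FOLD)
  stats::setNames(vapply(aas, function(a) .CODONS[.AA_SYN[[a]][1]], ""), aas)
}

# encode an amino-acid index vector (indices into names(.AA_FOLD)) as codons
encode_aa <- function(aa, beta, preferred_idx) {
  k <- .AA_FOLD[aa]
  fam_first <- vapply(names(.AA_FOLD), function(a) .AA_SYN[[a]][1], integer(1))
  take_pref <- stats::runif(length(aa)) < beta
  # uniform synonym draw for the rest
  r <- 1L + as.integer(floor(stats::runif(length(aa)) * k))
  r[r > k] <- k[r > k]
  fam_rows <- fam_first[aa]
  idx <- .SYN_MAT[cbind(fam_rows, r)]
  idx[take_pref] <- preferred_idx[aa[take_pref]]
  idx
}

#' Simulate one coding sequence with tunable codon bias
#'
#' Draws `n_codons` amino acids (uniformly over the 20 by default) and
#' encodes each with probability `beta` by the preferred codon and otherwise
#' by a uniformly random synonym, so the preferred codon's total probability
#' is `beta + (1 - beta)/k`. Optionally wraps the gene in an ATG start and a
#' TAA stop.
#'
#' @param n_codons Number of body codons (>= 1).
#' @param beta Bias strength in `[0, 1]`.
#' @param preferred Named amino-acid -> codon map (default
#'   [default_preferred_map()]).
#' @param aa_freq Optional amino-acid sampling weights (named, over the 20
#'   one-letter codes); uniform when `NULL`.
#' @param add_start_stop Prepend ATG and append TAA (default `TRUE`).
#' @return A nucleotide string.
#' @export
simulate_gene <- function(n_codons, beta, preferred = default_preferred_map(),
                          aa_freq = NULL, add_start_stop = TRUE) {
  stopifnot(n_codons >= 1)
  if (!is.numeric(beta) || beta < 0 || beta > 1) {
    stop("beta must lie in [0, 1]")
  }
  aas <- names(.AA_FOLD)
  w <- if (is.null(aa_freq)) rep(1, length(aas)) else unname(aa_freq[aas])
  aa <- sample(aas, n_codons, replace = TRUE, prob = w)
  preferred_idx <- vapply(preferred, .codon_index_of, integer(1))
  idx <- encode_aa(aa, beta, preferred_idx)
  body <- paste(.CODONS[idx], collapse = "")
  if (add_start_stop) paste0("ATG", body, "TAA") else body
}

# log-normal codon-count draw, clipped
draw_lengths <- function(n, len_median = 250, len_log_sd = 0.6,
                         len_range = c(50, 3000)) {
  len <- round(exp(stats::rnorm(n, mean = log(len_median), sd = len_log_sd)))
  pmin(pmax(len, len_range[1]), len_range[2])
}

#' Simulate a genome with planted codon bias and gene sets
#'
#' Generates `n_genes` coding sequences with log-normal lengths. One planted
#' gene-set term of `planted_size` genes receives bias `beta_high`; all
#' other genes receive `beta_low`. A further `n_terms - 1` decoy terms
#' sample genes at random. The three outputs are cross-consistent and fully
#' reproducible from `seed`.
#'
#' @param n_genes Number of genes (default 300).
#' @param beta_low Background bias (default 0.05).
#' @param beta_high Planted-term bias (default 0.6).
#' @param planted_size Planted term size (default 20, must be >= 5).
#' @param n_terms Total number of gene-set terms including the planted one
#'   (default 10).
#' @param term_size Size of each decoy term (default 20).
#' @param len_median,len_log_sd,len_range Codon-count distribution: median,
#'   log-scale sd, and clipping range (defaults 250, 0.6, `[50, 3000]`).
#' @param preferred Preferred-codon map (default
#'   [default_preferred_map()]).
#' @param add_start_stop Wrap genes in ATG/TAA (default `TRUE`).
#' @param seed Integer seed.
#' @return A list with `cds` (tibble `gene_id`, `species`, `seq`),
#'   `gene_sets` (tibble `term_id`, `name`, `genes`), and `truth` (tibble
#'   `gene_id`, `beta`, `length`, `planted`, `terms`).
#' @export
simulate_genome <- function(n_genes = 300, beta_low = 0.05, beta_high = 0.6,
                            planted_size = 20, n_terms = 10, term_size = 20,
                            len_median = 250, len_log_sd = 0.6,
                            len_range = c(50, 3000),
                            preferred = default_preferred_map(),
                            add_start_stop = TRUE, seed = 1) {
  stopifnot(planted_size >= 5, planted_size <= n_genes, term_size <= n_genes)
  with_seed(seed, {
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    len <- draw_lengths(n_genes, len_median, len_log_sd, len_range)
    planted_genes <- sort(sample(gene_id, planted_size))
    beta <- ifelse(gene_id %in% planted_genes, beta_high, beta_low)
    seqs <- vapply(seq_len(n_genes), function(i) {
      simulate_gene(len[i], beta[i], preferred = preferred,
                    add_start_stop = add_start_stop)
    }, character(1))

    terms <- list(planted = planted_genes)
    if (n_terms > 1) {
      for (j in seq_len(n_terms - 1)) {
        terms[[sprintf("decoy%02d", j)]] <- sort(sample(gene_id, term_size))
      }
    }
    gene_sets <- tibble::tibble(
      term_id = names(terms),
      name = ifelse(names(terms) == "planted",
                    "planted biased process", "random decoy process"),
      genes = unname(terms)
    )
    membership <- vapply(gene_id, function(g) {
      paste(names(terms)[vapply(terms, function(t) g %in% t, logical(1))],
            collapse = ";")
    }, character(1))
    list(
      cds = tibble::tibble(gene_id = gene_id, species = "simA", seq = seqs),
      gene_sets = gene_sets,
      truth = tibble::tibble(
        gene_id = gene_id, beta = beta, length = len,
        planted = gene_id %in% planted_genes, terms = unname(membership)
      )
    )
  })
}

#' Simulate an ortholog pair of genomes with a planted bias shift
#'
#' Both species carry identical amino-acid sequences per gene; only the
#' codon choices differ. Species A genes in `shifted_subset` (by default a
#' random subset of `n_shifted` genes) are encoded at bias
#' `beta + beta_shift` (clipped to 1); all other genes in both species use
#' `beta`. An identity ortholog map is returned.
#'
#' @param n_genes Number of genes per species (default 100).
#' @param beta Background bias (default 0.05).
#' @param beta_shift Extra bias planted in species A (default 0.6).
#' @param n_shifted Number of shifted genes (default 30).
#' @param len_median,len_log_sd,len_range Length distribution as in
#'   [simulate_genome()].
#' @param preferred Preferred-codon map.
#' @param add_start_stop Wrap genes in ATG/TAA (default `TRUE`).
#' @param seed Integer seed.
#' @return A list with `cds_a`, `cds_b`, `map` (tibble `gene_a`, `gene_b`),
#'   and `truth` (tibble `gene_id`, `beta_a`, `beta_b`, `length`,
#'   `shifted`).
#' @export
simulate_ortholog_pair <- function(n_genes = 100, beta = 0.05,
                                   beta_shift = 0.6, n_shifted = 30,
                                   len_median = 250, len_log_sd = 0.6,
                                   len_range = c(50, 3000),
                                   preferred = default_preferred_map(),
                                   add_start_stop = TRUE, seed = 1) {
  if (beta_shift < 0 || beta_shift > 1) stop("beta_shift must lie in [0, 1]")
  stopifnot(n_shifted <= n_genes)
  with_seed(seed, {
    gene_id <- sprintf("g%04d", seq_len(n_genes))
    len <- draw_lengths(n_genes, len_median, len_log_sd, len_range)
    shifted <- gene_id %in% sample(gene_id, n_shifted)
    beta_a <- ifelse(shifted, pmin(beta + beta_shift, 1), beta)
    beta_b <- rep(beta, n_genes)
    preferred_idx <- vapply(preferred, .codon_index_of, integer(1))
    aas <- names(.AA_FOLD)
    enc_pair <- function(i) {
      aa <- sample(aas, len[i], replace = TRUE)
      a <- paste(.CODONS[encode_aa(aa, beta_a[i], preferred_idx)], collapse = "")
      b <- paste(.CODONS[encode_aa(aa, beta_b[i], preferred_idx)], collapse = "")
      if (add_start_stop) {
        a <- paste0("ATG", a, "TAA"); b <- paste0("ATG", b, "TAA")
      }
      c(a, b)
    }
    seqs <- vapply(seq_len(n_genes), enc_pair, character(2))
    list(
      cds_a = tibble::tibble(gene_id = gene_id, species = "simA", seq = seqs[1, ]),
      cds_b = tibble::tibble(gene_id = gene_id, species = "simB", seq = seqs[2, ]),
      map = tibble::tibble(gene_a = gene_id, gene_b = gene_id),
      truth = tibble::tibble(
        gene_id = gene_id, beta_a = beta_a, beta_b = beta_b,
        length = len, shifted = shifted
      )
    )
  })
}

#' Plant a lesion into a gene and return the gapped alignment
#'
#' Builds an aligned reference/target pair in which the target carries one
#' planted lesion: a deletion or insertion of given length at a nucleotide
#' position, or a stop substitution at a codon index. The truth record
#' states the lesion class the detector should recover (`"frameshift"` for
#' indels with length not divisible by 3, `"premature_stop"` for stop
#' substitutions, `"none"` for in-frame indels).
#'
#' @param seq The intact reference CDS (including its terminal stop).
#' @param gene_id Gene identifier for the pair.
#' @param lesion `"deletion"`, `"insertion"`, or `"stop_substitution"`.
#' @param position 1-based reference nucleotide position for indels, codon
#'   index for stop substitutions.
#' @param length Indel length in nt (ignored for stop substitutions).
#' @return A list with `pair` (tibble from [aligned_pair()]) and `truth`
#'   (tibble `gene_id`, `lesion_type`, `ref_codon_index`, `detail`).
#' @export
simulate_lesion_pair <- function(seq, gene_id = "gene",
                                 lesion = c("deletion", "insertion", "stop_substitution"),
                                 position, length = 1) {
  lesion <- match.arg(lesion)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n %% 3 != 0) stop("reference length must be a multiple of 3")
  if (lesion == "stop_substitution") {
    n_codons <- n %/% 3
    if (position < 1 || position >= n_codons) {
      stop("stop substitution codon index out of range (must precede the terminal codon)")
    }
    tgt <- seq
    substr(tgt, 3 * position - 2, 3 * position) <- "TGA"
    pair <- aligned_pair(gene_id, seq, tgt)
    truth <- tibble::tibble(
      gene_id = gene_id, lesion_type = "premature_stop",
      ref_codon_index = as.integer(position), detail = "TGA"
    )
  } else if (lesion == "deletion") {
    if (position < 1 || position + length - 1 > n) stop("deletion out of range")
    tgt <- paste0(
      substr(seq, 1, position - 1),
      strrep("-", length),
      substr(seq, position + length, n)
    )
    pair <- aligned_pair(gene_id, seq, tgt)
    truth <- tibble::tibble(
      gene_id = gene_id,
      lesion_type = if (length %% 3 == 0) "none" else "frameshift",
      ref_codon_index = as.integer((position - 1) %/% 3 + 1),
      detail = paste0("del", length)
    )
  } else {
    if (position < 1 || position > n + 1) stop("insertion out of range")
    ins <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
    ref_aln <- paste0(
      substr(seq, 1, position - 1), strrep("-", length),
      substr(seq, position, n)
    )
    tgt_aln <- paste0(
      substr(seq, 1, position - 1), ins, substr(seq, position, n)
    )
    pair <- aligned_pair(gene_id, ref_aln, tgt_aln)
    truth <- tibble::tibble(
      gene_id = gene_id,
      lesion_type = if (length %% 3 == 0) "none" else "frameshift",
      ref_codon_index = as.integer((position - 1) %/% 3 + 1),
      detail = paste0("ins", length)
    )
  }
  list(pair = pair, truth = truth)
}
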