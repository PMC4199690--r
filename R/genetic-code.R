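# Standard genetic code bookkeeping shared by every statistic in the package.
#
# Codons are indexed 1..64 by treating bases as digits A=0, C=1, G=2, T=3,
# index = 16*b1 + 4*b2 + b3 + 1; because A<C<G<T alphabetically this index
# order is also lexicographic codon order, which is what the tie-break rules
# rely on.

.CODE_CODONS <- c(
  "TTT", "TTC", "TTA", "TTG", "TCT", "TCC", "TCA", "TCG", "TAT", "TAC", "TAA",
  "TAG", "TGT", "TGC", "TGA", "TGG", "CTT", "CTC", "CTA", "CTG", "CCT", "CCC",
  "CCA", "CCG", "CAT", "CAC", "CAA", "CAG", "CGT", "CGC", "CGA", "CGG", "ATT",
  "ATC", "ATA", "ATG", "ACT", "ACC", "ACA", "ACG", "AAT", "AAC", "AAA", "AAG",
  "AGT", "AGC", "AGA", "AGG", "GTT", "GTC", "GTA", "GTG", "GCT", "GCC", "GCA",
  "GCG", "GAT", "GAC", "GAA", "GAG", "GGT", "GGC", "GGA", "GGG"
)
.CODE_AA <- c(
  "F", "F", "L", "L", "S", "S", "S", "S", "Y", "Y", "*", "*", "C", "C", "*",
  "W", "L", "L", "L", "L", "P", "P", "P", "P", "H", "H", "Q", "Q", "R", "R",
  "R", "R", "I", "I", "I", "M", "T", "T", "T", "T", "N", "N", "K", "K", "S",
  "S", "R", "R", "V", "V", "V", "V", "A", "A", "A", "A", "D", "D", "E", "E",
  "G", "G", "G", "G"
)

.codon_index_of <- function(codon) {
  b <- match(strsplit(codon, "")[[1]], c("A", "C", "G", "T")) - 1L
  16L * b[1] + 4L * b[2] + b[3] + 1L
}

# 64 codons in package index (lexicographic) order
.CODONS <- local({
  out <- character(64)
  for (i in seq_along(.CODE_CODONS)) out[.codon_index_of(.CODE_CODONS[i])] <- .CODE_CODONS[i]
  out
})

# amino acid (one-letter, "*" for stop) per codon index
.CODON_AA <- local({
  out <- character(64)
  for (i in seq_along(.CODE_CODONS)) out[.codon_index_of(.CODE_CODONS[i])] <- .CODE_AA[i]
  out
})

.STOP_IDX <- which(.CODON_AA == "*")
.SENSE_IDX <- which(.CODON_AA != "*")

# synonym family per codon: list of codon indices (ascending, hence
# lexicographic), family size, and a padded matrix for vectorised draws
.AA_SYN <- local({
  split(seq_len(64L), .CODON_AA)
})

.N_SYN <- local({
  sizes <- lengths(.AA_SYN)
  unname(sizes[.CODON_AA])
})

.SYN_MAT <- local({
  m <- matrix(NA_integer_, nrow = 64, ncol = 6)
  for (i in seq_len(64)) {
    fam <- .AA_SYN[[.CODON_AA[i]]]
    m[i, seq_along(fam)] <- fam
  }
  m
})

# degeneracy class (synonymous family size) per amino acid; the 20 amino
# acids partition into 2 one-fold (M, W), 9 two-fold, 1 three-fold (I),
# 5 four-fold and 3 six-fold (L, S, R) families: 61 sense codons in total
.AA_FOLD <- local({
  aas <- setdiff(names(.AA_SYN), "*")
  stats::setNames(lengths(.AA_SYN[aas]), aas)
})

#' Standard genetic code as a tibble
#'
#' One row per codon of the standard nuclear code, with its amino acid
#' (one-letter, `*` for stop) and the size of its synonymous family
#' (degeneracy). Useful for joining onto codon-level results.
#'
#' @return A tibble with columns `codon`, `aa`, `fold`.
#' @examples
#' genetic_code_table()
#' @export
genetic_code_table <- function() {
  tibble::tibble(
    codon = .CODONS,
    aa = .CODON_AA,
    fold = .N_SYN
  )
}

# --- fast codon <-> integer conversions -------------------------------------

# Map a nucleotide string to integer codon indices; any codon containing a
# base other than A/C/G/T (e.g. N) becomes NA. length(seq) must be %% 3 == 0.
codons_to_int <- function(seq) {
  v <- utf8ToInt(seq)
  key <- integer(128)
  key[utf8ToInt("A")] <- 1L; key[utf8ToInt("C")] <- 2L
  key[utf8ToInt("G")] <- 3L; key[utf8ToInt("T")] <- 4L
  b <- key[v] - 1L          # 0..3, or -1 for anything else
  b[b < 0L] <- NA_integer_
  n <- length(b) %/% 3L
  if (n == 0L) return(integer(0))
  dim(b) <- c(3L, n)
  16L * b[1L, ] + 4L * b[2L, ] + b[3L, ] + 1L
}

int_to_codons <- function(idx) .CODONS[idx]

# translate integer codons to one-letter amino acids ("*" for stops)
translate_int <- function(idx) .CODON_AA[idx]

#' Translate a coding sequence
#'
#' Translates a nucleotide string under the standard genetic code. Codons
#' containing characters other than A/C/G/T translate to `X`.
#'
#' @param seq A nucleotide string whose length is a multiple of 3.
#' @return A one-letter amino-acid string (`*` marks stop codons).
#' @examples
#' translate_cds("ATGAAATAA")
#' @export
translate_cds <- function(seq) {
  if (nchar(seq) %% 3 != 0) {
    stop("sequence length ", nchar(seq), " is not a multiple of 3")
  }
  idx <- codons_to_int(seq)
  aa <- .CODON_AA[idx]
  aa[is.na(idx)] <- "X"
  paste(aa, collapse = "")
}
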