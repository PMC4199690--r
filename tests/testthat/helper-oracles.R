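# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: counts by string chopping, formulas evaluated
# from first principles, exhaustive enumeration where feasible.

STD_CODE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, function(cd) {
    as.character(
      Biostrings::translate(Biostrings::DNAString(cd), no.init.codon = TRUE)
    )
  }, "")
  stats::setNames(aa, codons)
})

chop_codons <- function(seq) {
  n <- nchar(seq) %/% 3
  substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

# Shannon entropy in bits computed straight from a codon string
oracle_entropy <- function(seq) {
  cods <- chop_codons(seq)
  cods <- cods[STD_CODE[cods] != "*" & !is.na(STD_CODE[cods])]
  p <- table(cods) / length(cods)
  -sum(p * log2(p))
}

# Wright's ENC recomputed from first principles (independent arithmetic)
oracle_enc <- function(seq) {
  cods <- chop_codons(seq)
  aa <- STD_CODE[cods]
  cods <- cods[aa != "*"]; aa <- aa[aa != "*"]
  fold <- table(STD_CODE[STD_CODE != "*"])
  f_hat <- list()
  for (a in names(fold)) {
    x <- table(factor(cods[aa == a], levels = names(STD_CODE)[STD_CODE == a]))
    n <- sum(x)
    if (n >= 2) {
      p <- as.numeric(x) / n
      f_hat[[a]] <- c(fold = unname(fold[a]), f = (n * sum(p^2) - 1) / (n - 1))
    }
  }
  fb <- sapply(c(2, 3, 4, 6), function(k) {
    fs <- vapply(f_hat, function(z) if (z["fold"] == k) z["f"] else NA_real_,
                 numeric(1))
    mean(fs, na.rm = TRUE)
  })
  names(fb) <- c("2", "3", "4", "6")
  if (is.nan(fb["3"])) fb["3"] <- mean(c(fb["2"], fb["4"]))
  enc <- 2 + 9 / fb[["2"]] + 1 / fb[["3"]] + 5 / fb[["4"]] + 3 / fb[["6"]]
  min(max(enc, 20), 61)
}

# Exact mean null entropy by enumerating every synonymous re-encoding of a
# short gene (feasible for <= ~10 degenerate positions)
oracle_null_mean_entropy <- function(seq) {
  cods <- chop_codons(seq)
  cods <- cods[STD_CODE[cods] != "*"]
  syn <- lapply(cods, function(cd) names(STD_CODE)[STD_CODE == STD_CODE[cd]])
  grid <- expand.grid(syn, stringsAsFactors = FALSE)
  hs <- apply(grid, 1, function(row) oracle_entropy(paste(row, collapse = "")))
  mean(hs)
}

# Brute-force exact mHG p-value: enumerate all placements of B term genes
# among N ranked slots, score each by its minimal hypergeometric tail
oracle_mhg_p <- function(score, N, B) {
  combs <- utils::combn(N, B)
  mins <- apply(combs, 2, function(pos) {
    lam <- seq_len(N) %in% pos
    b <- cumsum(lam)
    min(stats::phyper(b - 1, B, N - B, seq_len(N), lower.tail = FALSE))
  })
  mean(mins <= score * (1 + 1e-9))
}

# minimal-tail score of one concrete placement (positions of term genes)
oracle_mhg_score <- function(pos, N, B) {
  lam <- seq_len(N) %in% pos
  b <- cumsum(lam)
  min(stats::phyper(b - 1, B, N - B, seq_len(N), lower.tail = FALSE))
}

# a CDS using exactly one codon per amino acid, each amino acid 3 times
one_codon_per_aa_cds <- function() {
  aas <- sort(unique(STD_CODE[STD_CODE != "*"]))
  cods <- vapply(aas, function(a) sort(names(STD_CODE)[STD_CODE == a])[1], "")
  paste(rep(cods, each = 3), collapse = "")
}

# a CDS with every sense codon exactly 4 times
all_codons_equal_cds <- function() {
  paste(rep(sort(names(STD_CODE)[STD_CODE != "*"]), each = 4), collapse = "")
}
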