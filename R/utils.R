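# shared internal helpers

#' @importFrom rlang .data
#' @importFrom tibble tibble
NULL

# Deterministic 31-bit hash of (master_seed, gene_id), used to derive a
# per-gene RNG seed so per-gene results do not depend on the order genes are
# processed in. Products stay below 2^53 so double arithmetic is exact.
gene_seed <- function(master_seed, gene_id) {
  h <- as.numeric(master_seed) %% 2147483647
  for (b in utf8ToInt(gene_id)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

# reverse complement of a plain nucleotide string (keeps N)
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}
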