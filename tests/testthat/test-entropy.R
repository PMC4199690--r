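test_that("codon entropy matches hand-computed values", {
  expect_equal(codon_entropy("ATGATGATG"), 0)
  expect_equal(codon_entropy("GCTGCC"), 1)
  # AAA x2, AAG x1: -(2/3 log2 2/3 + 1/3 log2 1/3)
  expect_equal(codon_entropy("AAAAAGAAA"), 0.9182958, tolerance = 1e-6)
  expect_equal(codon_entropy("AAAAAGAAA"), oracle_entropy("AAAAAGAAA"))
  expect_error(codon_entropy("NNN"), "usable")
  expect_error(codon_entropy("ATGA"), "multiple of 3")
})

test_that("entropy estimator agrees with the independent oracle on random genes", {
  set.seed(21)
  for (i in 1:10) {
    s <- simulate_gene(sample(10:60, 1), runif(1), add_start_stop = FALSE)
    expect_equal(codon_entropy(s), oracle_entropy(s), tolerance = 1e-12)
  }
})

test_that("LZ76 complexity is deterministic and ranks regularity correctly", {
  s <- "ACGTACGGTACGTTACG"
  expect_identical(lz76_complexity(s), lz76_complexity(s))
  expect_error(lz76_complexity("ACG"), "short")

  # homopolymer below random sequences of the same length (median over draws)
  set.seed(9)
  rand <- replicate(100, lz76_complexity(
    paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = "")
  ))
  expect_lt(lz76_complexity(strrep("A", 12)), median(rand))

  # periodic repeat below its own random shuffles, in expectation
  per <- strrep("ACGT", 30)
  shuf <- replicate(50, {
    paste(sample(strsplit(per, "")[[1]]), collapse = "")
  })
  expect_lt(lz76_complexity(per), median(vapply(shuf, lz76_complexity, 1)))
})

test_that("synonymous randomization preserves the protein codon-for-codon", {
  set.seed(3)
  for (i in 1:10) {
    s <- simulate_gene(sample(5:40, 1), runif(1), add_start_stop = FALSE)
    r <- synonymous_randomize(s)
    expect_equal(translate_cds(r), translate_cds(s))
  }
  # no synonymous freedom: output identical to input
  expect_equal(synonymous_randomize("ATGTGGATG"), "ATGTGGATG")
})

test_that("uniform null draws Lys codons as a fair coin", {
  set.seed(41)
  draws <- replicate(10000, synonymous_randomize("AAA"))
  n_aaa <- sum(draws == "AAA")
  expect_true(all(draws %in% c("AAA", "AAG")))
  # binomial(10000, 1/2): 3 sigma = 150
  expect_lt(abs(n_aaa - 5000), 150)
})

test_that("genome-frequency null tracks the supplied usage weights", {
  usage <- genetic_code_table()
  usage$count <- 0
  usage$count[usage$codon == "AAA"] <- 900
  usage$count[usage$codon == "AAG"] <- 100
  usage$per_thousand <- 1000 * usage$count / sum(usage$count)
  set.seed(42)
  draws <- replicate(3000, synonymous_randomize("AAA", "genome_frequency", usage))
  # binomial(3000, 0.9): 3 sigma ~ 49
  expect_lt(abs(sum(draws == "AAA") - 2700), 50)
  expect_error(synonymous_randomize("AAA", "genome_frequency"), "usage")
})

test_that("differential entropy is zero without synonymous freedom", {
  cds <- validate_cds(data.frame(gene_id = "m", seq = "ATGATGATG"))
  r <- cub_score(cds, n_random = 5)
  expect_equal(r$D, 0)
  expect_equal(r$H_null_sd, 0)
})

test_that("Monte-Carlo null mean matches exhaustive enumeration (small genes)", {
  genes <- c(kys = "AAAAAAAAA", mix = "AAAGAATTTATG", leu = "CTTCTcCTA")
  for (g in names(genes)) {
    s <- toupper(genes[[g]])
    exact <- oracle_null_mean_entropy(s)
    cds <- validate_cds(data.frame(gene_id = g, seq = s))
    r <- cub_score(cds, n_random = 2000, master_seed = 17)
    se <- r$H_null_sd / sqrt(2000)
    expect_lt(abs(r$H_null_mean - exact), 3 * se + 1e-12)
  }
})

test_that("per-gene seeding makes results order-independent and reproducible", {
  set.seed(77)
  cds <- validate_cds(data.frame(
    gene_id = paste0("g", 1:6),
    seq = replicate(6, simulate_gene(40, 0.2))
  ))
  a <- cub_score(cds, master_seed = 5)
  b <- cub_score(cds[sample(6), ], master_seed = 5)
  expect_equal(
    dplyr::arrange(a, gene_id), dplyr::arrange(b, gene_id),
    ignore_attr = TRUE
  )
  c2 <- cub_score(cds, master_seed = 6)
  expect_false(isTRUE(all.equal(a$D, dplyr::arrange(c2, match(gene_id, a$gene_id))$D)))
})

test_that("ranking sorts ascending D with lexicographic tie-break", {
  res <- tibble::tibble(
    gene_id = c("gB", "gC", "gA", "gD"),
    D = c(0, -5, -2, 0),
    estimator = "codon_shannon"
  )
  rk <- rank_cub(res)
  expect_equal(rk$gene_id, c("gC", "gA", "gB", "gD"))
  expect_equal(rk$rank, 1:4)
  expect_true(all(rk$tie[rk$gene_id %in% c("gB", "gD")]))
  expect_false(any(rk$tie[rk$gene_id %in% c("gC", "gA")]))
  expect_error(rank_cub(dplyr::bind_rows(res, res[1, ])), "duplicate")
  empty <- rank_cub(res[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("ineligible genes are excluded from scoring with a count", {
  cds <- validate_cds(data.frame(
    gene_id = c("ok", "bad"),
    seq = c("AAAAAGCTT", "ATGTAACTT")
  ))
  expect_message(r <- cub_score(cds, n_random = 3), "1 ineligible")
  expect_equal(r$gene_id, "ok")
})
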