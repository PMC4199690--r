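test_that("duplicate removal keeps the best-ranked occurrence", {
  expect_message(out <- dedup_ranked(c("A", "B", "A", "C")), "1 duplicate")
  expect_equal(out, c("A", "B", "C"))
  expect_equal(dedup_ranked(c("A", "B", "C")), c("A", "B", "C"))
  expect_message(one <- dedup_ranked(rep("Z", 5)), "4 duplicate")
  expect_equal(one, "Z")
})

test_that("hypergeometric tail matches enumeration and handles edge cases", {
  expect_equal(hypergeom_tail(2, 4, 2, 2), 1 / 6)
  expect_equal(hypergeom_tail(0, 10, 3, 4), 1)
  expect_equal(hypergeom_tail(3, 3, 3, 3), 1)
  expect_error(hypergeom_tail(5, 4, 2, 2), "<=")
})

test_that("mHG scan finds the minimal tail and optimal threshold", {
  m <- mhg(c("a", "b", "c", "d"), c("a", "b"))
  expect_equal(m$mhg_score, 1 / 6)
  expect_equal(m$n_star, 2L)
  expect_equal(m$b_star, 2L)

  all_in <- mhg(c("a", "b"), c("a", "b"))
  expect_equal(all_in$mhg_score, 1)

  bottom <- mhg(c("a", "b", "c", "d"), c("d"))
  expect_equal(bottom$mhg_score, 1) # no prefix enriches

  expect_error(mhg(c("a", "a"), "a"), "duplicates")
  expect_error(mhg(c("a", "b"), "zzz"), "empty")
})

test_that("mHG score never exceeds the tail at any single threshold", {
  set.seed(6)
  for (i in 1:20) {
    N <- sample(10:40, 1)
    ranked <- paste0("g", sample(N))
    term <- sample(ranked, sample(3:8, 1))
    m <- mhg(ranked, term)
    b <- cumsum(ranked %in% term)
    tails <- stats::phyper(b - 1, m$B, m$N - m$B, seq_len(m$N), lower.tail = FALSE)
    expect_true(all(m$mhg_score <= tails + 1e-15))
  }
})

test_that("exact mHG p equals the exhaustive permutation fraction (N <= 8)", {
  for (N in 3:8) {
    for (B in 1:(N - 1)) {
      combs <- utils::combn(N, B)
      for (j in seq_len(ncol(combs))) {
        s <- oracle_mhg_score(combs[, j], N, B)
        expect_equal(
          mhg_pvalue(s, N, B), oracle_mhg_p(s, N, B),
          tolerance = 1e-10,
          info = sprintf("N=%d B=%d placement=%d", N, B, j)
        )
      }
    }
  }
})

test_that("mHG p respects its analytic bounds", {
  expect_equal(mhg_pvalue(1, 30, 5), 1)
  expect_equal(mhg_pvalue(0.2, 10, 10), 1) # single labeling
  set.seed(12)
  for (i in 1:20) {
    N <- sample(10:60, 1); B <- sample(2:6, 1)
    ranked <- paste0("g", sample(N))
    m <- mhg(ranked, sample(ranked, B))
    p <- mhg_pvalue(m$mhg_score, N, B)
    expect_gt(p, 0)
    expect_lte(p, min(1, N * m$mhg_score) + 1e-12)
    expect_gte(p, m$mhg_score - 1e-12)
  }
})

test_that("BH q-values reproduce the step-up adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(50)
  expect_gte(min(bh_fdr(p) - p), 0)
})

test_that("GMT round-trip and enrichment table structure", {
  tmp <- withr::local_tempfile(fileext = ".gmt")
  sets <- tibble::tibble(
    term_id = c("T1", "T2"),
    name = c("first process", "second process"),
    genes = list(c("a", "b", "c"), c("c", "d", "e", "f"))
  )
  write_gmt(sets, tmp)
  back <- read_gmt(tmp)
  expect_equal(back, sets)

  ranked <- letters[1:10]
  res <- suppressMessages(enrich_ranked(ranked, sets, min_size = 2))
  expect_setequal(res$term_id, c("T1", "T2"))
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(res$b_star <= pmin(res$n_star, res$B)))
  # T1 sits on top of the ranking, T2 lower
  expect_equal(res$term_id[1], "T1")
  lead <- strsplit(res$leading_genes[res$term_id == "T1"], ";")[[1]]
  expect_equal(length(lead), res$b_star[res$term_id == "T1"])
})

test_that("universe is restricted to annotated genes with a logged count", {
  sets <- list(T1 = c("a", "b"))
  expect_message(
    res <- enrich_ranked(c("a", "b", "x", "y"), sets, min_size = 2),
    "2 unannotated"
  )
  expect_equal(res$N, 2)
  expect_error(
    suppressMessages(enrich_ranked(c("x", "y"), sets)),
    "no ranked genes"
  )
})
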