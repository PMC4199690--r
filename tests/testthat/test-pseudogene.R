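# a clean 20-codon reference gene with terminal stop, no internal stops
ref_gene <- function(seed = 1) {
  withr::with_seed(seed, simulate_gene(18, 0.1, add_start_stop = TRUE))
}

test_that("aligned pair invariants are enforced", {
  expect_error(aligned_pair("g", "ATG", "ATGAAA"), "equal")
  expect_error(aligned_pair("g", "AT-G", "AT-G"), "gap-vs-gap")
  expect_error(aligned_pair("g", "ATGA", "ATGA"), "multiple of 3")
})

test_that("identical target yields zero lesion calls", {
  s <- ref_gene()
  calls <- detect_lesions(aligned_pair("g", s, s))
  expect_equal(nrow(calls), 0)
})

test_that("non-triplet deletions are frameshifts, triplet deletions are not", {
  s <- ref_gene()
  del31 <- simulate_lesion_pair(s, "g", "deletion", position = 10, length = 31)
  calls <- detect_lesions(del31$pair)
  fs <- dplyr::filter(calls, lesion_type == "frameshift")
  expect_equal(nrow(fs), 1)
  expect_equal(fs$detail, "del31")
  expect_equal(fs$ref_codon_index, del31$truth$ref_codon_index)

  del3 <- simulate_lesion_pair(s, "g", "deletion", position = 10, length = 3)
  expect_equal(nrow(detect_lesions(del3$pair)), 0)
})

test_that("stop substitutions are called as premature stops, not frameshifts", {
  s <- ref_gene()
  les <- simulate_lesion_pair(s, "g", "stop_substitution", position = 7)
  calls <- detect_lesions(les$pair)
  expect_equal(calls$lesion_type, "premature_stop")
  expect_equal(calls$ref_codon_index, 7L)
  expect_equal(calls$detail, "TGA")
})

test_that("two nearby planted stops give two calls in positional order", {
  s <- ref_gene()
  tgt <- s
  substr(tgt, 3 * 5 - 2, 3 * 5) <- "TAA"
  substr(tgt, 3 * 8 - 2, 3 * 8) <- "TAG"
  calls <- detect_lesions(aligned_pair("g", s, tgt))
  expect_equal(calls$lesion_type, rep("premature_stop", 2))
  expect_equal(calls$ref_codon_index, c(5L, 8L))
})

test_that("the reference terminal stop is never called premature", {
  s <- ref_gene()
  calls <- detect_lesions(aligned_pair("g", s, s))
  expect_false(any(calls$lesion_type == "premature_stop"))
})

test_that("calls are invariant under equal flanking alignment padding", {
  s <- ref_gene()
  les <- simulate_lesion_pair(s, "g", "deletion", position = 8, length = 2)
  base <- detect_lesions(les$pair)
  # pad both sequences with matched flanking codons (frame preserved)
  pad <- aligned_pair(
    "g",
    paste0("GCACCA", les$pair$ref_seq),
    paste0("GCACCA", les$pair$target_seq)
  )
  padded <- detect_lesions(pad)
  expect_equal(padded$lesion_type, base$lesion_type)
  expect_equal(padded$detail, base$detail)
  expect_equal(padded$ref_codon_index, base$ref_codon_index + 2L)
})

test_that("planted lesions are recovered exactly across random cases", {
  set.seed(19)
  n_ok <- 0L
  for (i in 1:100) {
    s <- simulate_gene(sample(30:80, 1), 0.1)
    n <- nchar(s)
    type <- sample(c("deletion", "insertion", "stop_substitution"), 1)
    if (type == "stop_substitution") {
      les <- simulate_lesion_pair(s, "g", type,
                                  position = sample(2:(n %/% 3 - 1), 1))
    } else {
      len <- sample(c(1, 2, 4, 31), 1) # all non-triplet: frameshifts
      les <- simulate_lesion_pair(s, "g", type,
                                  position = sample(4:(n - 40), 1), length = len)
    }
    calls <- detect_lesions(les$pair)
    hit <- any(
      calls$lesion_type == les$truth$lesion_type &
        calls$ref_codon_index == les$truth$ref_codon_index
    )
    n_ok <- n_ok + hit
  }
  expect_equal(n_ok, 100L)
})

test_that("self-alignment filter flags genes with artifact-bearing references", {
  s <- ref_gene()
  les <- simulate_lesion_pair(s, "gX", "stop_substitution", position = 4)
  calls <- detect_lesions(les$pair)

  clean_self <- detect_lesions(aligned_pair("gX", s, s))
  expect_equal(filter_self_alignment(calls, clean_self)$filters_failed, "")

  dirty_self <- calls # pretend the reference self-alignment shows the lesion
  flagged <- filter_self_alignment(calls, dirty_self)
  expect_equal(flagged$filters_failed, "self_alignment")
  empty <- detect_lesions(aligned_pair("gX", s, s))
  expect_equal(nrow(filter_self_alignment(empty, dirty_self)), 0)
})

test_that("splice-adjacency filter uses the nt window around boundaries", {
  s <- ref_gene()
  les <- simulate_lesion_pair(s, "g", "stop_substitution", position = 10)
  calls <- detect_lesions(les$pair) # lesion at nt 28-30
  near <- filter_splice_adjacent(calls, boundaries = c(24), window = 10)
  expect_match(near$filters_failed, "splice_adjacent")
  far <- filter_splice_adjacent(calls, boundaries = c(3), window = 10)
  expect_equal(far$filters_failed, "")
  expect_warning(filter_splice_adjacent(calls, NULL), "skipped")
  expect_error(filter_splice_adjacent(calls, c(30, 10)), "sorted")
})

test_that("coverage filter applies depth and heterozygosity rules", {
  s <- ref_gene()
  les <- simulate_lesion_pair(s, "g", "stop_substitution", position = 6)
  calls <- detect_lesions(les$pair) # lesion codon = nt 16-18
  cov <- tibble::tibble(
    position = 16:18, depth = c(40, 40, 40), alt_fraction = c(1, 1, 1)
  )
  expect_equal(filter_coverage(calls, cov)$filters_failed, "")

  low <- dplyr::mutate(cov, depth = 2)
  expect_match(filter_coverage(calls, low)$filters_failed, "low_coverage")

  het <- dplyr::mutate(cov, alt_fraction = c(1, 0.48, 1))
  expect_match(filter_coverage(calls, het)$filters_failed, "heterozygous")

  absent <- tibble::tibble(position = 999, depth = 50, alt_fraction = 1)
  expect_message(
    miss <- filter_coverage(calls, absent),
    "absent from coverage"
  )
  expect_match(miss$filters_failed, "low_coverage")
})

test_that("report pools calls per gene and reproduces lesion context", {
  s <- ref_gene()
  les <- simulate_lesion_pair(s, "gA", "stop_substitution", position = 7)
  calls <- detect_lesions(les$pair)
  rep1 <- pseudogene_report(calls)
  expect_equal(rep1$verdict, "candidate_pseudogene")
  expect_match(rep1$lesions, "premature_stop@7")

  flagged <- filter_self_alignment(calls, calls)
  rep2 <- pseudogene_report(flagged)
  expect_equal(rep2$verdict, "filtered")

  ctx <- lesion_context(les$pair, calls[1, ], width = 6)
  expect_equal(nchar(ctx$ref), nchar(ctx$target))
  expect_match(ctx$target, "TGA")
})

test_that("aligned FASTA pairs round-trip through files", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  s <- ref_gene()
  les <- simulate_lesion_pair(s, "gF", "deletion", position = 10, length = 2)
  writeLines(c(
    ">ref", les$pair$ref_seq,
    ">gF candidate", les$pair$target_seq
  ), tmp)
  pair <- read_aligned_pair(tmp)
  expect_equal(pair$gene_id, "gF")
  expect_equal(detect_lesions(pair)$detail, "del2")
})
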