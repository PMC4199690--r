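test_that("bias strength controls the preferred-codon draw law", {
  # at beta = 1 every amino acid uses its preferred codon: ENC hits 20
  set.seed(1)
  s <- simulate_gene(500, 1, add_start_stop = FALSE)
  idx_pref <- unname(vapply(default_preferred_map(), identity, ""))
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  expect_true(all(cods %in% idx_pref))
  expect_equal(enc_score(data.frame(gene_id = "g", seq = s))$enc, 20)

  expect_error(simulate_gene(10, 1.2), "beta")
  expect_error(simulate_gene(0, 0.5))
})

test_that("translation length equals the requested codon count", {
  set.seed(2)
  s0 <- simulate_gene(40, 0.3, add_start_stop = FALSE)
  expect_equal(nchar(s0) / 3, 40)
  s1 <- simulate_gene(40, 0.3, add_start_stop = TRUE)
  expect_equal(nchar(s1) / 3, 42)
  expect_equal(substr(s1, 1, 3), "ATG")
  expect_equal(substr(s1, nchar(s1) - 2, nchar(s1)), "TAA")
  aa <- translate_cds(s1)
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1))) # no internal stop
})

test_that("preferred-codon frequency converges to beta + (1 - beta)/k", {
  set.seed(30)
  beta <- 0.4
  s <- simulate_gene(10000, beta, add_start_stop = FALSE)
  cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  aa <- strsplit(translate_cds(s), "")[[1]]
  pref <- default_preferred_map()
  code <- genetic_code_table()
  for (k in c(2, 4, 6)) {
    fam_aas <- code$aa[code$fold == k & code$aa != "*"]
    sel <- aa %in% fam_aas
    got <- mean(cods[sel] == pref[aa[sel]])
    expect_lt(abs(got - (beta + (1 - beta) / k)), 0.02)
  }
})

test_that("genome simulation is deterministic and cross-consistent", {
  a <- simulate_genome(n_genes = 60, planted_size = 8, n_terms = 4, seed = 7)
  b <- simulate_genome(n_genes = 60, planted_size = 8, n_terms = 4, seed = 7)
  expect_identical(a, b)
  c2 <- simulate_genome(n_genes = 60, planted_size = 8, n_terms = 4, seed = 8)
  expect_false(identical(a$cds$seq, c2$cds$seq))

  # GMT references only emitted genes; truth matches generation parameters
  expect_true(all(unlist(a$gene_sets$genes) %in% a$cds$gene_id))
  expect_equal(nrow(a$truth), 60)
  expect_equal(sum(a$truth$planted), 8)
  expect_setequal(
    a$truth$gene_id[a$truth$planted],
    a$gene_sets$genes[[which(a$gene_sets$term_id == "planted")]]
  )
  expect_true(all(a$truth$beta[a$truth$planted] == 0.6))
  expect_true(all(a$truth$beta[!a$truth$planted] == 0.05))
  expect_error(simulate_genome(n_genes = 10, planted_size = 20), "planted_size")
})

test_that("simulated FASTA validates under the strict policy", {
  sim <- simulate_genome(n_genes = 30, planted_size = 6, n_terms = 3, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_cds_fasta(sim$cds, tmp)
  cds <- read_cds_fasta(tmp, policy = "strict")
  expect_equal(nrow(cds), 30)
  expect_true(all(cds$cub_eligible))
  expect_true(all(cds$n_codons == sim$truth$length + 1)) # body + ATG
})

test_that("ortholog-pair genomes share amino-acid sequences exactly", {
  sim <- simulate_ortholog_pair(n_genes = 20, beta_shift = 0.5,
                                n_shifted = 6, seed = 5)
  expect_equal(
    vapply(sim$cds_a$seq, translate_cds, "", USE.NAMES = FALSE),
    vapply(sim$cds_b$seq, translate_cds, "", USE.NAMES = FALSE)
  )
  expect_equal(sum(sim$truth$shifted), 6)
  expect_equal(sim$truth$beta_a[sim$truth$shifted], rep(0.55, 6))
  expect_equal(sim$map$gene_a, sim$map$gene_b)
  expect_error(simulate_ortholog_pair(beta_shift = 2), "beta_shift")
})

test_that("lesion truth records the planted class", {
  set.seed(6)
  s <- simulate_gene(30, 0.1)
  del <- simulate_lesion_pair(s, "g", "deletion", position = 10, length = 3)
  expect_equal(del$truth$lesion_type, "none")
  fs <- simulate_lesion_pair(s, "g", "deletion", position = 10, length = 31)
  expect_equal(fs$truth$lesion_type, "frameshift")
  st <- simulate_lesion_pair(s, "g", "stop_substitution", position = 9)
  expect_equal(st$truth$lesion_type, "premature_stop")
  expect_error(simulate_lesion_pair(s, "g", "deletion", position = 1000, length = 2),
               "range")
})
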