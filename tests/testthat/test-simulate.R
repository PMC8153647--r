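test_that("genome generation is byte-deterministic and respects density 0", {
  g1 <- make_genome(7, n_chromosomes = 1L, chrom_length = 15000L)
  g2 <- make_genome(7, n_chromosomes = 1L, chrom_length = 15000L)
  expect_identical(g1$genome$seqs, g2$genome$seqs)
  expect_identical(g1$annotation$exons, g2$annotation$exons)
  expect_error(make_genome(1, chrom_length = 5000L), "10 kb")
  g0 <- make_genome(7, n_chromosomes = 1L, chrom_length = 12000L, gene_density = 0)
  expect_equal(nrow(g0$annotation$genes), 0L)
})

test_that("generated introns carry strand-appropriate splice dinucleotides", {
  gen <- make_genome(23, n_chromosomes = 1L, chrom_length = 30000L)
  intr <- gen$annotation$introns
  expect_gt(nrow(intr), 0)
  for (i in seq_len(nrow(intr))) {
    don <- genome_subseq(gen$genome, intr$chrom[i], intr$start[i], intr$start[i] + 2L)
    acc <- genome_subseq(gen$genome, intr$chrom[i], intr$end[i] - 2L, intr$end[i])
    if (intr$strand[i] == "+") expect_equal(c(don, acc), c("GT", "AG"))
    else expect_equal(c(don, acc), c("CT", "AC"))
  }
})

test_that("planted circles satisfy the validators they were designed against", {
  truth <- toy_truth()
  ci <- truth$circles
  expect_equal(nrow(ci), 30L)
  fp <- feature_params()
  for (i in seq_len(nrow(ci))) {
    expect_equal(classify_bf(truth$annotation, ci$chrom[i], ci$strand[i],
                             ci$A[i], ci$D[i]), ci$class[i])
    expect_equal(structural_category(truth$annotation, ci$chrom[i],
                                     ci$A[i], ci$D[i])$structure, ci$structure[i])
    expect_equal(splice_signal(truth$genome, ci$chrom[i], ci$strand[i],
                               ci$A[i], ci$D[i], fp), ci$signal[i])
    expect_equal(detect_shs(truth$genome, ci$chrom[i], ci$A[i], ci$D[i])$shs_length,
                 ci$shs_length[i])
  }
  # canonical circles carry the signal, interior-by-design circles do not
  expect_true(all(ci$signal[ci$class == "canonical"]))
  expect_false(any(ci$signal[ci$class == "complete_icirc"]))
  # planted SHS and flank repeats realized as designed
  expect_true(any(ci$shs_length >= 2))
  expect_true(any(ci$flank_repeat_length >= 12))
  # infeasible design errors out
  nointron <- make_genome(3, n_chromosomes = 1L, chrom_length = 12000L,
                          gene_density = 0)
  expect_error(plant_circles(nointron$genome, nointron$annotation,
                             data.frame(class = "complete_icirc",
                                        structure = "single_intron"), 1),
               "no intron")
})

test_that("read simulation is deterministic, stranded and provenance-complete", {
  truth <- toy_truth()
  s1 <- simulate_reads(truth, depth = 3, linear_pairs = 50, seed = 5)
  s2 <- simulate_reads(truth, depth = 3, linear_pairs = 50, seed = 5)
  expect_identical(s1$reads1, s2$reads1)
  expect_identical(s1$reads2, s2$reads2)
  expect_identical(s1$provenance, s2$provenance)
  expect_equal(nrow(s1$provenance), length(s1$reads1))
  expect_equal(sum(s1$provenance$junction), 3L * nrow(truth$circles))
  expect_true(all(nchar(c(s1$reads1, s1$reads2)) == 100L))
  expect_warning(simulate_reads(truth, depth = 0, linear_pairs = 10, seed = 6),
                 "linear-only")
})

test_that("FASTQ writing round-trips reads, ids and gzip compression", {
  truth <- toy_truth()
  sim <- simulate_reads(truth, depth = 2, interior_pairs = 0, linear_pairs = 20,
                        seed = 7)
  p1 <- withr::local_tempfile(fileext = "_1.fastq.gz")
  p2 <- withr::local_tempfile(fileext = "_2.fastq.gz")
  write_fastq_pair(sim, p1, p2)
  back <- read_fastq_pair(p1, p2)
  expect_identical(back$reads1, sim$reads1)
  expect_identical(back$reads2, sim$reads2)
  expect_identical(back$ids, sim$ids)
})

test_that("substitution errors appear at the configured rate", {
  truth <- toy_truth()
  clean <- simulate_reads(truth, depth = 5, interior_pairs = 0, linear_pairs = 200,
                          seed = 8, error_rate = 0)
  noisy <- simulate_reads(truth, depth = 5, interior_pairs = 0, linear_pairs = 200,
                          seed = 8, error_rate = 0.01)
  expect_identical(nchar(noisy$reads1), nchar(clean$reads1))
  diff_frac <- mean(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, clean$reads1, noisy$reads1)) / 100
  expect_gt(diff_frac, 0.004)
  expect_lt(diff_frac, 0.02)
})

test_that("expression simulation is deterministic with sane null and DE structure", {
  e1 <- simulate_expression(n_circ = 30, seed = 3)
  e2 <- simulate_expression(n_circ = 30, seed = 3)
  expect_identical(e1$expr$counts, e2$expr$counts)
  null <- simulate_expression(n_circ = 30, frac_de = 0, seed = 4)
  expect_true(all(!null$truth$de))
  fc1 <- simulate_expression(n_circ = 30, frac_de = 0.5, fold_change = 1, seed = 5)
  de <- differential_expression(fc1$expr, "A", "B")
  expect_lte(mean(de$significant), 0.15)  # fold change 1: indistinguishable
})

test_that("ceRNA simulation honors the correlation-strength contract", {
  c1 <- simulate_cerna(seed = 10)
  c2 <- simulate_cerna(seed = 10)
  expect_identical(c1$gene_expr, c2$gene_expr)
  perfect <- simulate_cerna(strength = 1, n_assoc = 5, seed = 11)
  for (g in perfect$truth$gene_id[perfect$truth$associated])
    expect_equal(spearman_cor(perfect$circ_expr, perfect$gene_expr[g, ])$rho, 1)
  expect_error(simulate_cerna(strength = 2), "strength")
})
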