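fake_split <- function(id, chrom = "c1", strand = "+", A = 100L, D = 500L) {
  data.frame(read_id = id, chrom = chrom, strand = strand, A = A, D = D,
             split_offset = 50L, shift_lo = 50L, shift_hi = 50L,
             mismatches = 0L, split_mate = 2L, mate_rotated = FALSE,
             stringsAsFactors = FALSE)
}

test_that("aggregation counts distinct pairs per sample and applies min support", {
  s1 <- do.call(rbind, lapply(c("p1", "p2", "p3"), fake_split))
  cat1 <- aggregate_candidates(list(sampleA = s1), 2L)
  expect_equal(nrow(cat1), 1L)
  expect_equal(unname(circ_counts(cat1)[1, "sampleA"]), 3L)
  expect_equal(cat1$id, "c1_100_500_+")

  # a single supporting read everywhere is dropped at k = 2
  cat0 <- aggregate_candidates(list(sampleA = fake_split("p1")), 2L)
  expect_equal(nrow(cat0), 0L)

  # the same junction in two samples gives one candidate with a count vector
  s2 <- do.call(rbind, lapply(paste0("q", 1:5), fake_split))
  cat2 <- aggregate_candidates(list(sA = rbind(fake_split("p1"), fake_split("p2")),
                                    sB = s2), 2L)
  expect_equal(nrow(cat2), 1L)
  expect_equal(unname(circ_counts(cat2)[1, ]), c(2L, 5L))

  # duplicated read ids vote once
  dup <- rbind(fake_split("p1"), fake_split("p1"), fake_split("p2"))
  expect_equal(unname(circ_counts(aggregate_candidates(list(s = dup), 2L))[1, 1]), 2L)
})

test_that("classification against exon boundaries follows the two-point rule", {
  ann <- tiny_genome()$annotation
  # exon [100, 200): both points on boundaries
  expect_equal(classify_bf(ann, "chrT", "+", 100L, 200L), "canonical")
  # strictly inside one exon
  expect_equal(classify_bf(ann, "chrT", "+", 120L, 180L), "complete_icirc")
  # one point at the exon start, one inside the intron
  expect_equal(classify_bf(ann, "chrT", "+", 100L, 250L), "partial_icirc")
  # tolerance widens the boundary match
  tol2 <- feature_params(boundary_tolerance = 2L)
  expect_equal(classify_bf(ann, "chrT", "+", 101L, 199L, tol2), "canonical")
})

test_that("structural categories keep the unambiguous classes and drop the rest", {
  ann <- tiny_genome()$annotation
  expect_equal(structural_category(ann, "chrT", 120L, 180L)$structure, "single_exon")
  expect_equal(structural_category(ann, "chrT", 210L, 290L)$structure, "single_intron")
  sc_adj <- structural_category(ann, "chrT", 150L, 250L)  # exon2's tail + intron
  expect_equal(sc_adj$structure, "adjacent_exon_intron")
  expect_true(sc_adj$kept)
  sc_ig <- structural_category(ann, "chrT", 450L, 550L)
  expect_equal(sc_ig$structure, "intergenic")
  # spanning exon-intron-exon is ambiguous: dropped
  sc_other <- structural_category(ann, "chrT", 150L, 350L)
  expect_equal(sc_other$structure, "other")
  expect_false(sc_other$kept)
})

test_that("SHS detection matches the brute-force string oracle on random junctions", {
  set.seed(77)
  v <- sample(c("A", "C", "G", "T"), 20000, replace = TRUE)
  g <- genome_from_seqs(c(cS = paste(v, collapse = "")))
  for (i in 1:300) {
    A <- sample(100:9000, 1); D <- A + sample(200:9000, 1)
    got <- detect_shs(g, "cS", A, D)
    expect_identical(got$shs_length, shs_oracle(g$seqs[["cS"]], A, D))
    if (got$shs_length > 0)
      expect_equal(nchar(got$shs_sequence), got$shs_length)
  }
  # planted forward homology of 3
  seqs <- g$seqs; A <- 500L; D <- 1500L
  substr(seqs[["cS"]], D + 1L, D + 3L) <- substr(seqs[["cS"]], A + 1L, A + 3L)
  g2 <- genome_from_seqs(seqs)
  expect_gte(detect_shs(g2, "cS", A, D)$f, 3L)
  expect_identical(detect_shs(g2, "cS", A, D)$shs_length,
                   shs_oracle(g2$seqs[["cS"]], A, D))
})

test_that("splice signal is detected across the homology shift window", {
  base <- strrep("T", 400)
  mk <- function(s) genome_from_seqs(c(cZ = s))
  # plus strand, literal junction: AG 5' of A, GT 3' of D
  s <- base
  A <- 100L; D <- 300L
  substr(s, A - 1L, A) <- "AG"; substr(s, D + 1L, D + 2L) <- "GT"
  expect_true(splice_signal(mk(s), "cZ", "+", A, D))
  expect_false(splice_signal(mk(s), "cZ", "-", A, D))
  expect_false(splice_signal(mk(base), "cZ", "+", A, D))

  # minus strand: AC before A, CT after D on the forward genome
  s2 <- base
  substr(s2, A - 1L, A) <- "AC"; substr(s2, D + 1L, D + 2L) <- "CT"
  expect_true(splice_signal(mk(s2), "cZ", "-", A, D))

  # signal appearing only after a 2 nt homology shift: plant the homology
  # itself as AG so the shifted acceptor window reads AG, put GT after the
  # shifted donor, and keep the literal junction signal-free
  set.seed(31)
  s3 <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  substr(s3, A + 1L, A + 2L) <- "AG"; substr(s3, D + 1L, D + 2L) <- "AG"  # SHS 2
  substr(s3, D + 3L, D + 4L) <- "GT"                  # donor at shift t = 2
  substr(s3, A - 1L, A) <- "CC"; substr(s3, D - 1L, D) <- "TA"  # b = 0, no t=0 signal
  substr(s3, A + 3L, A + 3L) <- "C"; substr(s3, D + 5L, D + 5L) <- "A"  # f = 2
  g3 <- mk(s3)
  expect_equal(detect_shs(g3, "cZ", A, D)$shs_length, 2L)
  # brute-force scan over every shifted junction agrees
  shs <- detect_shs(g3, "cZ", A, D)
  direct <- FALSE
  for (t in (-shs$b):shs$f) {
    up <- substr(s3, A + t - 1L, A + t); dn <- substr(s3, D + t + 1L, D + t + 2L)
    if (up == "AG" && dn == "GT") direct <- TRUE
  }
  expect_true(direct)
  expect_true(splice_signal(g3, "cZ", "+", A, D))
  # with the homology broken the shifted signal is out of reach
  s4 <- s3
  substr(s4, D + 1L, D + 2L) <- "CC"
  expect_false(splice_signal(mk(s4), "cZ", "+", A, D))
})

test_that("flank complementarity finds planted inverted repeats and respects the threshold", {
  set.seed(88)
  v <- sample(c("A", "C", "G", "T"), 3000, replace = TRUE)
  s <- paste(v, collapse = "")
  A <- 1000L; D <- 1600L
  piece <- substr(s, A - 50L + 1L, A - 50L + 12L)  # 12-mer in the upstream flank
  substr(s, D + 30L + 1L, D + 30L + 12L) <- rc_oracle(piece)
  g <- genome_from_seqs(c(cF = s))
  rep12 <- flank_complementarity(g, "cF", A, D)
  expect_false(is.null(rep12))
  expect_gte(rep12$length, 12L)
  expect_equal(substr(s, rep12$up_start + 1L, rep12$up_end),
               rc_oracle(substr(s, rep12$down_start + 1L, rep12$down_end)))

  # random flanks essentially never reach 8 bp; min_match = 1 always reports
  g2 <- genome_from_seqs(c(cF = paste(sample(c("A", "C", "G", "T"), 3000,
                                             replace = TRUE), collapse = "")))
  expect_null(flank_complementarity(g2, "cF", 1000L, 1600L))
  one <- flank_complementarity(g2, "cF", 1000L, 1600L,
                               feature_params(flank_min_match = 1L))
  expect_gte(one$length, 1L)
})

test_that("nesting reports proper containments and multi-circle hosts only", {
  cat_df <- aggregate_candidates(list(s = rbind(
    fake_split("p1", A = 100L, D = 900L), fake_split("p2", A = 100L, D = 900L),
    fake_split("p3", A = 200L, D = 600L), fake_split("p4", A = 200L, D = 600L),
    fake_split("p5", A = 2000L, D = 2500L), fake_split("p6", A = 2000L, D = 2500L))),
    2L)
  nest <- find_nestings(cat_df)
  expect_equal(nrow(nest$containments), 1L)
  expect_equal(nest$containments$outer, "c1_100_900_+")
  expect_equal(nest$containments$inner, "c1_200_600_+")
  # identical coordinates are not containments
  cat_same <- aggregate_candidates(list(s = rbind(
    fake_split("p1"), fake_split("p2"),
    fake_split("q1", strand = "-"), fake_split("q2", strand = "-"))), 2L)
  expect_equal(nrow(find_nestings(cat_same)$containments), 0L)
})

test_that("catalog writing and re-reading round-trips candidates and counts", {
  truth <- toy_truth()
  al <- toy_calls()
  catalog <- aggregate_candidates(list(s1 = al), 2L)
  catalog <- annotate_catalog(catalog, truth$genome, truth$annotation)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_catalog(catalog, tsv, bed = bed)
  back <- read_catalog(tsv)
  expect_equal(back$id, catalog$id)
  expect_equal(back$class, catalog$class)
  expect_equal(circ_counts(back)[, "s1"], circ_counts(catalog)[, "s1"])
  bed_df <- read.table(bed, sep = "\t")
  expect_equal(nrow(bed_df), nrow(catalog))
  expect_equal(bed_df$V4, catalog$id)
})
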