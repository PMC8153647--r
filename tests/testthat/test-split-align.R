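make_flat_genome <- function(seed, len = 10000L) {
  set.seed(seed)
  genome_from_seqs(c(chrS = paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")))
}

# build an error-free junction read for circle [A, D) split at offset s
junction_read <- function(genome, chrom, A, D, s, L = 100L) {
  paste0(genome_subseq(genome, chrom, D - s, D),
         genome_subseq(genome, chrom, A, A + L - s))
}

# remove incidental flank homology at [A, D) so the planted coordinates are
# their own canonical (leftmost-shift) representative with a singleton window
trim_flat_junction <- function(g, A, D) {
  s <- g$seqs[["chrS"]]
  ch <- function(p) substr(s, p + 1L, p + 1L)
  alt <- function(x) setdiff(c("A", "C", "G", "T"), x)[1]
  if (ch(A - 1L) == ch(D - 1L)) substr(s, D, D) <- alt(ch(A - 1L))
  if (ch(A) == ch(D)) substr(s, D + 1L, D + 1L) <- alt(ch(A))
  genome_from_seqs(c(chrS = s))
}

test_that("linear mapping places exact and near-exact reads and rejects the rest", {
  g <- make_flat_genome(11)
  read <- genome_subseq(g, "chrS", 2000, 2100)
  res <- map_linear(read, g)
  expect_true(res$mapped)
  expect_equal(res$start, 2000L)
  expect_equal(res$mismatches, 0L)

  # reverse-complement orientation is found too
  res_rc <- map_linear(rc_oracle(read), g)
  expect_true(res_rc$mapped)
  expect_equal(res_rc$orientation, "rev")

  # three substitutions exceed the budget of two
  bad <- read
  substr(bad, 10, 10) <- "N"; substr(bad, 50, 50) <- "N"; substr(bad, 90, 90) <- "N"
  expect_false(map_linear(bad, g)$mapped)

  # >10% N: unmappable without search
  nn <- paste0(strrep("N", 15), substr(read, 16, 100))
  resn <- map_linear(nn, g)
  expect_true(resn$n_excess)
  expect_false(resn$mapped)
})

test_that("a read straddling a planted junction has no contiguous placement", {
  g <- make_flat_genome(12)
  A <- 1000L; D <- 3000L
  rd <- junction_read(g, "chrS", A, D, 50L)
  expect_false(map_linear(rd, g)$mapped)
  # exhaustive confirmation: no offset on either strand leaves <= 2 mismatches
  gv <- strsplit(g$seqs[["chrS"]], "")[[1]]
  for (probe in c(rd, rc_oracle(rd))) {
    rv <- strsplit(probe, "")[[1]]
    best <- min(vapply(0:(length(gv) - 100L), function(off)
      sum(gv[off + 1:100] != rv), numeric(1)))
    expect_gt(best, 2)
  }
})

test_that("anchor extraction takes the terminal x-mers and skips short reads", {
  rd <- paste(rep(c("A", "C"), 50), collapse = "")
  anc <- extract_anchors(rd, 20L)
  expect_equal(anc$left, substr(rd, 1, 20))
  expect_equal(anc$right, substr(rd, 81, 100))
  anc40 <- extract_anchors(strrep("ACGT", 10), 20L)
  expect_equal(nchar(anc40$left), 20L)
  expect_equal(nchar(anc40$right), 20L)
  expect_message(res <- extract_anchors(strrep("A", 39), 20L), "skipped")
  expect_null(res)
})

test_that("anchor pairing keeps only reversed-orientation same-chromosome pairs", {
  hit <- function(chrom, start) data.frame(chrom = chrom, start = start,
                                           mismatches = 0L, uniqueness = 40)
  p <- find_reversed_anchor_pairs(hit("c1", 5000L), hit("c1", 1000L), 100L)
  expect_equal(nrow(p), 1L)
  expect_equal(p$span, 5000L - 1000L + 80L)
  # forward-spliced geometry is excluded
  expect_equal(nrow(find_reversed_anchor_pairs(hit("c1", 1000L),
                                               hit("c1", 5000L), 100L)), 0L)
  # different chromosomes are excluded
  expect_equal(nrow(find_reversed_anchor_pairs(hit("c1", 5000L),
                                               hit("c2", 1000L), 100L)), 0L)
  # low-uniqueness anchors are excluded
  lowq <- hit("c1", 5000L); lowq$uniqueness <- 20
  expect_equal(nrow(find_reversed_anchor_pairs(lowq, hit("c1", 1000L), 100L)), 0L)
})

test_that("split resolution recovers a planted junction exactly and uniquely", {
  A <- 1000L; D <- 3000L
  g <- trim_flat_junction(make_flat_genome(13), A, D)
  for (s in c(25L, 50L, 77L)) {
    rd <- junction_read(g, "chrS", A, D, s)
    sa <- split_map_read(rd, g)
    expect_equal(sa$A, A)
    expect_equal(sa$D, D)
    expect_equal(sa$split_offset, s)
    expect_equal(sa$mismatches, 0L)
    expect_equal(sa$valid_s, s)  # repeat-free locus: single valid split
  }
  # three mismatches against the best split: rejected
  rd <- junction_read(g, "chrS", A, D, 50L)
  substr(rd, 30, 30) <- "N"; substr(rd, 45, 45) <- "N"; substr(rd, 60, 60) <- "N"
  expect_null(split_map_read(rd, g))
})

test_that("junction homology widens the split window without moving the canonical point", {
  g <- make_flat_genome(14)
  A <- 1200L; D <- 4200L
  # plant a 3 nt identical sequence at both junction flanks, trimmed so the
  # planted coordinates are the leftmost representative
  seqs <- g$seqs
  piece <- substr(seqs[["chrS"]], A + 1L, A + 3L)
  substr(seqs[["chrS"]], D + 1L, D + 3L) <- piece
  if (substr(seqs[["chrS"]], A, A) == substr(seqs[["chrS"]], D, D))
    substr(seqs[["chrS"]], D, D) <- setdiff(c("A", "C", "G", "T"),
                                            substr(seqs[["chrS"]], A, A))[1]
  if (substr(seqs[["chrS"]], A + 4L, A + 4L) == substr(seqs[["chrS"]], D + 4L, D + 4L))
    substr(seqs[["chrS"]], A + 4L, A + 4L) <- setdiff(c("A", "C", "G", "T"),
                                                      substr(seqs[["chrS"]], D + 4L, D + 4L))[1]
  g2 <- genome_from_seqs(seqs)

  sa <- split_map_read(junction_read(g2, "chrS", A, D, 50L), g2)
  expect_equal(length(sa$valid_s), 4L)  # SHS length + 1
  expect_equal(sa$A, A)
  expect_equal(sa$D, D)

  # two reads split at different in-window offsets aggregate identically
  sa2 <- split_map_read(junction_read(g2, "chrS", A + 2L, D + 2L, 60L), g2)
  expect_equal(c(sa2$A, sa2$D), c(sa$A, sa$D))
})

test_that("canonicalize picks the leftmost offset and flags gaps", {
  expect_equal(canonicalize(45L), 45L)
  expect_equal(canonicalize(c(47L, 45L, 46L)), 45L)
  expect_warning(out <- canonicalize(c(45L, 47L)), "non-contiguous")
  expect_equal(out, 45L)
  expect_error(canonicalize(integer()), "at least one")
})

test_that("mate containment accepts interior mates, rejects distant ones, rotates short circles", {
  A <- 1000L; D <- 3000L
  g <- trim_flat_junction(make_flat_genome(15), A, D)
  mate_in <- genome_subseq(g, "chrS", 1500, 1600)
  expect_true(mate_within_circle(mate_in, g, "chrS", "+", A, D)$ok)
  mate_out <- genome_subseq(g, "chrS", 5000, 5100)
  expect_false(mate_within_circle(mate_out, g, "chrS", "+", A, D)$ok)

  # mate that itself spans the junction: accepted under the rotated rule only
  mate_j <- junction_read(g, "chrS", A, D, 40L)
  res <- mate_within_circle(mate_j, g, "chrS", "+", A, D)
  expect_true(res$ok)
  expect_true(res$rotated)
  strict <- detection_params(mate_mode = "strict")
  expect_false(mate_within_circle(mate_j, g, "chrS", "+", A, D, strict)$ok)
})

test_that("split resolution agrees with an exhaustive (A, D, s) oracle", {
  g <- make_flat_genome(16, len = 8000L)
  gv <- utf8ToInt(g$seqs[["chrS"]])
  len <- length(gv); L <- 100L; x <- 20L
  set.seed(160)
  for (rep in 1:20) {
    A <- sample(200:3000, 1); D <- A + sample(300:4000, 1)
    s_true <- sample(x:(L - x), 1)
    rd <- junction_read(g, "chrS", A, D, s_true)
    rv <- utf8ToInt(rd)
    # exhaustive: mismatches of every read prefix/suffix at every offset
    offs <- 0:(len - L)
    idx <- outer(1:L, offs, "+")
    mm <- matrix(gv[idx] != rv, nrow = L)
    pre <- apply(mm, 2, cumsum)              # prefix mm by (s, offset)
    suf <- apply(mm[L:1, , drop = FALSE], 2, cumsum)[L:1, , drop = FALSE]
    found <- list()
    for (s in x:(L - x)) {
      gl_off <- offs[pre[s, ] <= 2]   # whole-read offset of the prefix diagonal
      ga_off <- offs[suf[s + 1L, ] <= 2]
      for (g1 in gl_off) for (g2 in ga_off) {
        tot <- pre[s, match(g1, offs)] + suf[s + 1L, match(g2, offs)]
        if (tot <= 2 && g2 < g1)     # suffix diagonal upstream: A < D
          found[[length(found) + 1L]] <- c(A = g2 + s, D = g1 + s, s = s, mm = tot)
      }
    }
    found <- unique(do.call(rbind, found))
    best <- found[found[, "mm"] == min(found[, "mm"]), , drop = FALSE]
    sa <- split_map_read(rd, g)
    expect_true(!is.null(sa))
    expect_equal(sa$A, unname(min(best[, "A"])))
    expect_equal(sa$D, unname(min(best[, "D"])))
    expect_true(any(best[, "A"] == A & best[, "D"] == D & best[, "s"] == s_true))
  }
})

test_that("strand symmetry: the mirrored genome yields the mirrored junction", {
  A <- 1000L; D <- 3000L
  g <- trim_flat_junction(make_flat_genome(17), A, D)
  # also trim the mirrored-side homology so both windows are singletons
  s <- g$seqs[["chrS"]]
  if (substr(s, A + 1L, A + 1L) == substr(s, D + 1L, D + 1L))
    substr(s, A + 1L, A + 1L) <- setdiff(c("A", "C", "G", "T"),
                                         substr(s, D + 1L, D + 1L))[1]
  g <- genome_from_seqs(c(chrS = s))
  rd <- junction_read(g, "chrS", A, D, 50L)
  sa_fwd <- split_map_read(rd, g)
  len <- genome_length(g, "chrS")
  g_rc <- genome_from_seqs(c(chrS = rc_oracle(g$seqs[["chrS"]])))
  sa_rc <- split_map_read(rc_oracle(rd), g_rc)
  expect_equal(sa_rc$A, len - sa_fwd$D)
  expect_equal(sa_rc$D, len - sa_fwd$A)
})

test_that("reads from linear transcripts never produce split alignments", {
  truth <- toy_truth()
  lin_only <- truth
  lin_only$circles <- truth$circles[0, ]
  sim <- simulate_reads(lin_only, depth = 0L, linear_pairs = 300L, seed = 91)
  al <- detect_circles(sim$reads1, sim$reads2, truth$genome, ids = sim$ids)
  expect_equal(nrow(al), 0L)
})

test_that("the SAM adapter extracts unmapped records and reorients reverse flags", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    paste("r1", 77, "*", 0, 0, "*", "*", 0, 0, "ACGTACGT", "IIIIIIII", sep = "\t"),
    paste("r1", 141, "*", 0, 0, "*", "*", 0, 0, "GGGGCCCC", "IIIIIIII", sep = "\t"),
    paste("r2", 0, "chr1", 100, 60, "8M", "*", 0, 0, "AAAATTTT", "IIIIIIII", sep = "\t"),
    paste("r3", 21, "*", 0, 0, "*", "*", 0, 0, "ACGTACGT", "IIIIIIII", sep = "\t")),
    sam)
  un <- read_sam_unmapped(sam)
  expect_equal(un$read_id, c("r1", "r1", "r3"))
  expect_equal(un$mate, c(1L, 2L, NA))
  expect_equal(un$seq[3], rc_oracle("ACGTACGT"))  # flag 16 set
})
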