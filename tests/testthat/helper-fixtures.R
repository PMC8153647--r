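# Shared fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# a tiny deterministic genome: one 600 nt chromosome with one 2-exon gene
tiny_genome <- function() memo("tiny", function() {
  set.seed(101)
  v <- sample(c("A", "C", "G", "T"), 600, replace = TRUE)
  # gene: exon [100, 200), intron [200, 300) with GT..AG, exon [300, 400)
  v[201:202] <- c("G", "T"); v[299:300] <- c("A", "G")
  g <- genome_from_seqs(c(chrT = paste(v, collapse = "")))
  ex <- data.frame(gene_id = "g1", transcript_id = "g1_t1", chrom = "chrT",
                   strand = "+", start = c(100L, 300L), end = c(200L, 400L))
  list(genome = g, annotation = annotation_from_exons(ex, g))
})

# the standard simulated toy genome + planted circles (moderate scale)
toy_truth <- function() memo("toy_truth", function() {
  gen <- make_genome(42)
  plant_circles(gen$genome, gen$annotation, default_circle_design(), 43)
})

toy_reads <- function() memo("toy_reads", function() {
  simulate_reads(toy_truth(), depth = 6, interior_pairs = 2,
                 linear_pairs = 400, seed = 44)
})

toy_calls <- function() memo("toy_calls", function() {
  sim <- toy_reads()
  detect_circles(sim$reads1, sim$reads2, toy_truth()$genome, ids = sim$ids)
})

# independent brute-force SHS oracle: direct string comparison
shs_oracle <- function(seq, A, D, max_len = 60L) {
  ch <- function(p) substr(seq, p + 1L, p + 1L)  # 0-based accessor
  len <- nchar(seq)
  f <- 0L
  while (f < max_len && D + f < len && A + f < D && ch(A + f) == ch(D + f))
    f <- f + 1L
  b <- 0L
  while (b < max_len && A - b - 1L >= 0L && D - b > A && ch(A - b - 1L) == ch(D - b - 1L))
    b <- b + 1L
  f + b
}

# brute-force rank-sum p by enumerating every group assignment (combn)
ranksum_enum_p <- function(a, b) {
  n1 <- length(a); vals <- c(a, b); N <- length(vals)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  combos <- combn(N, n1)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# all permutations of a vector (for the Spearman enumeration oracle)
all_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], all_perms(v[-i])))
  out
}

spearman_enum_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  stat <- function(p) abs(sum(rx * p) - sum(rx) * sum(ry) / length(rx))
  perms <- all_perms(ry)
  obs <- stat(ry)
  mean(apply(perms, 1, stat) >= obs - 1e-9)
}

# independent reverse-complement helper (Biostrings, not the package's rc)
rc_oracle <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
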