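#' Generate a seeded toy genome with gene annotation
#'
#' Chromosomes are i.i.d. uniform A/C/G/T sequence carrying genes of 2-8
#' exons with GT-AG introns (strand-appropriate on the forward genome).
#' Genes are laid out left to right with intergenic gaps; the first 1 kb
#' of every chromosome is kept annotation-free.  Fully deterministic per
#' seed.
#'
#' @param seed Integer RNG seed.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in nt (>= 10 kb).
#' @param gene_density Genes per 10 kb (0 gives an empty annotation, all
#'   intergenic).
#' @return List with `genome` (`circat_genome`) and `annotation`
#'   (`circat_annotation`).
#' @export
make_genome <- function(seed, n_chromosomes = 2L, chrom_length = 50000L,
                        gene_density = 1.4) {
  if (chrom_length < 10000L) stop("chrom_length must be >= 10 kb")
  with_seed(seed, {
    seqs <- list(); exon_rows <- list()
    for (ci in seq_len(n_chromosomes)) {
      chr <- paste0("chr", ci)
      v <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
      n_genes <- round(gene_density * chrom_length / 10000)
      pos <- 1000L  # annotation-free head
      placed <- 0L
      while (placed < n_genes) {
        strand <- sample(c("+", "-"), 1L)
        n_ex <- sample(2:8, 1L)
        ex_len <- sample(120:450, n_ex, replace = TRUE)
        in_len <- sample(200:1200, n_ex - 1L, replace = TRUE)
        span <- sum(ex_len) + sum(in_len)
        if (pos + span + 500L > chrom_length - 500L) break
        gid <- sprintf("%s_g%d", chr, placed + 1L)
        starts <- integer(n_ex); ends <- integer(n_ex)
        p <- pos
        for (e in seq_len(n_ex)) {
          starts[e] <- p; ends[e] <- p + ex_len[e]
          p <- ends[e]
          if (e < n_ex) {
            # donor/acceptor dinucleotides on the forward genome:
            # plus-strand introns read GT...AG, minus-strand CT...AC
            is <- p; ie <- p + in_len[e]
            if (strand == "+") { v[is + 1:2] <- c("G", "T"); v[(ie - 1L):ie] <- c("A", "G") }
            else               { v[is + 1:2] <- c("C", "T"); v[(ie - 1L):ie] <- c("A", "C") }
            p <- ie
          }
        }
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          gene_id = gid, transcript_id = paste0(gid, "_t1"), chrom = chr,
          strand = strand, start = starts, end = ends, stringsAsFactors = FALSE)
        placed <- placed + 1L
        pos <- p + sample(500:1500, 1L)
      }
      if (n_genes > 0L && placed == 0L)
        stop("gene parameters unplaceable on a ", chrom_length, " nt chromosome")
      seqs[[chr]] <- paste(v, collapse = "")
    }
    genome <- genome_from_seqs(unlist(seqs))
    exons <- if (length(exon_rows)) do.call(rbind, exon_rows)
      else data.frame(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer())
    list(genome = genome, annotation = annotation_from_exons(exons, genome))
  })
}

# replace genomic interval [start, end) on chrom with `value` (same length)
edit_genome_chars <- function(seqs, chrom, start, value) {
  substr(seqs[[chrom]], start + 1L, start + nchar(value)) <- value
  seqs
}

# set one genomic character; positions falling inside the planted forward
# homology [D, D + h) are mirrored to the source copy at A + (pos - D) so
# the homology equality is preserved by construction
edit_mirrored <- function(seqs, chrom, A, D, h, pos, char) {
  seqs <- edit_genome_chars(seqs, chrom, pos, char)
  if (h > 0L && pos >= D && pos < D + h)
    seqs <- edit_genome_chars(seqs, chrom, A + (pos - D), char)
  seqs
}

# Trim incidental junction homology so the planted coordinates are the
# canonical (leftmost-shift) representative: backward homology 0 and
# forward homology exactly the designed h.  Edits stay inside the circle
# (positions D-1 and A+h), leaving boundary dinucleotides untouched.
other_base <- function(avoid) setdiff(c("A", "C", "G", "T"), avoid)[1]
trim_homology <- function(seqs, chrom, A, D, h) {
  at <- function(p) substr(seqs[[chrom]], p + 1L, p + 1L)
  if (at(A - 1L) == at(D - 1L))
    seqs <- edit_genome_chars(seqs, chrom, D - 1L, other_base(at(A - 1L)))
  if (at(A + h) == at(D + h))
    seqs <- edit_genome_chars(seqs, chrom, A + h, other_base(at(D + h)))
  seqs
}

# dinucleotide check at the literal (unshifted) junction coordinates
literal_signal <- function(g, chrom, strand, A, D, fparams) {
  splice_signal(g, chrom, strand, A, D,
                feature_params(shs_max = 0L,
                               splice_signals = fparams$splice_signals))
}

# ensure splice_signal(genome', ...) equals `want` by local dinucleotide
# edits, mirrored into the planted homology so the SHS survives; bounded
# retry because an edit can itself open a signal at another shift
force_signal <- function(seqs, chrom, strand, A, D, want, h, fparams) {
  up <- if (strand == "+") "AG" else "AC"  # 2 nt 5' of the acceptor A
  dn <- if (strand == "+") "GT" else "CT"  # 2 nt 3' of the donor D
  for (iter in 1:200) {
    g <- genome_from_seqs(seqs)
    if (splice_signal(g, chrom, strand, A, D, fparams) == want) return(seqs)
    if (want) {
      seqs <- edit_genome_chars(seqs, chrom, A - 2L, up)
      seqs <- edit_mirrored(seqs, chrom, A, D, h, D, substr(dn, 1, 1))
      seqs <- edit_mirrored(seqs, chrom, A, D, h, D + 1L, substr(dn, 2, 2))
    } else {
      shs <- detect_shs(g, chrom, A, D, fparams$shs_max)
      for (t in (-shs$b):shs$f) {
        if (literal_signal(g, chrom, strand, A + t, D + t, fparams)) {
          # breaking the donor dinucleotide alone kills this shift
          seqs <- edit_mirrored(seqs, chrom, A, D, h, D + t, "A")
          seqs <- edit_mirrored(seqs, chrom, A, D, h, D + t + 1L, "A")
          break
        }
      }
    }
  }
  stop("could not enforce splice-signal state at ", chrom, ":", A, "-", D)
}

#' Plant circRNAs of requested classes into a toy genome
#'
#' Chooses loci satisfying each design row's class and structural
#' category, locally edits the genome to create the requested short
#' homologous sequence (identical h-mers at both junction flanks),
#' splicing-signal presence or absence, and inverted flank repeats, and
#' records the final coordinates as the truth set.  Every planted circle
#' is validated against the package's own classifiers before being
#' returned (self-consistency gate).
#'
#' @param genome A `circat_genome` from [make_genome()].
#' @param annotation The matching `circat_annotation`.
#' @param design data.frame with columns `class` (`canonical`,
#'   `partial_icirc`, `complete_icirc`), `structure` (`single_exon`,
#'   `single_intron`, `adjacent_exon_intron`, `intergenic`) and optional
#'   `shs_length`, `signal`, `flank_repeat_length`.
#' @param seed Integer RNG seed.
#' @param fparams A [feature_params()] object used by the validators.
#' @return A `circat_truth` list: `genome` (edited), `annotation`,
#'   `circles` (truth table with realized features), `seed`.
#' @export
plant_circles <- function(genome, annotation, design, seed,
                          fparams = feature_params()) {
  if (!all(c("class", "structure") %in% names(design)))
    stop("design needs columns class and structure")
  design$shs_length <- design$shs_length %||% rep(0L, nrow(design))
  design$signal <- design$signal %||% rep(NA, nrow(design))
  design$flank_repeat_length <- design$flank_repeat_length %||% rep(0L, nrow(design))
  seqs <- genome$seqs
  ann <- annotation
  ex <- ann$exons
  # internal exons: neither first nor last of their transcript
  internal <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(e) {
    if (nrow(e) < 3L) return(NULL)
    e[order(e$start), ][2:(nrow(e) - 1L), ]
  }))
  used_feats <- character()
  ig_cursor <- rep(0L, nrow(ann$intergenic))  # circles per interval, packed left
  rows <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(design))) {
      cls <- design$class[i]; stc <- design$structure[i]
      h <- design$shs_length[i]; fr <- design$flank_repeat_length[i]
      margin <- max(15L, h + 15L)
      loc <- NULL
      if (stc == "intergenic") {
        ig <- ann$intergenic
        span <- sample(350:600, 1L)
        pad <- margin + fr + 250L
        need <- 2L * pad + span
        j <- which(ig$end - (ig$start + ig_cursor) >= need)
        if (!length(j)) stop("no intergenic interval available for design row ", i)
        j <- j[1]
        A <- ig$start[j] + ig_cursor[j] + pad
        D <- A + span
        ig_cursor[j] <- D + pad - ig$start[j]
        loc <- list(chrom = ig$chrom[j], strand = sample(c("+", "-"), 1L),
                    A = A, D = D, gene = "")
      } else if (stc == "single_exon") {
        need <- switch(cls, complete_icirc = 2L * margin + 170L,
                       partial_icirc = max(240L, 4L * margin), canonical = 150L)
        key <- paste(internal$transcript_id, internal$start)
        elen <- internal$end - internal$start
        cand <- which(!(key %in% used_feats) & elen >= need)
        if (!length(cand)) stop("no exon available for design row ", i)
        # smallest adequate exon, leaving large ones for later rows
        k <- cand[order(elen[cand])][1]
        e <- internal[k, ]; used_feats <- c(used_feats, key[k])
        AD <- switch(cls,
          canonical = c(e$start, e$end),
          partial_icirc = c(e$start, e$start + max(200L, round(0.7 * (e$end - e$start)))),
          complete_icirc = c(e$start + margin, e$end - margin))
        loc <- list(chrom = e$chrom, strand = e$strand, A = AD[1], D = AD[2],
                    gene = e$gene_id)
      } else if (stc == "single_intron") {
        intr <- ann$introns
        key <- paste("i", intr$transcript_id, intr$start)
        ilen <- intr$end - intr$start
        cand <- which(!(key %in% used_feats) & ilen >= 2L * margin + 300L)
        if (!length(cand)) stop("no intron available for design row ", i)
        k <- cand[order(ilen[cand])][1]
        it <- intr[k, ]; used_feats <- c(used_feats, key[k])
        AD <- switch(cls,
          canonical = c(it$start, it$end),
          partial_icirc = c(it$start, it$end - margin),
          complete_icirc = c(it$start + margin, it$end - margin))
        loc <- list(chrom = it$chrom, strand = it$strand, A = AD[1], D = AD[2],
                    gene = it$gene_id)
      } else if (stc == "adjacent_exon_intron") {
        intr <- ann$introns
        key <- paste("i", intr$transcript_id, intr$start)
        cand <- which(!(key %in% used_feats) &
                        (intr$end - intr$start) >= margin + 300L)
        ok <- FALSE
        for (k in cand) {
          it <- intr[k, ]
          e <- ex[ex$transcript_id == it$transcript_id & ex$end == it$start, ]
          ekey <- paste(e$transcript_id, e$start)
          if (nrow(e) && !(ekey[1] %in% used_feats) &&
              (e$end[1] - e$start[1]) >= margin + 60L) {
            A <- e$start[1] + margin
            D <- it$end - margin
            loc <- list(chrom = it$chrom, strand = it$strand, A = A, D = D,
                        gene = it$gene_id)
            used_feats <- c(used_feats, key[k], ekey[1])
            ok <- TRUE; break
          }
        }
        if (!ok) stop("no adjacent exon+intron available for design row ", i)
      } else stop("unknown structure: ", stc)

      A <- loc$A; D <- loc$D; ch <- loc$chrom; st <- loc$strand
      # plant the forward-homology SHS: copy the h-mer at the circle start
      # to the h positions just past the donor
      if (h > 0L)
        seqs <- edit_genome_chars(seqs, ch, D,
                                  substr(seqs[[ch]], A + 1L, A + h))
      # plant an inverted repeat across the two flanks
      if (fr > 0L) {
        w0 <- max(30L, h + 5L)
        up_piece <- substr(seqs[[ch]], A - w0 - fr + 1L, A - w0)
        seqs <- edit_genome_chars(seqs, ch, D + w0, rc(up_piece))
      }
      want_sig <- design$signal[i]
      if (is.na(want_sig)) want_sig <- cls == "canonical"
      # alternate trimming and signal forcing until both are stable (an
      # acceptor edit can recreate 1 nt of backward homology)
      for (it in 1:10) {
        seqs <- trim_homology(seqs, ch, A, D, h)
        seqs <- force_signal(seqs, ch, st, A, D, want_sig, h, fparams)
        g <- genome_from_seqs(seqs)
        shs <- detect_shs(g, ch, A, D, fparams$shs_max)
        if (shs$b == 0L && shs$f == h &&
            splice_signal(g, ch, st, A, D, fparams) == want_sig) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste(ch, A, D, st, sep = "_"), chrom = ch, strand = st,
        A = A, D = D, class = cls, structure = stc, gene_id = loc$gene,
        stringsAsFactors = FALSE)
    }
  })
  g2 <- genome_from_seqs(seqs)
  circles <- do.call(rbind, rows)
  circles$shs_length <- 0L
  circles$signal <- FALSE
  circles$flank_repeat_length <- 0L
  # self-consistency gate: realized features must satisfy the design
  for (i in seq_len(nrow(circles))) {
    ci <- circles[i, ]
    cls <- classify_bf(ann, ci$chrom, ci$strand, ci$A, ci$D, fparams)
    if (cls != ci$class)
      stop("planted circle ", ci$id, " classifies as ", cls, " not ", ci$class)
    sc <- structural_category(ann, ci$chrom, ci$A, ci$D)
    if (sc$structure != ci$structure)
      stop("planted circle ", ci$id, " has structure ", sc$structure)
    shs <- detect_shs(g2, ci$chrom, ci$A, ci$D, fparams$shs_max)
    if (shs$shs_length != design$shs_length[i] || shs$b != 0L)
      stop("planted SHS not realized canonically at ", ci$id)
    circles$shs_length[i] <- shs$shs_length
    circles$signal[i] <- splice_signal(g2, ci$chrom, ci$strand, ci$A, ci$D, fparams)
    fl <- flank_complementarity(g2, ci$chrom, ci$A, ci$D, fparams)
    circles$flank_repeat_length[i] <- if (is.null(fl)) 0L else fl$length
    if (design$flank_repeat_length[i] > 0L &&
        circles$flank_repeat_length[i] < design$flank_repeat_length[i])
      stop("planted flank repeat shorter than requested at ", ci$id)
  }
  want <- design$signal
  mismatchd <- !is.na(want) & circles$signal != want
  if (any(mismatchd)) stop("signal state not realized for ",
                           paste(circles$id[mismatchd], collapse = ", "))
  structure(list(genome = g2, annotation = ann, circles = circles, seed = seed),
            class = "circat_truth")
}

#' @export
print.circat_truth <- function(x, ...) {
  cat("circat truth set:", nrow(x$circles), "planted circRNA(s)\n")
  print(table(x$circles$class, x$circles$structure))
  invisible(x)
}

# circular substring of sequence `s` (character scalar) starting at
# 0-based offset `from`, length `n`; wraps as often as needed
circular_substr <- function(s, from, n) {
  len <- nchar(s)
  from <- from %% len
  reps <- ceiling((from + n) / len)
  substr(paste(rep(s, reps), collapse = ""), from + 1L, from + n)
}

add_read_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    L <- nchar(r)
    k <- rbinom(1L, L, rate)
    if (k == 0L) return(r)
    pos <- sample.int(L, k)
    for (p in pos) {
      cur <- substr(r, p, p)
      substr(r, p, p) <- sample(setdiff(bases, cur), 1L)
    }
    r
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate stranded paired-end reads from a planted truth set
#'
#' Generates, per planted circle, `depth` read pairs whose split mate
#' crosses the back-fusion junction with at least `anchor_length + 2` nt
#' on each side (uniformly positioned otherwise) plus `interior_pairs`
#' fully interior pairs, and a linear background of pairs drawn from the
#' annotated transcripts.  The library layout is dUTP-style
#' (fr-firststrand): read 2 carries the transcript sense, read 1 its
#' reverse complement.  Fragments longer than a circle wrap around it
#' (rotated-circle geometry) and are flagged in the provenance.
#' Substitution errors are i.i.d. per base; FASTQ qualities are constant.
#'
#' @param truth A `circat_truth` from [plant_circles()].
#' @param read_length Read length L in nt.
#' @param fragment_mean,fragment_sd Fragment length model (normal,
#'   clamped to at least `read_length + 10`).
#' @param depth Junction-crossing read pairs per circle.
#' @param interior_pairs Additional interior pairs per circle.
#' @param error_rate Per-base substitution probability.
#' @param linear_pairs Total background pairs from linear transcripts.
#' @param seed Integer RNG seed.
#' @param anchor_length Used for the junction-crossing margin.
#' @return List with `reads1`, `reads2`, `ids` and a `provenance`
#'   data.frame recording each pair's true origin.
#' @export
simulate_reads <- function(truth, read_length = 100L, fragment_mean = 250,
                           fragment_sd = 25, depth = 10L, interior_pairs = 3L,
                           error_rate = 0, linear_pairs = 1000L, seed = 1L,
                           anchor_length = 20L) {
  L <- read_length
  margin <- anchor_length + 2L
  circles <- truth$circles
  g <- truth$genome
  with_seed(seed, {
    r1 <- character(); r2 <- character(); prov <- list()
    if (depth == 0L && nrow(circles))
      warning("depth 0 for every circle: linear-only output")
    for (i in seq_len(nrow(circles))) {
      ci <- circles[i, ]
      plus_seq <- genome_subseq(g, ci$chrom, ci$A, ci$D)
      C <- if (ci$strand == "+") plus_seq else rc(plus_seq)
      clen <- nchar(C)
      n_i <- if (depth > 0L) depth else 0L
      for (j in seq_len(n_i)) {
        # draw until the non-split mate is resolvable: fully interior,
        # starting exactly at the junction, or crossing it with at least
        # the anchor margin on both sides (short circles force the mate
        # across the junction -- the rotated-circle geometry)
        for (try in 1:200) {
          m <- sample(1:2, 1L)
          t <- sample(margin:(L - margin), 1L)
          flen <- max(L + 10L, round(rnorm(1L, fragment_mean, fragment_sd)))
          u <- if (m == 2L) (clen - t) %% clen else (clen - t - (flen - L)) %% clen
          other_start <- if (m == 2L) u + flen - L else u
          t_other <- (-other_start) %% clen
          if (t_other == 0L || t_other >= L ||
              (t_other >= margin && t_other <= L - margin)) break
          if (try == 200L) stop("no resolvable mate geometry for circle ", ci$id)
        }
        Fg <- circular_substr(C, u, flen)
        r2 <- c(r2, substr(Fg, 1L, L))
        r1 <- c(r1, rc(substr(Fg, flen - L + 1L, flen)))
        prov[[length(prov) + 1L]] <- data.frame(
          origin = "circle", origin_id = ci$id, junction = TRUE,
          split_mate = m, crossing_offset = t, rotated = flen > clen,
          stringsAsFactors = FALSE)
      }
      for (j in seq_len(if (depth > 0L) interior_pairs else 0L)) {
        ok <- FALSE
        for (try in 1:50) {
          flen <- max(L + 10L, round(rnorm(1L, fragment_mean, fragment_sd)))
          if (flen + 2L >= clen) next
          u <- sample.int(clen - flen, 1L) - 1L  # no wrap: fully interior
          ok <- TRUE; break
        }
        if (!ok) next
        Fg <- substr(C, u + 1L, u + flen)
        r2 <- c(r2, substr(Fg, 1L, L))
        r1 <- c(r1, rc(substr(Fg, flen - L + 1L, flen)))
        prov[[length(prov) + 1L]] <- data.frame(
          origin = "circle", origin_id = ci$id, junction = FALSE,
          split_mate = NA_integer_, crossing_offset = NA_integer_,
          rotated = FALSE, stringsAsFactors = FALSE)
      }
    }
    # linear background from spliced transcripts
    if (linear_pairs > 0L) {
      tx <- truth$annotation$transcripts
      tx_seqs <- vapply(seq_len(nrow(tx)), function(k) {
        e <- truth$annotation$exons[
          truth$annotation$exons$transcript_id == tx$transcript_id[k], ]
        e <- e[order(e$start), ]
        s <- paste(vapply(seq_len(nrow(e)), function(q)
          genome_subseq(g, e$chrom[q], e$start[q], e$end[q]), character(1)),
          collapse = "")
        if (tx$strand[k] == "+") s else rc(s)
      }, character(1))
      names(tx_seqs) <- tx$transcript_id
      min_flen <- L + 10L
      long_enough <- nchar(tx_seqs) >= min_flen
      if (!any(long_enough)) {
        warning("no transcript long enough for the fragment model; ",
                "linear background skipped")
      } else {
        tx_seqs <- tx_seqs[long_enough]
        wts <- nchar(tx_seqs)
        k <- sample.int(length(tx_seqs), linear_pairs, replace = TRUE, prob = wts)
        tlen <- nchar(tx_seqs)[k]
        flen <- pmin(tlen, pmax(min_flen, round(rnorm(linear_pairs,
                                                      fragment_mean, fragment_sd))))
        u <- floor(runif(linear_pairs) * (tlen - flen + 1L))
        Fg <- substring(tx_seqs[k], u + 1L, u + flen)
        r2 <- c(r2, substring(Fg, 1L, L))
        r1 <- c(r1, rc(substring(Fg, flen - L + 1L, flen)))
        prov[[length(prov) + 1L]] <- data.frame(
          origin = "linear", origin_id = names(tx_seqs)[k], junction = FALSE,
          split_mate = NA_integer_, crossing_offset = NA_integer_,
          rotated = FALSE, stringsAsFactors = FALSE)
      }
    }
    provenance <- if (length(prov)) do.call(rbind, prov)
      else data.frame(origin = character(), origin_id = character(),
                      junction = logical(), split_mate = integer(),
                      crossing_offset = integer(), rotated = logical())
    ids <- sprintf("pair%06d", seq_len(length(r1)))
    provenance <- cbind(data.frame(read_id = ids, stringsAsFactors = FALSE),
                        provenance)
    r1 <- add_read_errors(unname(r1), error_rate)
    r2 <- add_read_errors(unname(r2), error_rate)
    list(reads1 = r1, reads2 = r2, ids = ids, provenance = provenance)
  })
}

#' Write a simulated read set as paired FASTQ
#'
#' Constant qualities; gzip output when the path ends in `.gz`.
#'
#' @param sim Output of [simulate_reads()].
#' @param path1,path2 Output FASTQ paths for mate 1 / mate 2.
#' @export
write_fastq_pair <- function(sim, path1, path2) {
  wr <- function(reads, ids, path) {
    reads <- unname(reads)
    ss <- Biostrings::DNAStringSet(reads)
    names(ss) <- ids
    q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = q,
                                compress = endsWith(path, ".gz"))
  }
  wr(sim$reads1, sim$ids, path1)
  wr(sim$reads2, sim$ids, path2)
  invisible(c(path1, path2))
}

#' Read paired FASTQ files
#' @param path1,path2 FASTQ paths (gzip tolerated).
#' @return List with `reads1`, `reads2`, `ids`.
#' @export
read_fastq_pair <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(s1) != length(s2)) stop("mate files differ in read count")
  list(reads1 = unname(toupper(as.character(s1))),
       reads2 = unname(toupper(as.character(s2))),
       ids = sub("\\s.*$", "", names(s1)))
}

#' Simulate a circRNA count matrix with planted differential expression
#'
#' Negative-binomial junction counts (real junction counts are
#' overdispersed) with library-size scaling; a `frac_de` fraction of rows
#' is scaled by `fold_change` in group A.
#'
#' @param n_circ Number of circRNAs (rows).
#' @param n_per_group Samples per group, length-2 vector (A, B).
#' @param frac_de Fraction of differentially expressed rows.
#' @param fold_change Fold change applied to group A of DE rows.
#' @param nb_mean Baseline mean count at the median library size.
#' @param nb_dispersion NB dispersion (`size = 1/dispersion`).
#' @param lib_size_range Uniform range of per-sample mapped-read totals.
#' @param seed Integer RNG seed.
#' @return List with `expr` (`circat_expr`) and `truth` (data.frame `id`,
#'   `de`, `direction`).
#' @export
simulate_expression <- function(n_circ = 200L, n_per_group = c(15L, 15L),
                                frac_de = 0.1, fold_change = 4,
                                nb_mean = 50, nb_dispersion = 0.2,
                                lib_size_range = c(2e7, 4e7), seed = 1L) {
  with_seed(seed, {
    nA <- n_per_group[1]; nB <- n_per_group[2]
    samples <- c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB)))
    groups <- setNames(rep(c("A", "B"), c(nA, nB)), samples)
    libs <- setNames(runif(nA + nB, lib_size_range[1], lib_size_range[2]), samples)
    base <- nb_mean * exp(rnorm(n_circ, 0, 0.4))
    n_de <- round(frac_de * n_circ)
    de <- seq_len(n_circ) <= n_de
    mu <- outer(base, libs / mean(libs))
    mu[de, groups == "A"] <- mu[de, groups == "A"] * fold_change
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
                     nrow = n_circ, dimnames = list(sprintf("circ%04d",
                                                            seq_len(n_circ)),
                                                    samples))
    truth <- data.frame(id = rownames(counts), de = de,
                        direction = ifelse(de, "up", "none"),
                        stringsAsFactors = FALSE)
    list(expr = expression_matrix(counts, libs, groups), truth = truth)
  })
}

#' Simulate a ceRNA scenario with known associations
#'
#' Two equal groups of samples; the circRNA is down-regulated in group A
#' (latent shift 2 sd, giving roughly a 3-fold expression change, in line
#' with abundant-circRNA fold changes seen in skin data).  Truly
#' associated genes are monotone functions of the circRNA's latent level
#' (correlation `strength`) and so are co-down-regulated;
#' opposite-direction controls are up-regulated independently;
#' independent genes are pure noise.  Each gene is a target of one of
#' `n_mirnas` miRNAs, all of which also bind the circRNA.
#'
#' @param n_samples Total samples (split evenly into groups A and B).
#' @param n_assoc,n_indep,n_opposite Gene counts per truth category.
#' @param n_mirnas Number of shared miRNAs.
#' @param strength Latent correlation in (0, 1) between circRNA and
#'   associated genes.
#' @param seed Integer RNG seed.
#' @return List with `circ_expr` (named vector), `gene_expr` (matrix),
#'   `groups`, `circ_direction`, `circ_mirnas` (binding-site truth),
#'   `targets` (miRNA-gene map) and `truth` (per-gene category and
#'   associated flag).
#' @export
simulate_cerna <- function(n_samples = 30L, n_assoc = 10L, n_indep = 30L,
                           n_opposite = 10L, n_mirnas = 3L, strength = 0.8,
                           seed = 1L) {
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  with_seed(seed, {
    nA <- n_samples %/% 2L; nB <- n_samples - nA
    samples <- c(sprintf("A%02d", seq_len(nA)), sprintf("B%02d", seq_len(nB)))
    groups <- setNames(rep(c("A", "B"), c(nA, nB)), samples)
    shift <- 2
    z <- rnorm(n_samples) - shift * (groups == "A")
    expr_of <- function(latent) exp(1 + 0.7 * latent)
    circ <- setNames(expr_of(z), samples)
    n_genes <- n_assoc + n_indep + n_opposite
    category <- rep(c("associated", "independent", "opposite"),
                    c(n_assoc, n_indep, n_opposite))
    gene_ids <- sprintf("gene%03d", seq_len(n_genes))
    gene_expr <- matrix(0, n_genes, n_samples,
                        dimnames = list(gene_ids, samples))
    for (gi in seq_len(n_genes)) {
      lat <- switch(category[gi],
        associated = strength * z + sqrt(1 - strength^2) * rnorm(n_samples),
        independent = rnorm(n_samples),
        opposite = rnorm(n_samples) + shift * (groups == "A"))
      gene_expr[gi, ] <- expr_of(lat)
    }
    mir_ids <- sprintf("miR-%02d", seq_len(n_mirnas))
    targets <- data.frame(mirna = mir_ids[(seq_len(n_genes) - 1L) %% n_mirnas + 1L],
                          gene = gene_ids, stringsAsFactors = FALSE)
    circ_mirnas <- data.frame(mirna = mir_ids, n_sites = 2L,
                              stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = gene_ids, category = category,
                        associated = category == "associated",
                        stringsAsFactors = FALSE)
    list(circ_expr = circ, gene_expr = gene_expr, groups = groups,
         circ_direction = "down", circ_mirnas = circ_mirnas,
         targets = targets, truth = truth)
  })
}

#' Write a truth set's circle table as BED and TSV
#'
#' The BED columns mirror the catalog writer so truth and called catalogs
#' diff directly.
#'
#' @param truth A `circat_truth`.
#' @param tsv,bed Output paths (either may be `NULL`).
#' @export
write_truth <- function(truth, tsv = NULL, bed = NULL) {
  ci <- truth$circles
  if (!is.null(tsv)) write_tsv_versioned(ci, tsv, "planted circRNA truth set")
  if (!is.null(bed)) {
    bed_df <- data.frame(ci$chrom, ci$A, ci$D, ci$id, 0L, ci$strand,
                         ci$class, ci$structure, ci$signal, ci$shs_length)
    write.table(bed_df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(truth)
}
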