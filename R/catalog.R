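#' Aggregate split alignments into circRNA candidates
#'
#' Groups canonicalized split alignments from one or more samples by their
#' back-fusion point `(chrom, strand, A, D)`, counting distinct supporting
#' read pairs per sample.  Candidates whose support is below `min_support`
#' in every sample are dropped (default 2 reads, the detection-stage
#' threshold).
#'
#' @param alignments Named list of per-sample data.frames as returned by
#'   [detect_circles()] (a single data.frame is treated as one sample).
#' @param min_support Minimum per-sample supporting reads in the best
#'   sample.
#' @return A `circat_catalog` data.frame (`id`, `chrom`, `strand`, `A`,
#'   `D`) with the per-sample count matrix attached as attribute
#'   `"counts"` and accessible via [circ_counts()].  Candidate ids are
#'   deterministic `chrom_A_D_strand` strings.
#' @export
aggregate_candidates <- function(alignments, min_support = 2L) {
  if (is.data.frame(alignments)) alignments <- list(sample1 = alignments)
  if (is.null(names(alignments)))
    names(alignments) <- sprintf("sample%d", seq_along(alignments))
  tab <- list()
  for (sm in names(alignments)) {
    al <- alignments[[sm]]
    if (!nrow(al)) next
    al <- al[!duplicated(al$read_id), , drop = FALSE]  # one vote per pair
    key <- paste(al$chrom, al$A, al$D, al$strand, sep = "_")
    cnt <- table(key)
    tab[[sm]] <- data.frame(sample = sm, id = names(cnt),
                            count = as.integer(cnt), stringsAsFactors = FALSE)
  }
  empty <- data.frame(id = character(), chrom = character(), strand = character(),
                      A = integer(), D = integer(), stringsAsFactors = FALSE)
  if (!length(tab)) {
    attr(empty, "counts") <- matrix(0L, 0, length(alignments),
                                    dimnames = list(NULL, names(alignments)))
    class(empty) <- c("circat_catalog", "data.frame")
    return(empty)
  }
  long <- do.call(rbind, tab)
  ids <- sort(unique(long$id))
  counts <- matrix(0L, length(ids), length(alignments),
                   dimnames = list(ids, names(alignments)))
  counts[cbind(match(long$id, ids), match(long$sample, names(alignments)))] <- long$count
  keep <- apply(counts, 1, max) >= min_support
  counts <- counts[keep, , drop = FALSE]
  if (!nrow(counts)) {
    attr(empty, "counts") <- counts
    class(empty) <- c("circat_catalog", "data.frame")
    return(empty)
  }
  parts <- strsplit(rownames(counts), "_")
  cat_df <- data.frame(
    id = rownames(counts),
    chrom = vapply(parts, function(p) paste(p[seq_len(length(p) - 3L)], collapse = "_"),
                   character(1)),
    strand = vapply(parts, function(p) p[length(p)], character(1)),
    A = as.integer(vapply(parts, function(p) p[length(p) - 2L], character(1))),
    D = as.integer(vapply(parts, function(p) p[length(p) - 1L], character(1))),
    stringsAsFactors = FALSE)
  ord <- order(cat_df$chrom, cat_df$A, cat_df$D, cat_df$strand)
  cat_df <- cat_df[ord, , drop = FALSE]
  rownames(cat_df) <- NULL
  attr(cat_df, "counts") <- counts[ord, , drop = FALSE]
  class(cat_df) <- c("circat_catalog", "data.frame")
  cat_df
}

#' Per-sample support counts of a catalog
#' @param catalog A `circat_catalog`.
#' @return Integer matrix, candidates x samples.
#' @export
circ_counts <- function(catalog) attr(catalog, "counts")

#' @export
print.circat_catalog <- function(x, ...) {
  cat("circat catalog:", nrow(x), "candidate(s) across",
      ncol(circ_counts(x) %||% matrix(nrow = 0, ncol = 0)), "sample(s)\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Classify a back-fusion point against exon boundaries
#'
#' Both back-fusion points within `boundary_tolerance` of an annotated
#' exon boundary gives `canonical`; exactly one gives `partial_icirc`;
#' neither gives `complete_icirc`.
#'
#' @param ann A `circat_annotation`.
#' @param chrom,strand,A,D The candidate junction.
#' @param fparams A [feature_params()] object (tolerance and strand
#'   awareness).
#' @return One of `"canonical"`, `"partial_icirc"`, `"complete_icirc"`.
#' @export
classify_bf <- function(ann, chrom, strand, A, D, fparams = feature_params()) {
  tol <- fparams$boundary_tolerance
  aware <- fparams$boundary_strand_aware
  at <- c(boundary_distance(ann, chrom, strand, A, strand_aware = aware) <= tol,
          boundary_distance(ann, chrom, strand, D, strand_aware = aware) <= tol)
  switch(as.character(sum(at)), "2" = "canonical", "1" = "partial_icirc",
         "0" = "complete_icirc")
}

#' Structural category of a candidate circle
#'
#' A candidate is kept only when `[A, D)` lies within a single exon, a
#' single intron, a pair of adjacent exon and intron of one transcript
#' (either order), or wholly inside an intergenic interval; anything else
#' is `other` and excluded from the abundant set, since multi-feature
#' internal structure cannot be inferred reliably from junction reads.
#'
#' @param ann A `circat_annotation`.
#' @param chrom,A,D The candidate interval.
#' @return List with `structure` (one of `single_exon`, `single_intron`,
#'   `adjacent_exon_intron`, `intergenic`, `other`) and `kept` (logical).
#' @export
structural_category <- function(ann, chrom, A, D) {
  within <- function(df) any(df$chrom == chrom & df$start <= A & D <= df$end)
  if (within(ann$exons)) return(list(structure = "single_exon", kept = TRUE))
  if (within(ann$introns)) return(list(structure = "single_intron", kept = TRUE))
  # adjacent exon+intron of one transcript, either order
  intr <- ann$introns[ann$introns$chrom == chrom, , drop = FALSE]
  if (nrow(intr)) {
    for (i in seq_len(nrow(intr))) {
      tx <- intr$transcript_id[i]
      ex <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
      left_ex <- ex[ex$end == intr$start[i], , drop = FALSE]   # exon then intron
      right_ex <- ex[ex$start == intr$end[i], , drop = FALSE]  # intron then exon
      if (nrow(left_ex) && left_ex$start[1] <= A && D <= intr$end[i])
        return(list(structure = "adjacent_exon_intron", kept = TRUE))
      if (nrow(right_ex) && intr$start[i] <= A && D <= right_ex$end[1])
        return(list(structure = "adjacent_exon_intron", kept = TRUE))
    }
  }
  ig <- ann$intergenic
  if (any(ig$chrom == chrom & ig$start <= A & D <= ig$end))
    return(list(structure = "intergenic", kept = TRUE))
  list(structure = "other", kept = FALSE)
}

#' Short homologous sequence at a junction
#'
#' Measures the identical sequence shared by the two junction flanks:
#' `f` is the longest forward match `genome[A, A+h) == genome[D, D+h)` and
#' `b` the longest backward match `genome[A-h, A) == genome[D-h, D)`; the
#' SHS length is `f + b` and its sequence spans `[A-b, A+f)`.  A junction
#' inside an SHS has an ambiguous exact split position, the footprint
#' expected from template switching.
#'
#' @param genome A `circat_genome`.
#' @param chrom,A,D The candidate junction (canonical coordinates).
#' @param max_len Scan cap per direction.
#' @return List with `shs_length`, `shs_sequence`, `f`, `b`.
#' @export
detect_shs <- function(genome, chrom, A, D, max_len = 60L) {
  len <- genome_length(genome, chrom)
  sq <- genome$seqs[[chrom]]
  f <- 0L
  while (f < max_len && D + f < len && A + f < D &&
         substr(sq, A + f + 1L, A + f + 1L) == substr(sq, D + f + 1L, D + f + 1L))
    f <- f + 1L
  b <- 0L
  while (b < max_len && A - b > 0L && D - b > A &&
         substr(sq, A - b, A - b) == substr(sq, D - b, D - b))
    b <- b + 1L
  list(shs_length = f + b,
       shs_sequence = if (f + b > 0L) substr(sq, A - b + 1L, A + f) else "",
       f = f, b = b)
}

#' Splicing signal at a junction
#'
#' TRUE iff for some shift of the junction within its homology window the
#' donor dinucleotide immediately 3' of `D` is GT and the acceptor
#' dinucleotide immediately 5' of `A` is AG, on the candidate's strand
#' (reverse-complemented for "-": `AC` before `A` and `CT` after `D` on
#' the forward genome).  The result is therefore invariant to the
#' canonical-split choice.
#'
#' @param genome A `circat_genome`.
#' @param chrom,strand,A,D The candidate junction.
#' @param fparams A [feature_params()] object; `splice_signals` lists the
#'   accepted donor-acceptor dinucleotide pairs (canonical GT-AG default).
#' @return Logical.
#' @export
splice_signal <- function(genome, chrom, strand, A, D, fparams = feature_params()) {
  len <- genome_length(genome, chrom)
  shs <- detect_shs(genome, chrom, A, D, fparams$shs_max)
  sq <- genome$seqs[[chrom]]
  for (t in (-shs$b):shs$f) {
    a <- A + t; d <- D + t
    if (a < 2L || d + 2L > len) next
    up <- substr(sq, a - 1L, a)      # 2 nt 5' of acceptor
    dn <- substr(sq, d + 1L, d + 2L) # 2 nt 3' of donor
    for (sig in fparams$splice_signals) {
      donor <- sig[1]; acceptor <- sig[2]
      hit <- if (strand == "+") dn == donor && up == acceptor
             else up == rc(donor) && dn == rc(acceptor)
      if (hit) return(TRUE)
    }
  }
  FALSE
}

#' Reverse-complementary pairing of the junction flanks
#'
#' Finds the longest exact reverse-complement match between the upstream
#' flank `[A - flank_window, A)` and the downstream flank
#' `[D, D + flank_window)` (truncated at chromosome ends), the fold-back
#' geometry that can bring the two junction sides together.
#'
#' @param genome A `circat_genome`.
#' @param chrom,A,D The candidate junction.
#' @param fparams A [feature_params()] object.
#' @return `NULL` when the best match is shorter than
#'   `fparams$flank_min_match`; otherwise a list with `length`,
#'   `up_start`, `up_end`, `down_start`, `down_end` (genomic, 0-based
#'   half-open).
#' @export
flank_complementarity <- function(genome, chrom, A, D, fparams = feature_params()) {
  len <- genome_length(genome, chrom)
  w <- fparams$flank_window
  us <- max(0L, A - w); ue <- A
  ds <- D; de <- min(len, D + w)
  if (ue <= us || de <= ds) return(NULL)
  up <- genome_subseq(genome, chrom, us, ue)
  down <- genome_subseq(genome, chrom, ds, de)
  m <- cpp_longest_rc_match(up, down)
  if (m[1] < fparams$flank_min_match) return(NULL)
  mlen <- m[1]
  up_end <- us + m[2]
  # position in rc(down) maps back to down coordinates from the right end
  down_start <- ds + (nchar(down) - m[3])
  list(length = mlen, up_start = up_end - mlen, up_end = up_end,
       down_start = down_start, down_end = down_start + mlen)
}

#' Containments and multi-circRNA host genes
#'
#' Lists proper containments `(outer, inner)` between candidates on the
#' same chromosome and strand, and host genes producing two or more
#' candidates.
#'
#' @param catalog An annotated `circat_catalog` (needs the `host_genes`
#'   column from [annotate_catalog()] for the multi-circle gene report;
#'   containments need only coordinates).
#' @return List with `containments` (data.frame `outer`, `inner`) and
#'   `multi_circle_genes` (data.frame `gene_id`, `n_circles`).
#' @export
find_nestings <- function(catalog) {
  cont <- list()
  if (nrow(catalog) > 1L) {
    for (i in seq_len(nrow(catalog))) for (j in seq_len(nrow(catalog))) {
      if (i == j) next
      if (catalog$chrom[i] == catalog$chrom[j] &&
          catalog$strand[i] == catalog$strand[j] &&
          catalog$A[i] <= catalog$A[j] && catalog$D[j] <= catalog$D[i] &&
          (catalog$A[i] < catalog$A[j] || catalog$D[j] < catalog$D[i]))
        cont[[length(cont) + 1L]] <- data.frame(outer = catalog$id[i],
                                                inner = catalog$id[j],
                                                stringsAsFactors = FALSE)
    }
  }
  containments <- if (length(cont)) do.call(rbind, cont)
    else data.frame(outer = character(), inner = character())
  multi <- data.frame(gene_id = character(), n_circles = integer())
  if (!is.null(catalog$host_genes)) {
    genes <- unlist(strsplit(catalog$host_genes[catalog$host_genes != ""], ","))
    if (length(genes)) {
      tb <- table(genes)
      tb <- tb[tb >= 2L]
      if (length(tb)) multi <- data.frame(gene_id = names(tb),
                                          n_circles = as.integer(tb),
                                          stringsAsFactors = FALSE)
    }
  }
  list(containments = containments, multi_circle_genes = multi)
}

#' Annotate a catalog with class, structure and junction features
#'
#' Adds per-candidate classification (`class`), structural category and
#' keep flag, host genes (any gene whose span contains the circle; all
#' recorded), splicing-signal flag, SHS length and sequence, and flank
#' complementarity length.
#'
#' @param catalog A `circat_catalog` from [aggregate_candidates()].
#' @param genome A `circat_genome`.
#' @param ann A `circat_annotation`.
#' @param fparams A [feature_params()] object.
#' @return The catalog with feature columns appended (counts attribute
#'   preserved).
#' @export
annotate_catalog <- function(catalog, genome, ann, fparams = feature_params()) {
  n <- nrow(catalog)
  cls <- structure_lab <- host <- shs_seq <- character(n)
  kept <- sig <- logical(n)
  shs_len <- flank_len <- integer(n)
  for (i in seq_len(n)) {
    ch <- catalog$chrom[i]; st <- catalog$strand[i]
    A <- catalog$A[i]; D <- catalog$D[i]
    cls[i] <- classify_bf(ann, ch, st, A, D, fparams)
    sc <- structural_category(ann, ch, A, D)
    structure_lab[i] <- sc$structure; kept[i] <- sc$kept
    g <- ann$genes
    hg <- g$gene_id[g$chrom == ch & g$start <= A & D <= g$end]
    host[i] <- paste(hg, collapse = ",")
    sig[i] <- splice_signal(genome, ch, st, A, D, fparams)
    shs <- detect_shs(genome, ch, A, D, fparams$shs_max)
    shs_len[i] <- shs$shs_length; shs_seq[i] <- shs$shs_sequence
    fl <- flank_complementarity(genome, ch, A, D, fparams)
    flank_len[i] <- if (is.null(fl)) 0L else fl$length
  }
  counts <- circ_counts(catalog)
  catalog$class <- cls
  catalog$structure <- structure_lab
  catalog$kept <- kept
  catalog$host_genes <- host
  catalog$has_splice_signal <- sig
  catalog$shs_length <- shs_len
  catalog$shs_sequence <- shs_seq
  catalog$flank_pairing_length <- flank_len
  attr(catalog, "counts") <- counts
  class(catalog) <- c("circat_catalog", "data.frame")
  catalog
}

#' Write / read a circRNA catalog
#'
#' `write_catalog()` writes the full annotated table as versioned TSV and
#' optionally a BED6+ companion (chrom, A, D, id, max support, strand,
#' class, structure, signal, SHS length).  `read_catalog()` re-ingests the
#' TSV, restoring the count matrix.
#'
#' @param catalog An annotated `circat_catalog`.
#' @param path Output TSV path.
#' @param bed Optional BED output path.
#' @return The path, invisibly.
#' @export
write_catalog <- function(catalog, path, bed = NULL) {
  counts <- circ_counts(catalog)
  df <- as.data.frame(catalog)
  if (!is.null(counts) && ncol(counts))
    for (sm in colnames(counts)) df[[paste0("count.", sm)]] <- counts[, sm]
  write_tsv_versioned(df, path, "circRNA catalog")
  if (!is.null(bed)) {
    maxsup <- if (!is.null(counts) && ncol(counts)) apply(counts, 1, max) else 0L
    bed_df <- data.frame(catalog$chrom, catalog$A, catalog$D, catalog$id,
                         maxsup, catalog$strand,
                         catalog$class %||% "", catalog$structure %||% "",
                         catalog$has_splice_signal %||% "",
                         catalog$shs_length %||% "")
    write.table(bed_df, bed, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read_tsv_versioned(path)
  cc <- grep("^count\\.", names(df))
  counts <- as.matrix(df[, cc, drop = FALSE])
  colnames(counts) <- sub("^count\\.", "", colnames(counts))
  rownames(counts) <- df$id
  df <- df[, setdiff(seq_along(df), cc), drop = FALSE]
  attr(df, "counts") <- counts
  class(df) <- c("circat_catalog", "data.frame")
  df
}
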