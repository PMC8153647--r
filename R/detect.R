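#' End-to-end (linear) read mapping
#'
#' Maps reads contiguously to the genome in both orientations with at most
#' `max_mismatches` substitutions.  Reads that place are linear-RNA reads
#' and are excluded from the circRNA search; reads with more than
#' `max_n_frac` N bases are classified unmappable without search.
#'
#' @param reads Character vector of read sequences.
#' @param genome A `circat_genome`.
#' @param params A [detection_params()] object.
#' @return data.frame with one row per read: `mapped`, `chrom`, `start`
#'   (0-based), `orientation` ("fwd"/"rev"), `mismatches`, `n_hits`, and
#'   `n_excess` (TRUE when the read was skipped for N content).
#' @export
map_linear <- function(reads, genome, params = detection_params()) {
  if (any(nchar(reads) < 2L * params$anchor_length))
    stop("read shorter than twice the anchor length")
  n_frac <- nchar(gsub("[^N]", "", reads)) / nchar(reads)
  excess <- n_frac > params$max_n_frac
  out <- data.frame(mapped = rep(FALSE, length(reads)), chrom = NA_character_,
                    start = NA_integer_, orientation = NA_character_,
                    mismatches = NA_integer_, n_hits = 0L, n_excess = excess,
                    stringsAsFactors = FALSE)
  todo <- which(!excess)
  if (length(todo)) {
    res <- cpp_map_linear_batch(genome_index(genome), reads[todo],
                                params$max_mismatches)
    out$mapped[todo] <- res$mapped
    out$chrom[todo] <- names(genome$seqs)[res$chrom]
    out$start[todo] <- res$start
    out$orientation[todo] <- as.character(res$orientation)
    out$mismatches[todo] <- res$mismatches
    out$n_hits[todo] <- res$n_hits
  }
  out
}

#' Extract left and right anchors from a read
#'
#' The left anchor is the first `x` bases (read 5' end), the right anchor
#' the last `x` bases (read 3' end).  Reads shorter than `2x` cannot be
#' anchored and return `NULL`.
#'
#' @param read Read sequence (character scalar).
#' @param x Anchor length in nt.
#' @return List with elements `left` and `right`, or `NULL` if the read is
#'   too short (a message is emitted).
#' @export
extract_anchors <- function(read, x = 20L) {
  L <- nchar(read)
  if (L < 2L * x) {
    message("read of length ", L, " skipped: shorter than 2 * anchor length")
    return(NULL)
  }
  list(left = substr(read, 1L, x), right = substr(read, L - x + 1L, L))
}

#' Place an anchor on the genome with a uniqueness score
#'
#' Finds all placements of an anchor with up to `max_mismatches + 2`
#' substitutions and derives a pseudo-MAPQ per placement from the gap to
#' the best competing placement: 40 when the runner-up carries at least
#' two more mismatches, 0 when tied, linear in between.  Only placements
#' within the mismatch budget are returned.
#'
#' @param genome A `circat_genome`.
#' @param anchor Anchor sequence.
#' @param params A [detection_params()] object.
#' @param max_hits Guard against low-complexity anchors: more competing
#'   placements than this returns an empty table.
#' @return data.frame with `chrom`, `start` (0-based), `mismatches`,
#'   `uniqueness`.
#' @export
find_anchor_hits <- function(genome, anchor, params = detection_params(),
                             max_hits = 200L) {
  pl <- cpp_placements(genome_index(genome), anchor, params$max_mismatches + 2L)
  empty <- data.frame(chrom = character(), start = integer(),
                      mismatches = integer(), uniqueness = numeric())
  if (!nrow(pl) || nrow(pl) > max_hits) return(empty)
  uniq <- vapply(seq_len(nrow(pl)), function(i) {
    others <- pl$mismatches[-i]
    second <- if (length(others)) min(others) else Inf
    max(0, min(40, 20 * (second - pl$mismatches[i])))
  }, numeric(1))
  keep <- pl$mismatches <= params$max_mismatches
  data.frame(chrom = names(genome$seqs)[pl$chrom[keep]],
             start = pl$start[keep], mismatches = pl$mismatches[keep],
             uniqueness = uniq[keep], stringsAsFactors = FALSE)
}

#' Pair anchor placements in reversed (back-fusion) orientation
#'
#' Keeps pairs on the same chromosome where the left anchor places
#' strictly downstream of the right anchor -- the geometry of a read
#' crossing a back-fusion junction, and the opposite of a forward splice.
#' Both anchors must pass the uniqueness threshold, and the implied circle
#' span must not exceed `max_span`.
#'
#' @param left_hits,right_hits Hit tables from [find_anchor_hits()].
#' @param read_length Full read length L (needed for the implied span
#'   `left_start - right_start + L - anchor_length`).
#' @param params A [detection_params()] object.
#' @return data.frame with `chrom`, `left_start`, `right_start`, `span`.
#' @export
find_reversed_anchor_pairs <- function(left_hits, right_hits, read_length,
                                       params = detection_params()) {
  empty <- data.frame(chrom = character(), left_start = integer(),
                      right_start = integer(), span = integer())
  lh <- left_hits[left_hits$uniqueness >= params$min_anchor_mapq, , drop = FALSE]
  rh <- right_hits[right_hits$uniqueness >= params$min_anchor_mapq, , drop = FALSE]
  if (!nrow(lh) || !nrow(rh)) return(empty)
  pairs <- merge(lh[, c("chrom", "start")], rh[, c("chrom", "start")],
                 by = "chrom", suffixes = c("_left", "_right"))
  if (!nrow(pairs)) return(empty)
  span <- pairs$start_left - pairs$start_right + read_length - params$anchor_length
  keep <- pairs$start_left > pairs$start_right & span <= params$max_span
  data.frame(chrom = pairs$chrom[keep], left_start = pairs$start_left[keep],
             right_start = pairs$start_right[keep], span = span[keep],
             stringsAsFactors = FALSE)
}

#' Canonical split choice among equivalent split offsets
#'
#' When the junction lies inside a short homologous sequence several split
#' offsets produce valid alignments of the same read; all describe the
#' same circle shifted within the homology.  The canonical representative
#' is the smallest (leftmost) valid offset, so reads split anywhere in the
#' window aggregate to one back-fusion point.  A non-contiguous valid set
#' is unexpected (logged) and resolved the same way.
#'
#' @param valid_s Integer vector of valid split offsets (non-empty).
#' @return The canonical offset.
#' @export
canonicalize <- function(valid_s) {
  if (!length(valid_s)) stop("canonicalize() requires at least one valid split")
  valid_s <- sort(unique(as.integer(valid_s)))
  if (length(valid_s) > 1L && any(diff(valid_s) != 1L))
    warning("non-contiguous valid split set; keeping the smallest offset")
  valid_s[1L]
}

#' Resolve the back-fusion split point for one anchor pair
#'
#' Enumerates every split offset `s` in `[x, L - x]`; at offset `s` the
#' read prefix `read[0:s)` must align ending at donor `D = left_start + s`
#' and the suffix `read[s:L)` must align starting at acceptor
#' `A = right_start + x - L + s`, with combined mismatches within budget.
#' All valid offsets are recorded as the shift window; the canonical
#' (leftmost) offset defines the reported `(A, D)`.
#'
#' @param read Read sequence.
#' @param genome A `circat_genome`.
#' @param chrom Chromosome name.
#' @param left_start,right_start 0-based anchor placements from
#'   [find_reversed_anchor_pairs()].
#' @param params A [detection_params()] object.
#' @return A `split_alignment` list (`chrom`, `A`, `D`, `split_offset`,
#'   `valid_s`, `shift_window`, `mismatches`) or `NULL` when no valid
#'   split exists.
#' @export
resolve_split_point <- function(read, genome, chrom, left_start, right_start,
                                params = detection_params()) {
  L <- nchar(read); x <- params$anchor_length
  idx <- genome_index(genome)
  ci <- match(chrom, names(genome$seqs))
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  mmL <- cpp_diag_mismatch(idx, ci, left_start, read)
  mmR <- cpp_diag_mismatch(idx, ci, right_start + x - L, read)
  cumL <- cumsum(mmL)
  cumR <- cumsum(mmR)
  totR <- cumR[L]
  s_all <- x:(L - x)
  total <- cumL[s_all] + (totR - cumR[s_all])
  A <- right_start + x - L + s_all
  D <- left_start + s_all
  ok <- total <= params$max_mismatches & A >= 0L & D <= len & A < D &
    (D - A) <= params$max_span
  if (!any(ok)) return(NULL)
  # the split-offset window is the set of *minimum-mismatch* splits: under
  # a mismatch budget every 1-2 nt shift off the junction would otherwise
  # count as "valid", dragging the leftmost representative off the true
  # back-fusion point; at the minimum the window is exactly the junction
  # homology (width SHS + 1 on error-free reads)
  ok <- ok & total == min(total[ok])
  valid <- s_all[ok]
  s <- canonicalize(valid)
  structure(list(chrom = chrom,
                 A = right_start + x - L + s,
                 D = left_start + s,
                 split_offset = s,
                 valid_s = valid,
                 shift_window = range(valid),
                 mismatches = unname(total[match(s, s_all)])),
            class = "split_alignment")
}

#' Split-map one oriented read sequence
#'
#' The composed per-read operation: anchor extraction, reversed-orientation
#' anchor pairing and split-point resolution.  Returns the unique
#' `split_alignment`, or `NULL` when no valid split exists or distinct
#' canonical junctions compete (ambiguous placement).  A cheap prescreen
#' (placements within the mismatch budget only) rejects the overwhelmingly
#' common case -- linear spliced reads, whose anchors sit in forward
#' orientation -- before the wider-radius scan that placement uniqueness
#' scoring requires.
#'
#' @param seq Read sequence, already oriented (see [detect_circles()]).
#' @param genome A `circat_genome`.
#' @param params A [detection_params()] object.
#' @return A `split_alignment` list or `NULL`.
#' @export
split_map_read <- function(seq, genome, params = detection_params()) {
  anc <- suppressMessages(extract_anchors(seq, params$anchor_length))
  if (is.null(anc)) return(NULL)
  idx <- genome_index(genome)
  pre_l <- cpp_placements(idx, anc$left, params$max_mismatches)
  if (!nrow(pre_l)) return(NULL)
  pre_r <- cpp_placements(idx, anc$right, params$max_mismatches)
  if (!nrow(pre_r)) return(NULL)
  slack <- nchar(seq) - params$anchor_length
  reversed <- FALSE
  for (k in seq_len(nrow(pre_l))) {
    same <- pre_r$chrom == pre_l$chrom[k] & pre_r$start < pre_l$start[k] &
      pre_l$start[k] - pre_r$start + slack <= params$max_span
    if (any(same)) { reversed <- TRUE; break }
  }
  if (!reversed) return(NULL)
  lh <- find_anchor_hits(genome, anc$left, params)
  rh <- find_anchor_hits(genome, anc$right, params)
  pairs <- find_reversed_anchor_pairs(lh, rh, nchar(seq), params)
  if (!nrow(pairs)) return(NULL)
  hits <- list()
  for (i in seq_len(nrow(pairs))) {
    sa <- resolve_split_point(seq, genome, pairs$chrom[i], pairs$left_start[i],
                              pairs$right_start[i], params)
    if (!is.null(sa)) hits[[length(hits) + 1L]] <- sa
  }
  if (!length(hits)) return(NULL)
  keys <- vapply(hits, function(h) paste(h$chrom, h$A, h$D), character(1))
  if (length(unique(keys)) > 1L) return(NULL)  # ambiguous junction
  hits[[which.min(vapply(hits, `[[`, numeric(1), "mismatches"))]]
}

#' Check the mate-pair containment constraint
#'
#' A back-fusion candidate from one read of a pair is retained only when
#' the other read is consistent with the circle: either it maps end-to-end
#' entirely inside `[A, D)` in the orientation implied by the circle
#' strand, or (rotated-circle rule, for circles shorter than the
#' fragment) it split-maps to the same canonical junction.
#'
#' @param mate_sense The mate's sense-strand sequence (see
#'   [detect_circles()] for the library convention).
#' @param genome A `circat_genome`.
#' @param chrom,strand,A,D The candidate circle.
#' @param params A [detection_params()] object; `params$mate_mode`
#'   controls whether the rotated rule applies.
#' @return List with `ok` (logical) and `rotated` (logical flag).
#' @export
mate_within_circle <- function(mate_sense, genome, chrom, strand, A, D,
                               params = detection_params()) {
  oriented <- if (strand == "+") mate_sense else rc(mate_sense)
  L <- nchar(oriented)
  pl <- cpp_placements(genome_index(genome), oriented, params$max_mismatches)
  ci <- match(chrom, names(genome$seqs))
  inside <- nrow(pl) > 0 && any(pl$chrom == ci & pl$start >= A & pl$start + L <= D)
  if (inside) return(list(ok = TRUE, rotated = FALSE))
  if (params$mate_mode == "rotated") {
    sa <- split_map_read(oriented, genome, params)
    if (!is.null(sa) && sa$chrom == chrom && sa$A == A && sa$D == D)
      return(list(ok = TRUE, rotated = TRUE))
  }
  list(ok = FALSE, rotated = FALSE)
}

#' Detect back-fusion junctions from paired-end reads
#'
#' The full per-sample detection pass.  Reads mapping end-to-end are
#' discarded as linear RNA.  For each remaining pair, the unmapped mate is
#' split-mapped (anchors, reversed-orientation pairing, split resolution)
#' in both orientations, and a candidate junction is kept only when the
#' other mate satisfies the containment constraint.
#'
#' The library is assumed stranded dUTP-style (fr-firststrand): read 2
#' carries the transcript sense, read 1 its reverse complement.  Either
#' mate may be the split one; a junction found on the as-is sense sequence
#' is assigned strand "+", on its reverse complement strand "-".
#'
#' @param reads1,reads2 Character vectors of mate-1 / mate-2 sequences.
#' @param genome A `circat_genome`.
#' @param params A [detection_params()] object.
#' @param ids Optional read-pair identifiers.
#' @return data.frame of split alignments: `read_id`, `chrom`, `strand`,
#'   `A`, `D`, `split_offset`, `shift_lo`, `shift_hi`, `mismatches`,
#'   `split_mate`, `mate_rotated`.  A per-read decision log is attached as
#'   attribute `"log"`.
#' @export
detect_circles <- function(reads1, reads2, genome, params = detection_params(),
                           ids = NULL) {
  stopifnot(length(reads1) == length(reads2))
  n <- length(reads1)
  if (is.null(ids)) ids <- sprintf("pair%06d", seq_len(n))
  empty <- data.frame(read_id = character(), chrom = character(),
                      strand = character(), A = integer(), D = integer(),
                      split_offset = integer(), shift_lo = integer(),
                      shift_hi = integer(), mismatches = integer(),
                      split_mate = integer(), mate_rotated = logical(),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "log") <- data.frame(read_id = character(), decision = character())
    return(empty)
  }
  ml1 <- map_linear(reads1, genome, params)
  ml2 <- map_linear(reads2, genome, params)
  sense <- function(read, mate) if (mate == 2L) read else rc(read)

  rows <- list(); decisions <- character(n)
  for (i in seq_len(n)) {
    if (ml1$n_excess[i] || ml2$n_excess[i]) { decisions[i] <- "n_excess"; next }
    if (ml1$mapped[i] && ml2$mapped[i]) { decisions[i] <- "linear"; next }
    unmapped <- c(1L, 2L)[!c(ml1$mapped[i], ml2$mapped[i])]
    found <- FALSE
    for (m in unmapped) {
      rd <- if (m == 1L) reads1[i] else reads2[i]
      mate <- if (m == 1L) reads2[i] else reads1[i]
      S <- sense(rd, m)
      for (strand in c("+", "-")) {
        sa <- split_map_read(if (strand == "+") S else rc(S), genome, params)
        if (is.null(sa)) next
        chk <- mate_within_circle(sense(mate, 3L - m), genome, sa$chrom, strand,
                                  sa$A, sa$D, params)
        if (!chk$ok) { decisions[i] <- "mate_failed"; next }
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = ids[i], chrom = sa$chrom, strand = strand,
          A = sa$A, D = sa$D, split_offset = sa$split_offset,
          shift_lo = sa$shift_window[1], shift_hi = sa$shift_window[2],
          mismatches = sa$mismatches, split_mate = m,
          mate_rotated = chk$rotated, stringsAsFactors = FALSE)
        decisions[i] <- "bf_candidate"
        found <- TRUE
        break
      }
      if (found) break
    }
    if (!found && decisions[i] == "") decisions[i] <- "unresolved"
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "log") <- data.frame(read_id = ids, decision = decisions,
                                 stringsAsFactors = FALSE)
  out
}

#' Read candidate reads from a SAM text file
#'
#' Adapter for externally aligned data: extracts the unmapped-flag records
#' (flag bit 0x4) from a plain-text SAM file as the candidate pool for the
#' split-mapping stage, reorienting reverse-flag sequences.  Only the
#' columns the pipeline needs (name, flag, sequence) are used.
#'
#' @param path Path to a SAM text file.
#' @return data.frame with `read_id`, `mate` (1 or 2 from the pairing
#'   flags, NA for unpaired), `seq`.
#' @export
read_sam_unmapped <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln)) return(data.frame(read_id = character(), mate = integer(),
                                     seq = character()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  ok <- lengths(f) >= 10L
  f <- f[ok]
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  unmapped <- bitwAnd(flag, 4L) > 0L
  f <- f[unmapped]; flag <- flag[unmapped]
  seqs <- vapply(f, `[[`, character(1), 10L)
  rev <- bitwAnd(flag, 16L) > 0L
  seqs[rev] <- rc(seqs[rev])
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                 ifelse(bitwAnd(flag, 128L) > 0L, 2L, NA_integer_))
  data.frame(read_id = vapply(f, `[[`, character(1), 1L), mate = mate,
             seq = toupper(seqs), stringsAsFactors = FALSE)
}
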