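#' Load a reference genome from FASTA
#'
#' Reads a (possibly line-wrapped) FASTA file into an in-memory genome
#' object.  Sequences are uppercased on load; the alphabet is A, C, G, T, N.
#'
#' @param path Path to a FASTA file.
#' @return A `circat_genome` object: a list with `seqs` (named character
#'   vector of chromosome sequences) and `lengths` (named integer vector).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- load_genome(fa)
#' genome_length(g, "chr1")
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("duplicate chromosome name in FASTA: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  genome_from_seqs(setNames(toupper(as.character(ss)), nm))
}

#' Construct a genome object from named sequences
#'
#' @param seqs Named character vector, one uppercase DNA sequence per
#'   chromosome.
#' @return A `circat_genome` object.
#' @export
genome_from_seqs <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyDuplicated(names(seqs)))
    stop("chromosome names must be unique and non-empty")
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0L)) stop("every chromosome sequence must be non-empty")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN characters in chromosome(s): ",
                     paste(names(seqs)[bad], collapse = ", "))
  g <- list(seqs = seqs, lengths = setNames(nchar(seqs), names(seqs)))
  g$index_env <- new.env(parent = emptyenv())
  class(g) <- "circat_genome"
  g
}

#' @export
print.circat_genome <- function(x, ...) {
  cat("circat genome:", length(x$seqs), "chromosome(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "nt total\n")
  for (nm in head(names(x$seqs), 10))
    cat("  ", nm, ": ", format(x$lengths[[nm]], big.mark = ","), " nt\n", sep = "")
  invisible(x)
}

#' Chromosome length
#' @param genome A `circat_genome`.
#' @param chrom Chromosome name.
#' @export
genome_length <- function(genome, chrom) {
  if (!chrom %in% names(genome$lengths)) stop("unknown chromosome: ", chrom)
  unname(genome$lengths[[chrom]])
}

#' Extract a genomic subsequence
#'
#' Coordinates are 0-based half-open, the internal convention used
#' throughout the package.  Requests outside `[0, length)` are an error,
#' never silently clipped.
#'
#' @param genome A `circat_genome`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Character scalar.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  len <- genome_length(genome, chrom)
  if (start < 0 || end > len || start > end)
    stop(sprintf("subsequence [%d, %d) outside [0, %d) on %s", start, end, len, chrom))
  substr(genome$seqs[[chrom]], start + 1L, end)
}

#' Write a genome to FASTA
#' @param genome A `circat_genome`.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs), path)
  invisible(path)
}

# Seed index for the placement engine, built once per genome object and
# cached in its private environment.  Sequence edits must go through
# genome_from_seqs() (which allocates a fresh cache) so the index can
# never go stale.
genome_index <- function(genome) {
  env <- genome$index_env
  if (is.null(env$ptr))
    env$ptr <- cpp_build_index(unname(genome$seqs), names(genome$seqs))
  env$ptr
}
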