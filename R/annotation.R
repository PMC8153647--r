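#' Load a gene annotation from GTF
#'
#' Imports exon features from a GTF file (1-based inclusive coordinates per
#' the GTF standard), converts them to the package-internal 0-based
#' half-open convention, and derives introns, gene spans, intergenic
#' intervals and the per-strand set of exon boundary coordinates used for
#' circRNA classification.
#'
#' @param path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes on exon features.
#' @param genome A `circat_genome`; features on chromosomes absent from the
#'   genome, or extending past a chromosome end, are an error.
#' @return A `circat_annotation` object.
#' @export
load_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    ex <- data.frame(gene_id = character(), transcript_id = character(),
                     chrom = character(), strand = character(),
                     start = integer(), end = integer())
  } else {
    ex <- data.frame(
      gene_id = as.character(gr$gene_id),
      transcript_id = as.character(gr$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
  }
  annotation_from_exons(ex, genome)
}

#' Build an annotation from an exon table
#'
#' The programmatic constructor behind [load_annotation()], also used by
#' the synthetic-data generator.  Coordinates are 0-based half-open.
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand` ("+" or "-"), `start`, `end`.
#' @param genome A `circat_genome`.
#' @return A `circat_annotation` object with components `exons`,
#'   `transcripts`, `genes`, `introns`, `intergenic` and `boundaries`.
#' @export
annotation_from_exons <- function(exons, genome) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons)))
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  exons <- exons[order(exons$transcript_id, exons$start), need, drop = FALSE]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)

  bad_chr <- setdiff(unique(exons$chrom), names(genome$lengths))
  if (length(bad_chr)) stop("annotation chromosome(s) absent from genome: ",
                            paste(bad_chr, collapse = ", "))
  over <- exons$end > genome$lengths[exons$chrom] | exons$start < 0L
  if (any(over)) stop("exon extends past chromosome end (e.g. transcript ",
                      exons$transcript_id[which(over)[1]], ")")
  if (any(exons$end <= exons$start)) stop("empty or inverted exon interval")
  if (!all(exons$strand %in% c("+", "-"))) stop("exon strand must be '+' or '-'")

  introns <- NULL
  if (nrow(exons)) {
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    introns <- do.call(rbind, lapply(by_tx, function(ix) {
      e <- exons[ix, ]
      if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L)
        stop("transcript ", e$transcript_id[1], " spans chromosomes or strands")
      if (nrow(e) > 1L && any(e$start[-1] < e$end[-nrow(e)]))
        stop("overlapping or unsorted exons in transcript ", e$transcript_id[1])
      if (nrow(e) < 2L) return(NULL)
      data.frame(gene_id = e$gene_id[1], transcript_id = e$transcript_id[1],
                 chrom = e$chrom[1], strand = e$strand[1],
                 start = e$end[-nrow(e)], end = e$start[-1],
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(introns))
    introns <- data.frame(gene_id = character(), transcript_id = character(),
                          chrom = character(), strand = character(),
                          start = integer(), end = integer())
  rownames(introns) <- NULL

  agg <- function(df, key) {
    if (!nrow(df)) return(data.frame(id = character(), chrom = character(),
                                     strand = character(), start = integer(),
                                     end = integer()))
    sp <- split(seq_len(nrow(df)), df[[key]])
    out <- do.call(rbind, lapply(names(sp), function(k) {
      e <- df[sp[[k]], ]
      data.frame(id = k, chrom = e$chrom[1], strand = e$strand[1],
                 start = min(e$start), end = max(e$end), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }
  transcripts <- agg(exons, "transcript_id")
  names(transcripts)[1] <- "transcript_id"
  if (nrow(transcripts))
    transcripts$gene_id <- exons$gene_id[match(transcripts$transcript_id,
                                               exons$transcript_id)]
  genes <- agg(exons, "gene_id")
  names(genes)[1] <- "gene_id"

  # intergenic = complement of the union of gene spans, unstranded
  intergenic <- do.call(rbind, lapply(names(genome$lengths), function(chr) {
    len <- genome$lengths[[chr]]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (!nrow(g)) return(data.frame(chrom = chr, start = 0L, end = len))
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    gp <- IRanges::gaps(ir, start = 1L, end = len)
    if (!length(gp)) return(NULL)
    data.frame(chrom = chr, start = IRanges::start(gp) - 1L,
               end = IRanges::end(gp), stringsAsFactors = FALSE)
  }))
  if (is.null(intergenic))
    intergenic <- data.frame(chrom = character(), start = integer(), end = integer())
  rownames(intergenic) <- NULL

  # boundary set: exon starts and (half-open) ends, per chromosome and strand
  boundaries <- lapply(setNames(nm = names(genome$lengths)), function(chr) {
    lapply(setNames(nm = c("+", "-")), function(s) {
      e <- exons[exons$chrom == chr & exons$strand == s, , drop = FALSE]
      sort(unique(c(e$start, e$end)))
    })
  })

  ann <- list(exons = exons, transcripts = transcripts, genes = genes,
              introns = introns, intergenic = intergenic,
              boundaries = boundaries, seqlengths = genome$lengths)
  class(ann) <- "circat_annotation"
  check_partition(ann)
  ann
}

#' @export
print.circat_annotation <- function(x, ...) {
  cat("circat annotation:", nrow(x$genes), "gene(s),", nrow(x$transcripts),
      "transcript(s),", nrow(x$exons), "exon(s),", nrow(x$introns),
      "intron(s),", nrow(x$intergenic), "intergenic interval(s)\n")
  invisible(x)
}

#' Verify the genomic partition invariant
#'
#' Asserts that exonic, intronic and intergenic intervals jointly cover
#' every chromosome with no overlap between genic and intergenic space,
#' and that within each transcript the exons and derived introns tile the
#' transcript span exactly.  Called on every constructed annotation.
#'
#' @param ann A `circat_annotation`.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
check_partition <- function(ann) {
  for (chr in names(ann$seqlengths)) {
    len <- ann$seqlengths[[chr]]
    genic <- rbind(ann$exons[ann$exons$chrom == chr, c("start", "end")],
                   ann$introns[ann$introns$chrom == chr, c("start", "end")])
    inter <- ann$intergenic[ann$intergenic$chrom == chr, c("start", "end")]
    all_iv <- rbind(genic, inter)
    if (!nrow(all_iv)) stop("no intervals cover chromosome ", chr)
    cov <- IRanges::reduce(IRanges::IRanges(all_iv$start + 1L, all_iv$end))
    if (length(cov) != 1L || IRanges::start(cov) != 1L || IRanges::end(cov) != len)
      stop("partition violated on ", chr, ": union does not cover [0, ", len, ")")
    if (nrow(genic) && nrow(inter)) {
      ov <- IRanges::countOverlaps(IRanges::IRanges(inter$start + 1L, inter$end),
                                   IRanges::IRanges(genic$start + 1L, genic$end))
      if (any(ov > 0)) stop("intergenic interval overlaps genic feature on ", chr)
    }
  }
  for (tx in unique(ann$exons$transcript_id)) {
    e <- ann$exons[ann$exons$transcript_id == tx, ]
    i <- ann$introns[ann$introns$transcript_id == tx, ]
    tiles <- rbind(e[, c("start", "end")], i[, c("start", "end")])
    tiles <- tiles[order(tiles$start), ]
    if (any(tiles$start[-1] != tiles$end[-nrow(tiles)]))
      stop("exons and introns do not tile transcript ", tx)
  }
  invisible(TRUE)
}

#' Distance to the nearest exon boundary
#'
#' Returns the distance (nt) from `coord` to the closest annotated exon
#' start or end on the given chromosome and strand.  The distance is 0 iff
#' the coordinate is itself a boundary; a chromosome/strand with no
#' annotated exon yields `Inf`.
#'
#' @param ann A `circat_annotation`.
#' @param chrom Chromosome name.
#' @param strand `"+"`, `"-"`, or `"*"` for strand-agnostic lookup.
#' @param coord 0-based coordinate.
#' @param strand_aware If `FALSE`, boundaries from both strands are pooled
#'   regardless of `strand`.
#' @export
boundary_distance <- function(ann, chrom, strand, coord, strand_aware = TRUE) {
  if (!chrom %in% names(ann$boundaries)) stop("unknown chromosome: ", chrom)
  if (coord < 0 || coord > ann$seqlengths[[chrom]])
    stop("coordinate outside chromosome ", chrom)
  bset <- if (!strand_aware || identical(strand, "*"))
    sort(unique(c(ann$boundaries[[chrom]][["+"]], ann$boundaries[[chrom]][["-"]])))
  else ann$boundaries[[chrom]][[strand]]
  if (!length(bset)) return(Inf)
  min(abs(bset - coord))
}

#' Write an annotation back to GTF
#'
#' Exon rows only, with `gene_id` and `transcript_id` attributes;
#' coordinates are converted back to the 1-based inclusive GTF convention.
#' Re-loading the written file reproduces the identical interval sets.
#'
#' @param ann A `circat_annotation`.
#' @param path Output path.
#' @export
write_annotation <- function(ann, path) {
  e <- ann$exons
  gr <- GenomicRanges::GRanges(
    seqnames = e$chrom,
    ranges = IRanges::IRanges(e$start + 1L, e$end),
    strand = e$strand)
  gr$type <- "exon"
  gr$source <- "circat"
  gr$gene_id <- e$gene_id
  gr$transcript_id <- e$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write derived intervals to BED
#'
#' Writes exons, introns or intergenic intervals as 0-based half-open BED.
#'
#' @param ann A `circat_annotation`.
#' @param path Output path.
#' @param what One of `"exons"`, `"introns"`, `"intergenic"`.
#' @export
write_intervals_bed <- function(ann, path, what = c("exons", "introns", "intergenic")) {
  what <- match.arg(what)
  df <- ann[[what]]
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if (what == "intergenic") paste0("intergenic_", seq_len(nrow(df)))
                           else paste(df$transcript_id, what, seq_len(nrow(df)), sep = "_"),
                    score = 0L,
                    strand = if (what == "intergenic") "." else df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
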