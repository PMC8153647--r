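#' Detection parameters for the split-alignment core
#'
#' Defaults follow the published method: 20-nt anchors on 100-bp reads, at
#' most two mismatches for any end-to-end or combined split alignment, a
#' pseudo-mapping-quality threshold of 40 for both anchors, and at least
#' two supporting reads per back-fusion point at the detection stage.
#'
#' @param anchor_length Anchor size x in nt; both anchors have exactly this
#'   length and a read must satisfy `2 * anchor_length <= read length`.
#' @param max_mismatches Mismatch budget applied to each end-to-end mapping
#'   and to the combined split alignment (not per segment).
#' @param max_span Maximum circle span `D - A` in nt considered.
#' @param min_anchor_mapq Minimum placement-uniqueness pseudo-MAPQ (0-60
#'   scale; 40 requires the second-best placement to carry at least two
#'   more mismatches than the best).
#' @param min_support Minimum split-read support per back-fusion point for
#'   a candidate to be reported.
#' @param max_n_frac Reads with more than this fraction of N bases are
#'   classified unmappable without search.
#' @param mate_mode `"rotated"` accepts mates that themselves split-map to
#'   the same canonical junction (short circles); `"strict"` requires the
#'   mate fully inside `[A, D)`.
#' @return A `circat_detection_params` list.
#' @export
detection_params <- function(anchor_length = 20L, max_mismatches = 2L,
                             max_span = 100000L, min_anchor_mapq = 40,
                             min_support = 2L, max_n_frac = 0.1,
                             mate_mode = c("rotated", "strict")) {
  anchor_length <- stopifnot_scalar_int(anchor_length, "anchor_length", 6L)
  max_mismatches <- stopifnot_scalar_int(max_mismatches, "max_mismatches", 0L)
  max_span <- stopifnot_scalar_int(max_span, "max_span", 1L)
  if (min_anchor_mapq < 0 || min_anchor_mapq > 60) stop("min_anchor_mapq in [0, 60]")
  p <- list(anchor_length = anchor_length, max_mismatches = max_mismatches,
            max_span = max_span, min_anchor_mapq = min_anchor_mapq,
            min_support = stopifnot_scalar_int(min_support, "min_support", 1L),
            max_n_frac = max_n_frac, mate_mode = match.arg(mate_mode))
  class(p) <- "circat_detection_params"
  p
}

#' Abundance and differential-expression filter parameters
#'
#' Defaults follow the published analysis: a circRNA is abundant when at
#' least one sample supports it with `min_reads = 5` junction reads and it
#' appears (count >= 1) in at least `min_samples = 10` samples; rank-sum
#' differential expression uses raw p <= 0.01.
#'
#' @param min_reads k, minimum junction-read count in the best sample.
#' @param min_samples m, minimum number of samples the circRNA appears in.
#' @param de_alpha Raw p-value threshold for the rank-sum DE call
#'   (Benjamini-Hochberg adjusted values are always reported alongside).
#' @param pseudocount SRPBM pseudocount added to both group means for the
#'   fold-change ratio.
#' @return A `circat_filter_params` list.
#' @export
filter_params <- function(min_reads = 5L, min_samples = 10L, de_alpha = 0.01,
                          pseudocount = 0.1) {
  if (de_alpha <= 0 || de_alpha >= 1) stop("de_alpha in (0, 1)")
  p <- list(min_reads = stopifnot_scalar_int(min_reads, "min_reads", 1L),
            min_samples = stopifnot_scalar_int(min_samples, "min_samples", 1L),
            de_alpha = de_alpha, pseudocount = pseudocount)
  class(p) <- "circat_filter_params"
  p
}

#' Junction feature parameters
#'
#' @param boundary_tolerance Maximum nt distance to an annotated exon
#'   boundary for a back-fusion point to count as boundary-residing
#'   (default 0, exact).
#' @param boundary_strand_aware Classify against boundaries of the
#'   candidate's strand only (default) or of both strands.
#' @param shs_max Maximum short-homologous-sequence length scanned.
#' @param flank_window Flank width scanned for reverse-complementary
#'   pairing around the junction.
#' @param flank_min_match Minimum exact reverse-complement match length
#'   reported as a pairing.
#' @param splice_signals Donor-acceptor dinucleotide pairs accepted as a
#'   splicing signal (canonical GT-AG only by default).
#' @return A `circat_feature_params` list.
#' @export
feature_params <- function(boundary_tolerance = 0L, boundary_strand_aware = TRUE,
                           shs_max = 60L, flank_window = 200L,
                           flank_min_match = 8L,
                           splice_signals = list(c("GT", "AG"))) {
  p <- list(boundary_tolerance = as.integer(boundary_tolerance),
            boundary_strand_aware = isTRUE(boundary_strand_aware),
            shs_max = as.integer(shs_max),
            flank_window = as.integer(flank_window),
            flank_min_match = as.integer(flank_min_match),
            splice_signals = splice_signals)
  class(p) <- "circat_feature_params"
  p
}

#' ceRNA analysis parameters
#'
#' Defaults follow the published thresholds: target sites kept at duplex
#' score >= 140.0 and energy <= -1.0; association requires a shared miRNA,
#' Spearman rho > 0 with p < 0.01, and a concordant DE direction.
#'
#' @param score_threshold Minimum duplex score for a binding site.
#' @param energy_threshold Maximum (most permissive) duplex energy proxy.
#' @param cor_alpha Spearman p-value threshold.
#' @param require_concordance Require the gene's DE direction to match the
#'   circRNA's.
#' @return A `circat_cerna_params` list.
#' @export
cerna_params <- function(score_threshold = 140.0, energy_threshold = -1.0,
                         cor_alpha = 0.01, require_concordance = TRUE) {
  p <- list(score_threshold = score_threshold,
            energy_threshold = energy_threshold,
            cor_alpha = cor_alpha,
            require_concordance = isTRUE(require_concordance))
  class(p) <- "circat_cerna_params"
  p
}
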