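#' Spliced reads per billion mappings
#'
#' Normalizes a junction-read count by the sample's total mapped reads,
#' expressed per billion: `count * 1e9 / mapped_reads`.  Scale-invariant:
#' multiplying counts and library sizes by a common constant leaves the
#' value unchanged.
#'
#' @param count Junction-read count(s), >= 0.
#' @param mapped_reads Total mapped reads of the sample(s), > 0.
#' @return Numeric SRPBM value(s).
#' @examples
#' srpbm(5, 1e9)   # 5
#' srpbm(3, 5e8)   # 6
#' @export
srpbm <- function(count, mapped_reads) {
  if (any(mapped_reads <= 0)) stop("mapped_reads must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  count * 1e9 / mapped_reads
}

#' Construct a circRNA expression matrix
#'
#' @param counts Integer matrix, circRNAs x samples.
#' @param mapped_reads Named numeric vector of per-sample total mapped
#'   reads (library sizes).
#' @param groups Named character vector of per-sample group labels (e.g.
#'   PP / PN / NN).
#' @return A `circat_expr` object (list with `counts`, `mapped_reads`,
#'   `groups`, and an `srpbm` matrix view).
#' @export
expression_matrix <- function(counts, mapped_reads, groups) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  sm <- colnames(counts)
  if (!all(sm %in% names(mapped_reads)))
    stop("every sample needs a mapped-read total")
  if (!all(sm %in% names(groups))) stop("every sample needs a group label")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(mapped_reads[sm] <= 0)) stop("mapped-read totals must be positive")
  x <- list(counts = counts, mapped_reads = mapped_reads[sm],
            groups = groups[sm],
            srpbm = sweep(counts, 2, mapped_reads[sm], function(c, m) c * 1e9 / m))
  class(x) <- "circat_expr"
  x
}

#' @export
print.circat_expr <- function(x, ...) {
  cat("circat expression matrix:", nrow(x$counts), "circRNA(s) x",
      ncol(x$counts), "sample(s); groups:",
      paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Abundance filter for circRNA expression
#'
#' Retains circRNAs whose maximum per-sample junction-read count is at
#' least `min_reads` (k) and which appear -- count >= 1 -- in at least
#' `min_samples` (m) samples.
#'
#' @param expr A `circat_expr` object.
#' @param params A [filter_params()] object.
#' @return Character vector of retained circRNA ids.
#' @export
abundance_filter <- function(expr, params = filter_params()) {
  cm <- expr$counts
  keep <- apply(cm, 1, max) >= params$min_reads &
    rowSums(cm >= 1) >= params$min_samples
  rownames(cm)[keep]
}

#' Wilcoxon rank-sum test with exact tie-aware enumeration
#'
#' Two-sided rank-sum (Wilcoxon-Mann-Whitney) test on midranks.  When
#' `min(n)` is at most `exact_max_n` the p-value is computed by exact
#' enumeration of the permutation distribution (a count-distribution
#' dynamic program equivalent to listing all `choose(n1+n2, n1)` group
#' assignments, valid under ties); otherwise a tie-corrected normal
#' approximation (no continuity correction) is used.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param exact_max_n Largest `min(n)` for the exact path.
#' @return List with `statistic` (rank sum of `a`), `p` and `method`.
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))$p  # exactly 0.1
#' @export
ranksum_test <- function(a, b, exact_max_n = 12L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))  # midranks
  W <- sum(r[seq_len(n1)])
  if (min(n1, n2) <= exact_max_n) {
    p <- cpp_ranksum_exact_p(as.integer(round(2 * r)), n1, 2 * W)
    return(list(statistic = W, p = min(1, p), method = "exact"))
  }
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 * (N + 1) / 12 - n1 * n2 * tie_term / (12 * N * (N - 1))
  if (v <= 0) return(list(statistic = W, p = 1, method = "normal"))
  z <- (W - mu) / sqrt(v)
  list(statistic = W, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Differential expression of circRNAs by rank-sum test
#'
#' For each circRNA (rows of the abundance-filtered expression matrix),
#' SRPBM values of the two groups are compared with [ranksum_test()]; the
#' fold change is the ratio of pseudocounted group mean SRPBMs, and a
#' circRNA is flagged significant when the raw p-value is at or below
#' `de_alpha` (the published rule); Benjamini-Hochberg adjusted p-values
#' are reported alongside for FDR-based filtering.
#'
#' @param expr A `circat_expr` object (already abundance-filtered; use
#'   [abundance_filter()] to subset).
#' @param group_a,group_b Group labels to compare (A vs B; fold change is
#'   A over B).
#' @param params A [filter_params()] object.
#' @param ids Optional subset of circRNA ids to test.
#' @return A `circat_de` data.frame: `id`, `mean_srpbm_a`, `mean_srpbm_b`,
#'   `fold_change`, `direction`, `p`, `p_adj`, `significant`.
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    params = filter_params(), ids = NULL) {
  sel_a <- names(expr$groups)[expr$groups == group_a]
  sel_b <- names(expr$groups)[expr$groups == group_b]
  if (!length(sel_a) || !length(sel_b))
    stop("no samples in group ", if (!length(sel_a)) group_a else group_b)
  if (is.null(ids)) ids <- rownames(expr$counts)
  eps <- params$pseudocount
  res <- lapply(ids, function(id) {
    va <- expr$srpbm[id, sel_a]; vb <- expr$srpbm[id, sel_b]
    rt <- ranksum_test(va, vb)
    ma <- mean(va); mb <- mean(vb)
    fc <- (ma + eps) / (mb + eps)
    data.frame(id = id, mean_srpbm_a = ma, mean_srpbm_b = mb,
               fold_change = fc,
               direction = if (ma > mb) "up" else if (ma < mb) "down" else "none",
               p = rt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p <= params$de_alpha
  rownames(out) <- NULL
  class(out) <- c("circat_de", "data.frame")
  out
}

#' Load an external differentially-expressed-gene table
#'
#' Adapter for mRNA DE results computed by an external pipeline.  The TSV
#' must provide gene id, fold change and q-value columns (`gene_id` or
#' `id`; `fold_change`; `q_value`); a `direction` column is derived from
#' the fold change when absent.  Records failing `q < 0.05` or a 2-fold
#' change (ratio >= 2 or <= 0.5) are flagged not-DE.
#'
#' @param path Path to the TSV.
#' @param q_threshold,fc_threshold DE thresholds.
#' @return data.frame with `gene_id`, `fold_change`, `q_value`,
#'   `direction`, `de`.
#' @export
load_gene_de_table <- function(path, q_threshold = 0.05, fc_threshold = 2) {
  df <- read_tsv_versioned(path)
  if ("id" %in% names(df) && !"gene_id" %in% names(df))
    names(df)[names(df) == "id"] <- "gene_id"
  for (col in c("gene_id", "fold_change", "q_value"))
    if (!col %in% names(df)) stop("missing required column: ", col)
  if (!"direction" %in% names(df))
    df$direction <- ifelse(df$fold_change > 1, "up",
                           ifelse(df$fold_change < 1, "down", "none"))
  df$de <- df$q_value < q_threshold &
    (df$fold_change >= fc_threshold | df$fold_change <= 1 / fc_threshold)
  df[, c("gene_id", "fold_change", "q_value", "direction", "de")]
}

#' Write DE results as versioned TSV
#' @param de A `circat_de` data.frame.
#' @param path Output path.
#' @export
write_de_results <- function(de, path) {
  write_tsv_versioned(as.data.frame(de), path, "rank-sum DE results")
}
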