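# RNA alphabet normalization: targets and miRNAs may arrive as RNA (U) or
# DNA (T); everything is compared in DNA letters internally.
normalize_rna <- function(x) chartr("U", "T", toupper(x))

#' Scan a target sequence for miRNA binding sites
#'
#' Transparent seed-and-extend complementarity scorer.  Candidate sites
#' are anchored by Watson-Crick complementarity of the miRNA seed
#' (positions 2-8, at least 6 of the 7 positions pairing, no wobble
#' counted inside the seed) and scored over the full ungapped duplex:
#' +5 per Watson-Crick pair, +1 per G:U wobble, -4 per mismatch, with the
#' 5' half of the miRNA weighted twice.  The energy proxy is a pair-count
#' free-energy surrogate, `-(2 nGC + 1 nAU + 0.5 nGU)` kcal/mol-like
#' units.  Sites are kept at `score >= score_threshold` and
#' `energy <= energy_threshold`; overlapping sites are merged keeping the
#' best score.  Results are invariant to T/U alphabet choice.
#'
#' @param mirna Mature miRNA sequence, 5' to 3'.
#' @param target Target (circRNA or mRNA) sequence, 5' to 3'.
#' @param params A [cerna_params()] object (published default thresholds:
#'   score 140.0, energy -1.0).
#' @return data.frame of sites: `start`, `end` (0-based half-open on the
#'   target), `score`, `energy`.  Empty when the target is shorter than
#'   the miRNA.
#' @export
scan_targets <- function(mirna, target, params = cerna_params()) {
  mir <- normalize_rna(mirna); tg <- normalize_rna(target)
  m <- nchar(mir); n <- nchar(tg)
  empty <- data.frame(start = integer(), end = integer(), score = numeric(),
                      energy = numeric())
  if (n < m) return(empty)
  mv <- strsplit(mir, "")[[1]]
  tv <- strsplit(tg, "")[[1]]
  comp <- chartr("ACGT", "TGCA", mv)          # target base that WC-pairs mir
  half <- ceiling(m / 2)
  w <- ifelse(seq_len(m) <= half, 2, 1)
  seed_idx <- 2:8
  sites <- list()
  for (p in 0:(n - m)) {
    rsv <- tv[(p + m):(p + 1)]                # site read 3'->5' against mir 5'->3'
    wc <- comp == rsv
    if (sum(wc[seed_idx]) < 6L) next
    wob <- (mv == "G" & rsv == "T") | (mv == "T" & rsv == "G")
    wob <- wob & !wc
    score <- sum(w * ifelse(wc, 5, ifelse(wob, 1, -4)))
    if (score < params$score_threshold) next
    gc <- sum(wc & (mv == "G" | mv == "C"))
    au <- sum(wc & (mv == "A" | mv == "T"))
    energy <- -(2 * gc + 1 * au + 0.5 * sum(wob))
    if (energy > params$energy_threshold) next
    sites[[length(sites) + 1L]] <- c(p, p + m, score, energy)
  }
  if (!length(sites)) return(empty)
  df <- as.data.frame(do.call(rbind, sites))
  names(df) <- c("start", "end", "score", "energy")
  df <- df[order(df$start), , drop = FALSE]
  # merge overlapping sites, keeping the best-scoring representative
  merged <- df[1, , drop = FALSE]
  if (nrow(df) > 1) for (i in 2:nrow(df)) {
    last <- nrow(merged)
    if (df$start[i] < merged$end[last]) {
      if (df$score[i] > merged$score[last]) merged[last, ] <- df[i, ]
    } else merged <- rbind(merged, df[i, ])
  }
  rownames(merged) <- NULL
  merged$start <- as.integer(merged$start); merged$end <- as.integer(merged$end)
  merged
}

#' Scan a set of miRNAs against a set of targets
#'
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param targets Named character vector of target sequences.
#' @param kind Target kind label recorded in the output ("circRNA" or
#'   "mRNA").
#' @param params A [cerna_params()] object.
#' @return data.frame of hits: `mirna`, `target`, `kind`, `start`,
#'   `score`, `energy`.
#' @export
scan_target_set <- function(mirnas, targets, kind = c("mRNA", "circRNA"),
                            params = cerna_params()) {
  kind <- match.arg(kind)
  out <- list()
  for (mi in names(mirnas)) for (tg in names(targets)) {
    s <- scan_targets(mirnas[[mi]], targets[[tg]], params)
    if (nrow(s))
      out[[length(out) + 1L]] <- data.frame(mirna = mi, target = tg,
                                            kind = kind, start = s$start,
                                            score = s$score, energy = s$energy,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(mirna = character(), target = character(),
                                      kind = character(), start = integer(),
                                      score = numeric(), energy = numeric()))
  do.call(rbind, out)
}

#' Load externally predicted miRNA target sites
#'
#' Adapter for published-predictor output: a TSV with columns `miRNA`,
#' `target`, `position`, `score`, `energy`.  Duplicate
#' (miRNA, target, position) rows are collapsed, then the same thresholds
#' as [scan_targets()] are applied.
#'
#' @param path Path to the TSV.
#' @param params A [cerna_params()] object.
#' @param kind Target kind label.
#' @return data.frame in the [scan_target_set()] schema.
#' @export
load_external_targets <- function(path, params = cerna_params(),
                                  kind = c("mRNA", "circRNA")) {
  kind <- match.arg(kind)
  df <- read_tsv_versioned(path)
  need <- c("miRNA", "target", "position", "score", "energy")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(df$position) | is.na(suppressWarnings(as.numeric(df$score))) |
                 is.na(suppressWarnings(as.numeric(df$energy))) |
                 df$miRNA == "" | df$target == "")
  if (length(bad))
    stop("malformed row at data line ", bad[1], " of ", path)
  df <- df[!duplicated(df[, c("miRNA", "target", "position")]), , drop = FALSE]
  df <- df[df$score >= params$score_threshold &
             df$energy <= params$energy_threshold, , drop = FALSE]
  data.frame(mirna = df$miRNA, target = df$target, kind = kind,
             start = as.integer(df$position), score = as.numeric(df$score),
             energy = as.numeric(df$energy), stringsAsFactors = FALSE)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Midrank-based rho (tie-corrected, identical to Pearson correlation of
#' midranks).  The two-sided p-value uses the t approximation for
#' `n >= 10` and exact enumeration of the permutation distribution for
#' `n < 10` (tie-aware).  Zero variance in either vector leaves rho
#' undefined (`NA`, with a message); callers treat such pairs as
#' not-associated.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("spearman_cor requires n >= 4")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0) {
    message("zero variance in one vector: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (n < 10) {
    p <- cpp_spearman_perm_p(rx, ry)
    return(list(rho = rho, p = min(1, p), n = n, method = "exact"))
  }
  tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
  list(rho = rho, p = min(1, 2 * pt(-abs(tstat), n - 2)), n = n, method = "t")
}

#' Build circRNA-miRNA-mRNA association triples
#'
#' For each miRNA with a binding site on the circRNA and each
#' differentially expressed mRNA target of that miRNA, emits a candidate
#' ceRNA triple.  A triple is flagged `associated` when the gene's DE
#' direction is concordant with the circRNA's (positive ceRNA regulation;
#' relaxable via `params`), Spearman rho > 0 and p below `cor_alpha`.
#'
#' @param circ_id CircRNA identifier.
#' @param circ_hits Binding sites on the circRNA ([scan_target_set()]
#'   schema, kind "circRNA", rows for this circRNA).
#' @param gene_targets miRNA-to-mRNA target hits (same schema, kind
#'   "mRNA"), from [scan_target_set()] or [load_external_targets()].
#' @param de_genes DE gene table ([load_gene_de_table()] schema: columns
#'   `gene_id`, `direction`, `de`).
#' @param circ_expr Named numeric vector: circRNA expression per sample.
#' @param gene_expr Numeric matrix, genes x samples; column names must
#'   equal the circ samples.
#' @param circ_direction The circRNA's own DE direction ("up"/"down").
#' @param params A [cerna_params()] object.
#' @return A `cerna_triples` data.frame: `circ_id`, `mirna`, `gene_id`,
#'   `n_sites_circ`, `gene_direction`, `rho`, `p`, `associated`.
#' @export
associated_genes <- function(circ_id, circ_hits, gene_targets, de_genes,
                             circ_expr, gene_expr, circ_direction,
                             params = cerna_params()) {
  if (!setequal(names(circ_expr), colnames(gene_expr)))
    stop("sample sets of circRNA and gene expression disagree")
  gene_expr <- gene_expr[, names(circ_expr), drop = FALSE]
  empty <- data.frame(circ_id = character(), mirna = character(),
                      gene_id = character(), n_sites_circ = integer(),
                      gene_direction = character(), rho = numeric(),
                      p = numeric(), associated = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(circ_hits)) return(structure(empty, class = c("cerna_triples", "data.frame")))
  site_counts <- table(circ_hits$mirna)
  de_set <- de_genes[de_genes$de, , drop = FALSE]
  rows <- list()
  for (mi in names(site_counts)) {
    genes <- unique(gene_targets$target[gene_targets$mirna == mi])
    genes <- intersect(genes, de_set$gene_id)
    genes <- intersect(genes, rownames(gene_expr))
    for (g in genes) {
      sc <- spearman_cor(circ_expr, gene_expr[g, ])
      gdir <- de_set$direction[match(g, de_set$gene_id)]
      assoc <- !is.na(sc$rho) && sc$rho > 0 && !is.na(sc$p) &&
        sc$p < params$cor_alpha &&
        (!params$require_concordance || identical(gdir, circ_direction))
      rows[[length(rows) + 1L]] <- data.frame(
        circ_id = circ_id, mirna = mi, gene_id = g,
        n_sites_circ = as.integer(site_counts[[mi]]),
        gene_direction = gdir, rho = sc$rho, p = sc$p, associated = assoc,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  class(out) <- c("cerna_triples", "data.frame")
  out
}

#' Per-circRNA ceRNA cascade summary
#'
#' Summarizes triples per (circRNA, miRNA): binding sites on the circRNA,
#' mediated (associated) targets, and the miRNA's total targets, in the
#' "x out of y targets" report style.
#'
#' @param triples A `cerna_triples` data.frame.
#' @param total_targets Optional named integer vector of each miRNA's
#'   total target count (defaults to the targets present in `triples`).
#' @return data.frame: `circ_id`, `mirna`, `n_sites`, `mediated`,
#'   `total_targets`, `summary`.
#' @export
cascade_report <- function(triples, total_targets = NULL) {
  if (!nrow(triples))
    return(data.frame(circ_id = character(), mirna = character(),
                      n_sites = integer(), mediated = integer(),
                      total_targets = integer(), summary = character()))
  key <- paste(triples$circ_id, triples$mirna, sep = "\r")
  sp <- split(seq_len(nrow(triples)), key)
  out <- do.call(rbind, lapply(sp, function(ix) {
    t1 <- triples[ix, ]
    tot <- if (!is.null(total_targets) && t1$mirna[1] %in% names(total_targets))
      as.integer(total_targets[[t1$mirna[1]]]) else length(unique(t1$gene_id))
    med <- sum(t1$associated)
    data.frame(circ_id = t1$circ_id[1], mirna = t1$mirna[1],
               n_sites = t1$n_sites_circ[1], mediated = med,
               total_targets = tot,
               summary = sprintf("%d out of %d targets", med, tot),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$circ_id, out$mirna), , drop = FALSE]
}

#' Export ceRNA network edges
#'
#' Writes circRNA-miRNA and miRNA-gene edges of associated triples as a
#' two-column edge list for network tools.
#'
#' @param triples A `cerna_triples` data.frame.
#' @param path Output TSV path.
#' @export
write_cerna_edges <- function(triples, path) {
  t1 <- triples[triples$associated, , drop = FALSE]
  edges <- rbind(data.frame(from = t1$circ_id, to = t1$mirna,
                            type = "circ-miR", stringsAsFactors = FALSE),
                 data.frame(from = t1$mirna, to = t1$gene_id,
                            type = "miR-gene", stringsAsFactors = FALSE))
  edges <- edges[!duplicated(edges), , drop = FALSE]
  write_tsv_versioned(edges, path, "ceRNA network edges")
}
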