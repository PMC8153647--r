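#' Assemble a full run configuration
#'
#' Bundles the detection, abundance/DE, junction-feature and ceRNA
#' parameter sets with a seed into one serializable configuration whose
#' defaults are the published values (x = 20, 2 mismatches, MAPQ 40,
#' detection support 2, abundance k = 5 / m = 10, DE p <= 0.01, target
#' score 140.0 / energy -1.0, rho > 0 with p < 0.01).
#'
#' @param detection A [detection_params()] object.
#' @param filters A [filter_params()] object.
#' @param features A [feature_params()] object.
#' @param cerna A [cerna_params()] object.
#' @param seed Integer seed used by every stochastic stage.
#' @return A `circat_config` list.
#' @export
circat_config <- function(detection = detection_params(),
                          filters = filter_params(),
                          features = feature_params(),
                          cerna = cerna_params(), seed = 1L) {
  cfg <- list(detection = detection, filters = filters, features = features,
              cerna = cerna, seed = as.integer(seed))
  class(cfg) <- "circat_config"
  cfg
}

#' Write / read a run configuration as JSON
#' @param config A `circat_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- raw$features$splice_signals
  if (is.matrix(sig)) sig <- lapply(seq_len(nrow(sig)), function(i) sig[i, ])
  else if (!is.null(sig) && !is.list(sig)) sig <- list(sig)
  else if (is.list(sig)) sig <- lapply(sig, unlist)
  circat_config(
    detection = do.call(detection_params, raw$detection),
    filters = do.call(filter_params, raw$filters),
    features = do.call(feature_params,
                       modifyList(raw$features, list(splice_signals = sig))),
    cerna = do.call(cerna_params, raw$cerna),
    seed = raw$seed %||% 1L)
}

#' Simulate a complete detection fixture on disk
#'
#' Generates a seeded toy genome + annotation, plants the design's
#' circRNAs, simulates per-sample paired FASTQ files and writes genome
#' (FASTA), annotation (GTF), reads and the truth tables into `outdir`.
#'
#' @param outdir Output directory (created if needed).
#' @param design Planting design (see [plant_circles()]); defaults to the
#'   package's standard 30-circle validation design.
#' @param n_samples Number of samples to simulate.
#' @param config A `circat_config` (seed and feature parameters).
#' @param depth,linear_pairs,error_rate Passed to [simulate_reads()].
#' @return List with the truth set and the paths written.
#' @export
run_simulate <- function(outdir, design = default_circle_design(),
                         n_samples = 1L, config = circat_config(),
                         depth = 10L, linear_pairs = 1000L, error_rate = 0) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen <- make_genome(config$seed)
  truth <- plant_circles(gen$genome, gen$annotation, design, config$seed + 1L,
                         config$features)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                gtf = file.path(outdir, "annotation.gtf"),
                truth_tsv = file.path(outdir, "truth.tsv"),
                truth_bed = file.path(outdir, "truth.bed"))
  write_genome(truth$genome, paths$genome)
  write_annotation(truth$annotation, paths$gtf)
  write_truth(truth, tsv = paths$truth_tsv, bed = paths$truth_bed)
  paths$fastq <- list()
  for (s in seq_len(n_samples)) {
    sim <- simulate_reads(truth, depth = depth, linear_pairs = linear_pairs,
                          error_rate = error_rate, seed = config$seed + 100L + s,
                          anchor_length = config$detection$anchor_length)
    p1 <- file.path(outdir, sprintf("sample%02d_1.fastq", s))
    p2 <- file.path(outdir, sprintf("sample%02d_2.fastq", s))
    write_fastq_pair(sim, p1, p2)
    write_tsv_versioned(sim$provenance,
                        file.path(outdir, sprintf("sample%02d_provenance.tsv", s)),
                        "read provenance")
    paths$fastq[[sprintf("sample%02d", s)]] <- c(p1, p2)
  }
  list(truth = truth, paths = paths)
}

#' The standard 30-circle validation design
#'
#' 10 canonical single-exon circles, 10 complete interior circles (6 in
#' exons with SHS 0-3, 4 in introns), 5 partial interior circles and 5
#' intergenic circles (one carrying a 12-nt inverted flank repeat),
#' mirroring the structural categories retained by the detection
#' workflow.
#'
#' @return A design data.frame for [plant_circles()].
#' @export
default_circle_design <- function() {
  rbind(
    data.frame(class = "canonical", structure = "single_exon",
               shs_length = 0L, signal = TRUE, flank_repeat_length = 0L)[rep(1, 10), ],
    data.frame(class = "complete_icirc", structure = "single_exon",
               shs_length = c(0L, 0L, 2L, 2L, 3L, 0L), signal = FALSE,
               flank_repeat_length = 0L),
    data.frame(class = "complete_icirc", structure = "single_intron",
               shs_length = c(0L, 2L, 0L, 0L), signal = FALSE,
               flank_repeat_length = 0L),
    data.frame(class = "partial_icirc", structure = "single_exon",
               shs_length = 0L, signal = FALSE, flank_repeat_length = 0L)[rep(1, 5), ],
    data.frame(class = "complete_icirc", structure = "intergenic",
               shs_length = c(0L, 0L, 2L, 0L, 0L), signal = FALSE,
               flank_repeat_length = c(12L, 0L, 0L, 0L, 0L)))
}

#' Run detection on FASTQ samples
#'
#' Maps each sample's read pairs, split-maps the unmapped remainder,
#' aggregates back-fusion points across samples and annotates the catalog
#' with class, structure and junction features.  Writes per-sample split
#' tables, the merged catalog (TSV + BED) and a run manifest.
#'
#' @param samples Named list of `c(fastq1, fastq2)` paths.
#' @param genome_path FASTA path.
#' @param gtf_path GTF path.
#' @param outdir Output directory.
#' @param config A `circat_config`.
#' @return The annotated `circat_catalog`, invisibly; files in `outdir`.
#' @export
run_detect <- function(samples, genome_path, gtf_path, outdir,
                       config = circat_config()) {
  for (p in c(genome_path, gtf_path, unlist(samples)))
    if (!file.exists(p)) stop("input not found: ", p)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- load_genome(genome_path)
  ann <- load_annotation(gtf_path, genome)
  per_sample <- list()
  for (sm in names(samples)) {
    fq <- read_fastq_pair(samples[[sm]][1], samples[[sm]][2])
    if (!length(fq$reads1)) {
      warning("sample ", sm, " has no reads; empty split table")
      al <- detect_circles(character(), character(), genome, config$detection)
    } else {
      al <- detect_circles(fq$reads1, fq$reads2, genome, config$detection,
                           ids = fq$ids)
    }
    write_tsv_versioned(al, file.path(outdir, paste0(sm, "_splits.tsv")),
                        paste("split alignments for", sm))
    per_sample[[sm]] <- al
  }
  catalog <- aggregate_candidates(per_sample, config$detection$min_support)
  catalog <- annotate_catalog(catalog, genome, ann, config$features)
  write_catalog(catalog, file.path(outdir, "catalog.tsv"),
                bed = file.path(outdir, "catalog.bed"))
  manifest <- data.frame(
    key = c("circat_version", "seed", "anchor_length", "max_mismatches",
            "min_anchor_mapq", "min_support", "n_samples"),
    value = c(as.character(packageVersion("circat")), config$seed,
              config$detection$anchor_length, config$detection$max_mismatches,
              config$detection$min_anchor_mapq, config$detection$min_support,
              length(samples)))
  write_tsv_versioned(manifest, file.path(outdir, "manifest.tsv"), "run manifest")
  invisible(catalog)
}

#' Quantify and test differential expression from a catalog
#'
#' Builds the expression matrix from the catalog's per-sample counts and
#' a sample sheet (sample, group, mapped_reads), applies the abundance
#' filter and runs the rank-sum DE comparison.
#'
#' @param catalog_path Catalog TSV from [run_detect()].
#' @param sample_sheet data.frame or TSV path with columns `sample`,
#'   `group`, `mapped_reads`.
#' @param group_a,group_b Groups to compare.
#' @param outdir Output directory.
#' @param config A `circat_config`.
#' @return The `circat_de` table, invisibly.
#' @export
run_quant_de <- function(catalog_path, sample_sheet, group_a, group_b, outdir,
                         config = circat_config()) {
  if (!file.exists(catalog_path)) stop("catalog not found: ", catalog_path,
                                       " (run the detect stage first)")
  if (is.character(sample_sheet)) sample_sheet <- read_tsv_versioned(sample_sheet)
  for (col in c("sample", "group", "mapped_reads"))
    if (!col %in% names(sample_sheet)) stop("sample sheet missing column: ", col)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  catalog <- read_catalog(catalog_path)
  counts <- circ_counts(catalog)
  miss <- setdiff(colnames(counts), sample_sheet$sample)
  if (length(miss)) stop("sample(s) missing a mapped-read total: ",
                         paste(miss, collapse = ", "))
  expr <- expression_matrix(
    counts,
    setNames(sample_sheet$mapped_reads, sample_sheet$sample),
    setNames(sample_sheet$group, sample_sheet$sample))
  keep <- abundance_filter(expr, config$filters)
  de <- differential_expression(expr, group_a, group_b, config$filters,
                                ids = keep)
  write_tsv_versioned(data.frame(id = keep), file.path(outdir, "abundant.tsv"),
                      "abundance-filtered circRNAs")
  write_de_results(de, file.path(outdir, "de_results.tsv"))
  invisible(de)
}

#' Run the ceRNA association stage
#'
#' Scans miRNAs against circRNA and mRNA sequences (or ingests external
#' predictions), intersects with DE status and expression correlation,
#' and writes triples plus the per-circRNA cascade report.
#'
#' @param circ_seqs,mirna_seqs,gene_seqs Named character vectors of
#'   sequences (e.g. from [load_genome()]-style FASTA via
#'   `Biostrings::readDNAStringSet`).
#' @param de_circ A `circat_de` table for the circRNAs.
#' @param de_genes DE gene table ([load_gene_de_table()] schema).
#' @param circ_expr_mat,gene_expr_mat Expression matrices (rows = ids,
#'   columns = shared samples).
#' @param outdir Output directory.
#' @param config A `circat_config`.
#' @param external_targets Optional pre-computed target table
#'   ([load_external_targets()] schema) used instead of scanning.
#' @return The combined `cerna_triples` table, invisibly.
#' @export
run_cerna <- function(circ_seqs, mirna_seqs, gene_seqs, de_circ, de_genes,
                      circ_expr_mat, gene_expr_mat, outdir,
                      config = circat_config(), external_targets = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gene_hits <- if (is.null(external_targets))
    scan_target_set(mirna_seqs, gene_seqs, "mRNA", config$cerna)
  else external_targets
  all_triples <- list()
  for (cid in names(circ_seqs)) {
    circ_hits <- scan_target_set(mirna_seqs, circ_seqs[cid], "circRNA",
                                 config$cerna)
    if (!nrow(circ_hits)) next
    dd <- de_circ[de_circ$id == cid, , drop = FALSE]
    if (!nrow(dd) || !dd$significant[1]) next
    tr <- associated_genes(cid, circ_hits, gene_hits, de_genes,
                           circ_expr_mat[cid, ], gene_expr_mat,
                           dd$direction[1], config$cerna)
    if (nrow(tr)) all_triples[[cid]] <- tr
  }
  triples <- if (length(all_triples)) do.call(rbind, all_triples)
    else associated_genes("none", data.frame(mirna = character()),
                          data.frame(mirna = character(), target = character()),
                          data.frame(gene_id = character(),
                                     direction = character(), de = logical()),
                          setNames(numeric(ncol(gene_expr_mat)),
                                   colnames(gene_expr_mat)),
                          gene_expr_mat, "down", config$cerna)
  rownames(triples) <- NULL
  totals <- table(gene_hits$mirna[!duplicated(gene_hits[, c("mirna", "target")])])
  write_tsv_versioned(triples, file.path(outdir, "cerna_triples.tsv"),
                      "ceRNA triples")
  write_tsv_versioned(cascade_report(triples, setNames(as.integer(totals),
                                                       names(totals))),
                      file.path(outdir, "cascade_report.tsv"),
                      "ceRNA cascade report")
  write_cerna_edges(triples, file.path(outdir, "cerna_edges.tsv"))
  invisible(triples)
}
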