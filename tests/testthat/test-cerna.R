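# exhaustive window scorer independent of scan_targets: scores every
# target offset directly with the same published thresholds
window_scan_oracle <- function(mirna, target, score_min = 140, energy_max = -1) {
  mir <- chartr("U", "T", toupper(mirna)); tg <- chartr("U", "T", toupper(target))
  m <- nchar(mir); n <- nchar(tg)
  mv <- strsplit(mir, "")[[1]]
  comp <- chartr("ACGT", "TGCA", mv)
  out <- NULL
  if (n < m) return(out)
  for (p in 0:(n - m)) {
    site <- substr(tg, p + 1, p + m)
    rsv <- rev(strsplit(site, "")[[1]])
    wc <- comp == rsv
    if (sum(wc[2:8]) < 6) next
    wob <- ((mv == "G" & rsv == "T") | (mv == "T" & rsv == "G")) & !wc
    w <- ifelse(seq_len(m) <= ceiling(m / 2), 2, 1)
    score <- sum(w * ifelse(wc, 5, ifelse(wob, 1, -4)))
    energy <- -(2 * sum(wc & mv %in% c("G", "C")) +
                  sum(wc & mv %in% c("A", "T")) + 0.5 * sum(wob))
    if (score >= score_min && energy <= energy_max)
      out <- rbind(out, data.frame(start = p, score = score, energy = energy))
  }
  out
}

mir22 <- "UGAGGUAGUAGGUUGUAUAGUU"

test_that("a perfect full-length duplex is the scan's maximum and passes thresholds", {
  target <- paste0(strrep("AC", 30), rc_oracle(chartr("U", "T", mir22)),
                   strrep("GT", 30))
  hits <- scan_targets(mir22, target)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 60L)
  m <- nchar(mir22)
  expect_equal(hits$score, 5 * (2 * ceiling(m / 2) + (m - ceiling(m / 2))))
  expect_lte(hits$energy, -1)
  # T/U alphabet invariance on both inputs
  expect_equal(scan_targets(chartr("U", "T", mir22), chartr("T", "U", target)),
               hits)
  # a target shorter than the miRNA yields an empty table
  expect_equal(nrow(scan_targets(mir22, "ACGUACGU")), 0L)
})

test_that("planted sites are found where the exhaustive window scorer finds them", {
  set.seed(60)
  for (rep in 1:5) {
    bg <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
    site <- rc_oracle(chartr("U", "T", mir22))
    # distort one 3'-half position so the duplex is near- but not perfect
    substr(site, 3, 3) <- "A"
    pos <- 100L
    substr(bg, pos + 1L, pos + nchar(site)) <- site
    hits <- scan_targets(mir22, bg)
    orc <- window_scan_oracle(mir22, bg)
    expect_false(is.null(orc))
    expect_true(any(hits$start <= pos & pos < hits$end))
    expect_true(pos %in% orc$start)
    expect_equal(hits$score[hits$start == pos], orc$score[orc$start == pos])
  }
})

test_that("targets stripped of seed complements yield no sites", {
  set.seed(61)
  seed_rc <- rc_oracle(chartr("U", "T", substr(mir22, 2, 8)))
  repeat {
    bg <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
    if (!grepl(seed_rc, bg, fixed = TRUE)) break
  }
  expect_equal(nrow(scan_targets(mir22, bg)), 0L)
  expect_null(window_scan_oracle(mir22, bg))
})

test_that("external target tables are deduplicated, thresholded and validated", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(miRNA = c("m1", "m1", "m1", "m2"),
                   target = c("t1", "t1", "t2", "t1"),
                   position = c(10, 10, 50, 7),
                   score = c(150, 150, 120, 145),
                   energy = c(-12, -12, -20, -9))
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  hits <- load_external_targets(tsv)
  expect_equal(nrow(hits), 2L)  # dup collapsed, low score dropped
  expect_setequal(hits$mirna, c("m1", "m2"))
  df$position[2] <- NA
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_external_targets(tsv), "line 2")
  write.table(df[, -3], tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_external_targets(tsv), "position")
})

test_that("Spearman rho matches rank-then-Pearson to 1e-12 on tied and untied vectors", {
  expect_equal(spearman_cor(1:5, (1:5)^2)$rho, 1)
  expect_equal(spearman_cor(1:5, -(1:5))$rho, -1)
  expect_equal(spearman_cor(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4))$rho, 0.9)
  set.seed(70)
  for (rep in 1:300) {
    n <- sample(4:40, 1)
    x <- if (rep %% 3) rnorm(n) else sample(1:5, n, replace = TRUE)
    y <- if (rep %% 2) rnorm(n) else sample(1:4, n, replace = TRUE)
    if (var(rank(x)) == 0 || var(rank(y)) == 0) next
    got <- spearman_cor(x, y)
    expect_equal(got$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    if (got$n >= 10)
      expect_equal(got$p, cor.test(x, y, method = "spearman", exact = FALSE)$p.value,
                   tolerance = 1e-9)
  }
})

test_that("exact permutation p for n < 10 matches full enumeration", {
  set.seed(71)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    x <- rnorm(n)
    y <- if (rep %% 2) rnorm(n) else sample(1:3, n, replace = TRUE)
    if (var(rank(y)) == 0) next
    expect_equal(spearman_cor(x, y)$p, spearman_enum_p(x, y), tolerance = 1e-12)
  }
  expect_message(res <- spearman_cor(1:6, rep(1, 6)), "zero variance")
  expect_true(is.na(res$rho))
  expect_error(spearman_cor(1:3, 1:3), "n >= 4")
})

test_that("association triples enforce the shared-miRNA, correlation and concordance gates", {
  cs <- simulate_cerna(seed = 12)
  gde <- do.call(rbind, lapply(rownames(cs$gene_expr), function(g) {
    a <- cs$gene_expr[g, cs$groups == "A"]; b <- cs$gene_expr[g, cs$groups == "B"]
    rt <- ranksum_test(a, b)
    data.frame(gene_id = g,
               direction = if (mean(a) > mean(b)) "up" else "down",
               de = rt$p <= 0.01, stringsAsFactors = FALSE)
  }))
  circ_hits <- data.frame(mirna = rep(cs$circ_mirnas$mirna, cs$circ_mirnas$n_sites))
  gene_targets <- data.frame(mirna = cs$targets$mirna, target = cs$targets$gene)
  tr <- associated_genes("circX", circ_hits, gene_targets, gde, cs$circ_expr,
                         cs$gene_expr, cs$circ_direction)
  truth <- cs$truth
  assoc_called <- truth$gene_id %in% tr$gene_id[tr$associated]
  expect_gte(mean(assoc_called[truth$associated]), 0.8)
  expect_lte(mean(assoc_called[!truth$associated]), 0.05)
  # genes DE in the opposite direction are never associated
  opp <- truth$gene_id[truth$category == "opposite"]
  expect_false(any(tr$associated[tr$gene_id %in% opp]))
  # negative correlation blocks association even when gates would pass
  expect_false(any(tr$associated[!is.na(tr$rho) & tr$rho <= 0]))
  # sample mismatch is a hard error
  expect_error(associated_genes("circX", circ_hits, gene_targets, gde,
                                cs$circ_expr[-1], cs$gene_expr, "down"),
               "disagree")
})

test_that("cascade report counts sites, mediated and total targets per miRNA", {
  tr <- data.frame(circ_id = "c", mirna = c("m1", "m1", "m1", "m2"),
                   gene_id = c("g1", "g2", "g3", "g4"),
                   n_sites_circ = c(3L, 3L, 3L, 1L),
                   gene_direction = "down", rho = 0.5, p = 0.001,
                   associated = c(TRUE, TRUE, FALSE, FALSE))
  rep1 <- cascade_report(tr)
  expect_equal(rep1$mediated[rep1$mirna == "m1"], 2L)
  expect_equal(rep1$summary[rep1$mirna == "m1"], "2 out of 3 targets")
  rep2 <- cascade_report(tr, total_targets = c(m1 = 655L, m2 = 10L))
  expect_equal(rep2$summary[rep2$mirna == "m1"], "2 out of 655 targets")
  expect_equal(nrow(cascade_report(tr[0, ])), 0L)
})
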