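# circat

Detection and analysis of circular RNAs (circRNAs) of **all** structural
types — canonical back-spliced, partial and complete interior
(i-circRNAs), and intergenic — from stranded paired-end RNA-seq, without
using splice-signal or annotation information during detection.

## Who this is for

Transcriptomics researchers who need a circRNA caller that does not
assume back-splice junctions sit on annotated exon boundaries or GT-AG
dinucleotides, plus the standard downstream analyses: junction-feature
characterization, abundance filtering, differential expression, and
competing-endogenous-RNA (ceRNA) association — all testable end to end on
seeded synthetic data with a planted truth set.

## The method

A circRNA with acceptor `A` (circle 5′ start) and donor `D` (circle 3′
end, half-open) produces reads crossing the back-fusion junction
`D → A`.  For each read pair:

1. Reads mapping end-to-end (≤ 2 mismatches) are linear RNA — discarded.
2. From an unmapped read, the terminal *x*-mers (x = 20) are placed as
   left/right anchors; a junction read has its **left anchor downstream
   of its right anchor** — the reverse of a forward splice.
3. The split offset *s* ∈ [x, L−x] is resolved so that `read[0:s)`
   aligns ending at `D` and `read[s:L)` starts at `A`, with combined
   mismatches ≤ 2; junction homology (SHS) yields a shift window of
   equivalent splits, and the leftmost minimum-mismatch split is the
   canonical representative.
4. The mate must map entirely inside `[A, D)` (or split-map to the same
   junction when the circle is shorter than the fragment).
5. Junctions supported by ≥ 2 read pairs become candidates; the
   annotation then classifies them (canonical / partial / complete
   interior; single exon, single intron, adjacent exon+intron,
   intergenic) and junction features are computed (GT-AG signal over the
   shift window, SHS length `f + b`, complementary flanks, nesting).

Expression is SRPBM (spliced reads per billion mappings,
`count × 10⁹ / mapped reads`); abundant circles (k = 5 reads in ≥ 1
sample, present in m = 10 samples) are tested between groups with a
tie-aware **exact** Wilcoxon rank-sum test (significant at raw
p ≤ 0.01, BH-adjusted values reported alongside).  ceRNA triples link a
circRNA and a DE mRNA through a shared miRNA (seed-and-extend scanner,
site score ≥ 140.0, energy ≤ −1.0) with Spearman ρ > 0, p < 0.01 and
concordant DE direction.

See `vignettes/circat-methods.Rmd` for the full model, parameter
defaults and design rationale.

## Worked example

Simulate a fixture with 30 planted circRNAs on a 2 × 50 kb toy genome,
then detect and classify them:

```r
library(circat)
cfg <- circat_config(seed = 7)
fix <- run_simulate(file.path(tempdir(), "fixture"), config = cfg,
                    depth = 6, linear_pairs = 2000)
catalog <- run_detect(fix$paths$fastq, fix$paths$genome, fix$paths$gtf,
                      file.path(tempdir(), "detected"), cfg)
table(catalog$class, catalog$structure)
```

```
                 intergenic single_exon single_intron
  canonical               0          10             0
  complete_icirc          5           6             4
  partial_icirc           0           5             0
```

All 30 planted junctions are recovered at their exact `(A, D)`
coordinates with zero false calls from the 2,000 linear background
pairs, and the splice-signal rate separates the classes as expected —
100% of canonical circles carry GT-AG, 0% of the planted interior
circles do:

```r
round(100 * tapply(catalog$has_splice_signal, catalog$class, mean), 1)
#>      canonical complete_icirc  partial_icirc
#>            100              0              0
sum(catalog$id %in% fix$truth$circles$id)   # 30
```

Each row also reports SHS length/sequence (e.g. the planted 2-nt `TG`
homology), flank-pairing length (the planted 12-nt inverted repeat), and
host genes.  `run_quant_de()` and `run_cerna()` continue the pipeline
from the written catalog;
`Rscript inst/cli/circat.R simulate|detect|quant|all …` exposes the same
stages from the shell.

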