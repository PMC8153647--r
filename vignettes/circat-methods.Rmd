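---
title: "Detecting circular RNAs of all types: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circular RNAs of all types: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circat)
```

## The problem

Back-splicing and template switching produce covalently closed RNA
circles.  A circRNA leaves a single diagnostic footprint in RNA-seq data:
read fragments that cross its back-fusion (BF) junction, where the
genomically downstream donor coordinate `D` is joined back to the
upstream acceptor `A`.  Most detection tools require the junction to
coincide with annotated splice sites or canonical GT-AG dinucleotides,
which structurally excludes circles arising from exon interiors, intron
interiors, or intergenic transcripts.  `circat` detects circles of *all*
of these types: it uses no splice-signal or annotation information during
detection, and uses the annotation only afterwards, to classify what it
found.

## The detection algorithm

For stranded paired-end reads (length `L`, default 100 nt):

1. **Discard linear reads.** Any read that maps end-to-end to the genome
   (either orientation, at most `max_mismatches = 2` substitutions) is
   linear RNA and is removed.  Reads with more than 10% N are set aside
   without search.
2. **Anchor the remainder.** From each unmapped read, take the first and
   last `x`-mers (`anchor_length = 20`) as left and right anchors and
   place both on the genome.  Placement uses an internal exact-seed index
   (all 6-mers, 2-bit encoded) with mismatch-tolerant verification; the
   seeding is pigeonhole-complete for the mismatch budget, i.e. it cannot
   miss a placement with at most 2 mismatches.  Each placement carries a
   pseudo mapping quality on a 0-60 scale: 40 when the best competing
   placement has at least two more mismatches, 0 when tied, linear in
   between; both anchors must reach `min_anchor_mapq = 40`.
3. **Reversed-orientation pairing.** A junction-crossing read has its
   left anchor *downstream* of its right anchor -- the mirror image of a
   forward splice.  Only same-chromosome anchor pairs in this reversed
   orientation, with implied span at most `max_span` (100 kb), continue.
   Forward-spliced linear reads are rejected here, which is what makes
   the caller silent on spliced mRNA without ever consulting the
   annotation.
4. **Split-point resolution.** For each anchor pair, every split offset
   `s` in `[x, L - x]` is scored: the read prefix `read[0:s)` must align
   ending at `D` and the suffix `read[s:L)` starting at `A`, with
   *combined* mismatches within the budget (the stricter per-read
   reading, not per-segment).  All minimum-mismatch offsets form the
   *shift window*; when the junction sits inside a short homologous
   sequence (SHS) of length `h`, the window has width `h + 1` on
   error-free reads.  We deliberately restrict the window to
   minimum-mismatch splits: under a mismatch *budget*, shifting the
   junction 1-2 nt off its true position costs only 1-2 mismatches and
   would otherwise count as "valid", dragging the reported coordinate off
   the junction.  The canonical representative is the leftmost offset in
   the window -- a purely positional tie-break, chosen because the method
   must not prefer GT-AG-looking splits (that would reintroduce the
   splice-signal bias the approach exists to avoid).
5. **Mate constraint.** A candidate from one read is kept only if its
   mate is consistent with the circle: mapped end-to-end entirely inside
   `[A, D)` in the orientation the circle strand implies, or -- for
   circles shorter than the fragment, where an interior mate is
   geometrically impossible -- split-mapping to the *same* canonical
   junction (the "rotated-circle" rule, flagged in the output; a strict
   interior-only mode is available).
6. **Aggregation.** Canonical junctions are pooled across reads and
   samples; a BF point needs at least `min_support = 2` distinct read
   pairs in its best sample to become a candidate.

The library is treated as dUTP-style fr-firststrand (read 2 = transcript
sense); either mate may be the split one.  A junction found on the as-is
sense sequence is a "+" circle, on its reverse complement a "-" circle.

## Classification and junction features

With the annotation loaded (GTF, converted internally to 0-based
half-open coordinates everywhere -- one convention end to end prevents
off-by-one drift in junction arithmetic):

* **Class.** Both BF points on annotated exon boundaries: `canonical`;
  exactly one: `partial_icirc`; neither: `complete_icirc`.  Boundary
  matching is exact (`boundary_tolerance = 0`) and strand-aware by
  default; both are configurable.  The boundary set is the union over all
  transcripts, since no isoform-selection rule is defensible from
  junction reads alone.
* **Structure.** Only circles lying within a single exon, a single
  intron, an adjacent exon+intron pair of one transcript (either order),
  or wholly intergenic space are kept; anything wider is labelled
  `other` and excluded, because internal structure across more than two
  features cannot be inferred reliably from junction-spanning reads.
* **Splicing signal.** GT (donor side) plus AG (acceptor side), strand
  adjusted, evaluated at *every* shift inside the homology window -- so
  the call is invariant to the canonical-split choice.  Only canonical
  GT-AG counts by default; other dinucleotide pairs can be supplied.
* **SHS.** Forward homology `f` = longest `genome[A, A+h) ==
  genome[D, D+h)`, backward `b` analogous; SHS length `f + b`, capped at
  60 nt (real SHS observations reach the mid-50s).  An SHS makes the
  exact split ambiguous and is the expected footprint of polymerase
  template switching.
* **Complementary flanks.** Longest exact reverse-complement match
  between the 200 nt upstream of `A` and downstream of `D`, reported at
  8 nt and above.  Note that with 200 nt windows, chance 8-9 nt matches
  are common (the expected number of chance 8-mer hits is of order one);
  the reported length, not its mere presence, carries the signal.
* **Nesting.** Proper containments between circles and host genes
  producing two or more circles are reported.

## Quantification and differential expression

Expression is the junction-read count, normalized as SRPBM (spliced
reads per billion mappings): `count * 1e9 / mapped_reads`.  Abundant
circles must reach `k = 5` reads in at least one sample and appear
(count >= 1) in at least `m = 10` samples.  Group comparison uses the
Wilcoxon rank-sum test on SRPBM with midranks for ties:

* for `min(n) <= 12` the two-sided p-value is computed *exactly* by a
  count-distribution dynamic program over doubled midranks --
  mathematically identical to enumerating all `choose(n1+n2, n1)` group
  assignments, but feasible at these sizes and correct under ties (the
  stock exact path in `wilcox.test` switches to an approximation when
  ties are present, which is why the enumeration is implemented here and
  `wilcox.test` serves only as a cross-check in tie-free tests);
* otherwise a tie-corrected normal approximation without continuity
  correction is used.  At `n = 15/15` and a 0.01 threshold this is
  mildly conservative (empirical type-I error near 0.009 rather than
  0.010) purely because the rank-sum statistic is discrete; this is a
  property of rank tests, not an implementation artifact.

Significance is raw `p <= 0.01` (the convention this analysis style
uses); Benjamini-Hochberg adjusted values are always reported alongside
so users can apply FDR control instead.  Fold changes are ratios of
group-mean SRPBM with a 0.1 SRPBM pseudocount to avoid division by zero.
External mRNA DE tables are ingested as-is and re-thresholded at
`q < 0.05` and 2-fold.

## ceRNA association

The circRNA-miRNA-mRNA stage asks whether a circle and an mRNA share a
regulating miRNA and co-vary positively.  miRNA sites are found with a
transparent seed-and-extend scorer: a site needs at least 6 of 7
Watson-Crick pairs against miRNA positions 2-8 (no wobble inside the
seed), and the full ungapped duplex is scored +5 per Watson-Crick pair,
+1 per G:U wobble, -4 per mismatch, with the 5' miRNA half weighted
twice; the energy proxy counts pair contributions
(-2 kcal/mol-like per GC, -1 per AU, -0.5 per GU).  Sites are kept at
score >= 140.0 and energy <= -1.0 -- the published predictor's default
thresholds, which a perfect ~22-nt duplex (score 165 on this scale)
clears while random sequence essentially never does.  Bit-exact parity
with the external predictor's scores is a non-goal; an adapter ingests
that predictor's output for users who want it.

A triple (circRNA, miRNA, DE gene) is *associated* when the gene's DE
direction matches the circRNA's (positive ceRNA regulation implies
concordance; a flag relaxes this), Spearman rho > 0 and p < 0.01.  Rho
is Pearson correlation of midranks; the p-value uses the t approximation
for n >= 10 and exact enumeration of the permutation distribution (via
`std::next_permutation` over the rank multiset, tie-correct) for n < 10.
miRNA family labels like "miR-23a/b-3p" are kept distinct unless an
explicit family map merges them.

## The synthetic-data generator

Every claim the test suite makes is grounded in seeded synthetic data
with a recorded truth set; the generator is first-class, tested code.

* **Genome/annotation.** I.i.d. uniform A/C/G/T chromosomes; genes of
  2-8 exons (120-450 nt) with GT-AG introns (200-1200 nt,
  strand-appropriate dinucleotides on the forward strand), 1.4 genes per
  10 kb, at least 1 kb of annotation-free sequence per chromosome.  The
  density and length ranges were chosen so the standard 30-circle
  validation design always finds loci on a 2 x 50 kb genome while
  leaving several kb of intergenic space.
* **Planted circles.** Each design row (class, structure, SHS length,
  signal, flank-repeat length) picks a fresh locus; the genome is locally
  edited to realize the requested SHS (identical h-mers at both junction
  flanks), signal state and inverted repeats.  Incidental junction
  homology is trimmed (backward 0, forward exactly the designed h) so
  the planted coordinates are their own canonical leftmost-shift
  representative -- otherwise exact-coordinate recovery and
  exact-boundary classification would not be well-posed.  Every planted
  circle is validated against the package's own classifiers before use.
* **Reads.** Fragments of N(250, 25) nt (clamped at L + 10), dUTP
  layout, constant qualities, substitution-only errors (indels are a
  stated non-goal of the aligner, so the error model matches the
  contract).  Per circle, `depth` junction pairs are generated whose
  split mate crosses the junction with at least anchor-length + 2 nt on
  both sides and whose other mate is resolvable (interior, or crossing
  with the same margin -- forced for circles shorter than the fragment);
  unresolvable geometries exist in real data but would make "100%
  recovery at depth d" ill-defined as a specification.
* **Expression.** Negative-binomial junction counts (mean 50 at the
  median library, dispersion 0.2, library sizes uniform on 20-40
  million) -- junction counts in real data are overdispersed, and the NB
  stresses the rank test realistically.  DE rows are scaled by the fold
  change in group A.
* **ceRNA scenario.** A latent group shift of 2 standard deviations on
  the circRNA (about 3-fold on the expression scale, matching the 2.6-
  to 3.7-fold changes reported for abundant skin circRNAs), associated
  genes as monotone functions of the circRNA's latent level at the
  requested correlation strength, independent-noise genes, and
  opposite-direction DE controls that exercise the concordance gate.

## Problem sizes used in validation

The shipped validation suite uses: a 2 x 50 kb genome with 30 planted
circles (10 canonical, 10 complete interior of which 4 intronic, 5
partial, 5 intergenic) at junction depth 5 against 50,000 linear-only
read pairs; 1,000 random junctions for the SHS oracle; 500 (test suite)
or 200 (acceptance script) reads for the exhaustive split-mapping
oracle on a 10 kb genome; 10,000 null rows and 200 power replicates at
n = 15/15 for DE calibration; 1,000 random vectors for the Spearman
oracle; and a 30-sample ceRNA scenario at strength 0.8.  These sizes
give Monte-Carlo standard errors comfortably below the margins being
asserted while keeping the whole suite in the minutes range on one CPU.

## Known limitations

* No indels at the junction and no gapped anchor alignment; a read with
  an indel near its BF point is lost, not mis-set.
* The toy genomes are repeat-free by construction; on repetitive real
  genomes anchor uniqueness filtering (pseudo-MAPQ 40) will drop
  junctions in repeats rather than guess, and recovery rates from the
  synthetic suite do not transfer to such loci.
* Passing the synthetic suite demonstrates algorithmic correctness under
  the generator's assumptions (uniform base composition, substitution
  errors, exact fragment model); it does not demonstrate sensitivity on
  real libraries with coverage biases, chimeric artifacts, or
  rolling-circle multimers (multimer detection is out of scope).
* Pooled-sample Spearman correlation conflates within-group covariation
  with between-group shifts: a gene that is group-shifted for reasons
  unrelated to the circRNA can correlate positively with it across
  pooled samples.  The concordance and shared-miRNA gates reduce but do
  not eliminate this; causal claims require perturbation data.
* The miRNA site scorer reproduces the published thresholds' *logic*,
  not the external predictor's exact scores.
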