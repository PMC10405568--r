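---
title: "Methods: circular sisRNA identification and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circular sisRNA identification and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions
behind `circsis`. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates and conventions

All user-facing tables use 0-based half-open intervals (BED convention);
GTF input (1-based inclusive) is converted on read, and branch points
(BPs) are 0-based single positions. The 5′ splice site of an interval is
its start on the plus strand and `end - 1` on the minus strand; the 3′
splice site is the mirror. Sequence windows and positional profiles are
transcript-oriented: negative offsets are upstream in the direction of
transcription on both strands, so minus-strand windows are
reverse-complemented and reported in the RNA alphabet.

## The intron universe

Isoform structure is deliberately discarded: per gene, the introns of all
transcripts are union-merged, and every position covered by an exon is
subtracted from the merged span, leaving `kept_blocks`. Two choices were
genuinely open:

* **Masking scope.** By default only exons of the intron's own gene mask
  its positions (`mask_scope = "gene"`), which reads "alternative
  isoform" narrowly; `mask_scope = "strand"` additionally masks exons of
  other genes on the same chromosome and strand for loci with overlapping
  genes. The default is the narrower reading; the switch exists because
  annotation-dense loci differ.
* **Length filtering.** The 100–10 000 bp host-candidate filter applies
  to the merged *span*, not the kept-block total, because intron length
  is a property of the splicing event, whereas kept length is a property
  of the annotation. Sub-100 bp spans (annotation artifacts down to 1 bp
  exist in real annotations) are kept in the table but flagged
  `is_host_candidate = FALSE` and excluded from hosting downstream.

Host assignment returns the *shortest* intron fully containing a circle;
ties (identical spans from different genes) break deterministically by
smaller start coordinate, then lexicographic intron id. A separate
high-confidence flag records whether the circle's 5′ end lies within
10 bp of the host's 5′ splice site.

## Junction collapsing and classification

Reverse transcriptase traverses the 2′-5′ branch with low fidelity, so
one circular molecule typically produces several called junctions that
share the 5′ splice site and scatter at the 3′ end. Clusters are keyed by
(host intron, exact donor position): the donor sits at a splice site and
is reliable, so no fuzz is applied on that side. The representative end
is the member with the most junction-spanning reads; ties break by the
member seen in more samples, then by proximity to the annotated 3′ splice
site, then leftmost. Classification compares the representative end with
the 3′ splice site at tolerance `tol_3ss`:

* `tol_3ss = 0` (default) — the max-read representative defines the
  class exactly; real callers occasionally disagree by a base, so 1–2 is
  appropriate for noisy callers. Tests verify that intronic-circle recall
  is monotone in `tol_3ss` and reaches 1 once the tolerance covers the
  jitter bound.
* Representative ends outside the host span indicate an annotation
  conflict; such clusters are excluded and counted rather than guessed.

The "expressed in at least two samples" rule is applied after collapsing,
as a cluster-level filter on distinct samples with nonzero junction
reads.

## Branch points and sequence context

Two BP sources are kept side by side and never merged: the caller-derived
BP (representative end of a stable-lariat cluster) and an external map
(chrom, pos, strand, support). When an intron has several map BPs the
max-support record wins, ties resolving toward the 3′ splice site — the
map's own rule is not published, so the package picks the reading that
favours the canonical BP neighbourhood. Feature analyses default to the
external map where both exist; concordance between the two sources is
reported (median, mean, fraction of distances < 20 bp).

The 3′ tail is the number of intronic bases strictly 3′ of the BP. Tails
≤ 1 bp or negative are flagged discarded — they are more often
annotation-truncation artifacts than biology. BP-centred windows drop
introns with tails < 10 bp and mask in-window positions within 10 bp of
the 3′ splice site, so splice-site signal cannot leak into BP-region
nucleotide frequencies, information content or conservation summaries.
Information content is the Kullback–Leibler divergence from a uniform
background in bits (`0·log 0 := 0`; a zero background entry is an error,
not a convention).

Motif scanning is exact degenerate IUPAC matching reporting *all*
(possibly overlapping) matches, matching the default semantics of
occurrence scanners. Matches touching a masked position are discarded.
De-novo motif discovery is out of scope; the scanner takes a given motif
(default `AYAUUAUUAAU`).

## Tracks

Score tracks are sparse per-base maps. The one numerically consequential
convention: a missing depth position is 0, while a missing conservation
position is *missing* — phyloP is signed and zero means "neutral", not
"unobserved" — so conservation means exclude unscored positions from both
numerator and denominator. Whole-intron means trim 10 bp at each span end
and are restricted to kept blocks. Read-depth from aligned blocks
excludes a read from an intron only when one of its splice gaps spans the
whole intron (a linearly spliced read across it); per-sample tracks are
averaged position-wise across samples, absent samples counting zero. The
BP-region exceedance window for profile log-fold-changes defaults to
offsets −50..+50 excluding 0; the width is not fixed by any published
definition and is exposed as an argument.

## Expression and enrichment

Counting is deliberately loose and stranded: a read counts toward every
feature any of its aligned blocks overlaps by ≥ 1 base on the same
strand, so pre-mRNA reads partially overlapping an intron are counted and
a read may count several times. RPM divides by the per-sample total
mapped reads from the metadata (sequencing depth, not junction totals);
FPKM is `count·1e9 / (length·library_size)`. Relative intron expression
and group log-fold-changes add the pseudocount `1e-6` to numerator and
denominator.

RNase R enrichment includes a circular junction when it has ≥ 2
junction-spanning reads in both treated and control libraries; the linear
counterpart (intron-skipping splice reads across the same intron) is
included when its circular junction is included and linear reads are
reported in both samples (an absent linear counterpart is "not detected",
not zero). Enrichment is a treated/control RPM ratio strictly greater
than 1 (+∞ on a zero control counts as enriched), and the association
between junction type and enrichment is Fisher's exact test with the
sample odds ratio `ad/bc` reported alongside the conditional two-sided
p-value.

## Cohort statistics

The Wilcoxon rank-sum test is exact (full-enumeration semantics) when the
combined n ≤ 12 without ties and otherwise uses the normal approximation
with tie and continuity corrections. BH adjustment is applied within each
class-pair family — one family per comparison, matching per-pair
significance counts — with q < 0.1 as the significance threshold. The
differential-expression inclusion rule, "more than ten junction reads
across ten samples", is ambiguous; it is resolved as *total reads
strictly greater than 10* AND *detected in at least 10 samples*, with
both thresholds exposed (`min_reads`, `min_samples`) so the alternative
per-sample reading can be configured.

Survival uses Kaplan–Meier curves and the two-group log-rank test after
dichotomizing expression at the median (or a supplied cutoff). The high
group is strictly-greater-than-cutoff, so a median of 0 splits
zero-expression versus positive samples — the natural behaviour for
sparse junction counts. Censored observations contribute risk-set time
only; the event is progression.

## The synthetic-data generator

`sim_config()` defaults define the study conditions and are not tuned per
test:

* cohort of three risk classes sized 96/232/129 with log-normal library
  sizes (median 3·10⁷);
* host introns split ~55/45 between stable lariats and intronic circles
  (`fraction_lariat_hosts = 0.30`, `fraction_circle_hosts = 0.25` of
  candidate introns);
* intron lengths log-normal with median 1461 bp; lariat 3′ tails
  log-normal with median 33 bp;
* RT jitter: each read lands on the true 3′ end with probability 0.8,
  else on an upstream satellite at geometrically decaying offsets ≤ 5 bp
  — this reproduces the multiplicity of shared-5′SS junctions that makes
  collapsing necessary;
* the external BP map copies the true lariat BP exactly with probability
  0.52 and otherwise displaces it geometrically (mean ~15 bp), giving a
  median concordance distance of 0 and mean near 7–8 bp. (The printed
  trio "median 0, mean 7.7, ~52% < 20 bp" is not jointly satisfiable by
  any distribution; the generator preserves the median and mean.);
* BP nucleotides drawn at 48% adenine for lariats vs 66% for other
  introns; the `AYAUUAUUAAU` motif planted at lag −24 ± 8 bp from the BP
  in 9.4% of lariat hosts and 6.2× fewer controls;
* conservation: N(0.25, 0.25) background with +1.5 elevation in ±50 bp
  around lariat BPs (several-fold above background, so the planted
  contrast is unambiguous);
* expression: negative-binomial junction counts with sparse means
  (log-normal, median 0.04 reads/sample), a 2-fold class-1 effect on 10%
  of clusters, tissue-specific multipliers, and fraction assignment
  biased so shorter circles localize cytoplasmically;
* survival: exponential times with hazard 0.02/month for
  high-total-expression samples and hazard ratio 2 for low, exponential
  censoring near 30%.

Decoy junctions (mitochondrial, sub-30 bp, non-coding hosts) exercise the
filters and appear in the manifest's removal counts, never in the truth
tables.

What the generator does **not** emulate: realistic splice-site strength,
sequencing error, mappability, GC or length biases, correlated expression
across clusters, batch structure, or caller-specific artifacts beyond
symmetric-ish 3′-end jitter. Passing recovery tests therefore demonstrate
the correctness of the pipeline's logic under its stated assumptions, not
caller accuracy on real reads.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale chosen to make
each check sharp but quick: recovery simulations use 25–40 genes and
20–26 samples; the motif check uses 458 + 458 windows (the prevalence
setting's natural cohort size) over 20–50 seeds; differential expression
uses 200 features × (90 + 230) samples over 10–20 seeds; survival uses
n = 200 over 30–50 seeds; the acceptance cohort runs the full 457-sample
default. Every random draw derives from a single seed; identical seeds
give byte-identical simulation bundles, and the pipeline manifest is
reproducible modulo output paths.

## Known limitations

* Classification trusts the max-read representative; a true circle whose
  representative is jittered off the 3′SS is called a lariat at
  `tol_3ss = 0` (visible in the recovery tests as circle recall < 1 under
  jitter).
* Donor positions are matched exactly; callers that misplace the 5′
  splice site will split clusters.
* Multi-counted loose-overlap reads make intron counts non-additive
  across features by design.
* The GENCODE-scale intron universe check requires the external
  annotation download (`scripts/gencode_introns.R`); it is not shipped.
* Nested-intron donors resolve to the shortest containing intron; when a
  donor genuinely belongs to the outer intron of a nested pair the host
  call is wrong by construction.
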