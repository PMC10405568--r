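# circsis

Analysis of **circular stable intronic sequence RNAs (sisRNAs)** from total
RNA-Seq circular-junction calls.

Most excised introns are debranched and degraded within minutes of
splicing, but a subset persists as circular molecules. Two classes are
distinguishable from junction-spanning reads:

- **stable lariats** — the 2′-5′ branch junction survives; the circle runs
  from the 5′ splice site to an internal **branch point (BP)**;
- **intronic circles** — full-length introns closed by a 3′-5′ linkage;
  the circle's 3′ end coincides with the 3′ splice site.

`circsis` takes the *output* of a circular RNA caller (CIRCexplorer2-style
BED, or a generic junction TSV) and provides the downstream analysis a
study of these molecules needs: a unique non-exon-overlapping intron
universe, host-intron assignment, junction collapsing and classification,
branch-point characterization, sequence/conservation profiling, expression
normalization, and cohort statistics — plus a synthetic-data generator
with ground truth so that every recovery claim is testable.

## The core procedure

1. **Intron universe.** From a GTF, introns of all isoforms of a gene are
   union-merged; positions overlapped by any exon are subtracted, leaving
   `kept_blocks`. Host candidates have span length 100–10 000 bp.
2. **Filtering.** Junction calls from the mitochondrial genome, from
   non-protein-coding host genes, with circle length outside 30–10 000 bp,
   or without a containing intron are removed. The host intron is the
   *shortest* intron fully containing the circle.
3. **Collapsing.** Reverse transcriptase stumbles on the 2′-5′ linkage, so
   calls sharing a host intron and 5′ splice site but differing at the 3′
   end are one cluster, represented by the end with the most
   junction-spanning reads. Clusters must be expressed in ≥ 2 samples.
4. **Classification.** A cluster is an intronic circle iff its
   representative end lies within `tol_3ss` (default 0) bases of the 3′
   splice site; otherwise it is a stable lariat and its end estimates the BP.
5. **Characterization.** 3′ tail length (BP→3′SS distance), BP nucleotide,
   sequence windows with information content
   (`bits = Σ p·log2(p/q)`), IUPAC motif scanning (all overlapping
   matches), per-base read depth and phyloP conservation profiles anchored
   at 5′SS/BP/3′SS, and per-offset contrasts
   `log2((a1 + 1e-6)/(a2 + 1e-6))`.
6. **Cohort statistics.** RPM/FPKM normalization, relative intron
   expression `(intron + 1e-6)/(gene + 1e-6)`, RNase R enrichment with
   Fisher's exact test, tissue and cell-fraction summaries, risk-class
   differential expression (two-sided Wilcoxon rank-sum, BH FDR, q < 0.1),
   and Kaplan–Meier / log-rank survival with median-expression
   dichotomization.

## Worked example

Simulate a small cohort with known ground truth, run the pipeline, and
compare against the truth:

```r
library(circsis)

cfg <- sim_config(seed = 42, n_genes = 30, classes = c("1" = 20, "2" = 30, "3" = 15))
sim <- simulate_sisrna(cfg, "demo")
rc  <- run_config(gtf = sim$paths$gtf,
                  junctions_dir = sim$paths$junctions_dir,
                  metadata = sim$paths$metadata,
                  genome = sim$paths$genome,
                  bp_map = sim$paths$bp_map,
                  outdir = "demo/out",
                  de_min_reads = 5L, de_min_samples = 5L)
res <- run_pipeline(rc)

table(res$clusters$cls)
#> intronic_circle   stable_lariat
#>              23              31

cat(sprintf("BP concordance: median %g bp, mean %.1f bp (n = %d)\n",
    res$bp_concordance$median, res$bp_concordance$mean, res$bp_concordance$n))
#> BP concordance: median 0 bp, mean 7.8 bp (n = 31)

cat(sprintf("survival log-rank p = %.3g (cutoff %.2f RPM)\n",
    res$survival$p, res$survival$cutoff))
#> survival log-rank p = 0.00303 (cutoff 0.21 RPM)

truth_compare(res$clusters, sim$truth_clusters)
#> truth comparison report
#>   clusters expected/recovered: 54/54 (recovery 1.000)
#>   class accuracy 0.981 (lariat recall 1.000, circle recall 0.958)
#>   BP distance: median 0, mean 0.00
```

The 54 planted circular sisRNAs are all recovered; 31 are classified as
stable lariats and 23 as intronic circles; the caller-inferred branch
points agree with the external BP map with median distance 0 bp; and the
planted coupling between total sisRNA expression and progression-free
survival is detected by the log-rank test. One circle is mis-called a
lariat because RT jitter moved its max-read end off the 3′ splice site —
raising `tol_3ss` recovers it.

A thin command-line front end with the same stages lives at
`inst/cli/circsis.R` (subcommands `simulate`, `build-introns`, `collapse`,
`run`, `truth-compare`).

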