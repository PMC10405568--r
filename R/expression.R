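# Expression matrices, normalization, RNase R enrichment, and the small
# statistics used throughout (log fold change, Fisher 2x2, Spearman).

#' Build stranded block features for counting
#'
#' Gene features are exon unions per gene; intron features are the kept
#' (non-exon-overlapping) blocks of each intron record.
#'
#' @param introns intron table, or NULL.
#' @param exons exon table (for gene features), or NULL.
#' @return data.table: feature_id, chrom, strand, bstart, bend (one row per
#'   block), length (total block length of the feature, repeated).
#' @export
block_features <- function(introns = NULL, exons = NULL) {
  out <- list()
  if (!is.null(introns)) {
    x <- as.data.table(introns)
    out$introns <- x[, {
      ks <- kept_starts[[1]]; ke <- kept_ends[[1]]
      if (length(ks)) .(chrom = chrom, strand = strand, bstart = ks, bend = ke)
    }, by = .(feature_id = intron_id)]
  }
  if (!is.null(exons)) {
    ex <- as.data.table(exons)
    gr <- GenomicRanges::reduce(.gr0(paste0(ex$gene_id, "|", ex$chrom, "|", ex$strand),
                                     ex$start, ex$end))
    parts <- tstrsplit(as.character(GenomicRanges::seqnames(gr)), "|", fixed = TRUE)
    out$genes <- data.table(feature_id = parts[[1]], chrom = parts[[2]],
                            strand = parts[[3]],
                            bstart = GenomicRanges::start(gr) - 1L,
                            bend = GenomicRanges::end(gr))
  }
  f <- rbindlist(out)
  f[, length := sum(bend - bstart), by = feature_id]
  f[]
}

#' Count reads per feature (loose, stranded overlap)
#'
#' A read counts toward a feature when any of its aligned blocks overlaps
#' any feature block by at least one base on the same strand; pre-mRNA
#' reads partially overlapping an intron are therefore counted, and a read
#' may count toward multiple features (a documented deviation from
#' unique-assignment counters).
#'
#' @param reads data.frame: read_id, sample_id, chrom, strand,
#'   block_starts, block_sizes (comma-separated 0-based genomic).
#' @param features block feature table from [block_features()].
#' @param stranded require matching strand (default TRUE; antisense reads
#'   are not counted).
#' @return integer matrix features x samples.
#' @export
count_reads <- function(reads, features, stranded = TRUE) {
  rd <- as.data.table(reads)
  split_int <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  bl <- rd[, {
    bs <- split_int(block_starts); sz <- split_int(block_sizes)
    .(bstart = bs, bend = bs + sz)
  }, by = .(read_id, sample_id, chrom, strand)]
  fs <- as.data.table(features)
  feat_ids <- unique(fs$feature_id)
  samples <- sort(unique(rd$sample_id))
  key <- function(ch, st) if (stranded) paste0(ch, "|", st) else ch
  bgr <- .gr0(key(bl$chrom, bl$strand), bl$bstart, bl$bend)
  fgr <- .gr0(key(fs$chrom, fs$strand), fs$bstart, fs$bend)
  shared <- intersect(GenomeInfoDb::seqlevels(bgr), GenomeInfoDb::seqlevels(fgr))
  counts <- matrix(0L, length(feat_ids), length(samples),
                   dimnames = list(feat_ids, samples))
  if (length(shared)) {
    lv <- union(GenomeInfoDb::seqlevels(bgr), GenomeInfoDb::seqlevels(fgr))
    GenomeInfoDb::seqlevels(bgr) <- lv
    GenomeInfoDb::seqlevels(fgr) <- lv
    hits <- GenomicRanges::findOverlaps(bgr, fgr, minoverlap = 1L)
    if (length(hits)) {
      pairs <- unique(data.table(
        read_id = bl$read_id[S4Vectors::queryHits(hits)],
        sample_id = bl$sample_id[S4Vectors::queryHits(hits)],
        feature_id = fs$feature_id[S4Vectors::subjectHits(hits)]))
      agg <- pairs[, .(n = .N), by = .(feature_id, sample_id)]
      counts[cbind(match(agg$feature_id, feat_ids),
                   match(agg$sample_id, samples))] <- agg$n
    }
  }
  counts
}

#' FPKM normalization
#'
#' `fpkm = count * 1e9 / (length * library_size)`.
#'
#' @param counts features x samples count matrix.
#' @param lengths named feature lengths (bp); all > 0.
#' @param library_sizes named per-sample library sizes.
#' @return FPKM matrix.
#' @export
fpkm <- function(counts, lengths, library_sizes) {
  ln <- lengths[rownames(counts)]
  if (anyNA(ln)) stop("missing length for feature(s): ",
                      paste(head(rownames(counts)[is.na(ln)], 5), collapse = ", "))
  if (any(ln <= 0)) stop("feature lengths must be > 0")
  missing <- setdiff(colnames(counts), names(library_sizes))
  if (length(missing)) stop("missing library size for sample(s): ",
                            paste(missing, collapse = ", "))
  ls <- library_sizes[colnames(counts)]
  counts * 1e9 / outer(as.numeric(ln), as.numeric(ls))
}

#' Relative intron expression
#'
#' Ratio of intron FPKM to parent mRNA FPKM with a pseudocount added to
#' both numerator and denominator; a ratio above 1 indicates intron
#' expression exceeding the parent gene's.
#'
#' @param intron_fpkm,gene_fpkm paired non-negative values.
#' @param pseudocount default 1e-6.
#' @return ratio vector.
#' @export
relative_intron_expression <- function(intron_fpkm, gene_fpkm, pseudocount = 1e-6) {
  if (any(intron_fpkm < 0, na.rm = TRUE) || any(gene_fpkm < 0, na.rm = TRUE)) {
    stop("FPKM values must be non-negative")
  }
  (intron_fpkm + pseudocount) / (gene_fpkm + pseudocount)
}

#' Log2 fold change between two group means
#'
#' `log2((a1 + pc) / (a2 + pc))` with pseudocount `pc`.
#'
#' @param a1,a2 non-negative group means.
#' @param pseudocount default 1e-6.
#' @return logFC value(s).
#' @export
logfc <- function(a1, a2, pseudocount = 1e-6) {
  log2((a1 + pseudocount) / (a2 + pseudocount))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the conditional (hypergeometric) minimum-likelihood
#' method -- the sum over tables with point probability not exceeding the
#' observed one -- and the sample odds ratio `ad/bc`. A zero margin yields
#' p = 1 and an undefined (NA) odds ratio.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return list: `odds_ratio`, `p`.
#' @export
fisher_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p = fisher.test(tab)$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties). Undefined
#' (NA, with a warning) when either variable has zero rank variance.
#'
#' @param x,y paired finite values, n >= 3.
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("spearman_rho requires n >= 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("zero rank variance; correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' RNase R enrichment of circular versus linear junctions
#'
#' RNase R degrades linear RNA, so circular junction reads should be
#' enriched in treated versus control libraries. Circular junctions are
#' included when supported by at least `min_reads` junction-spanning reads
#' in both the treated and the control sample; linear counterparts
#' (intron-skipping splice reads across the same intron) are included when
#' their circular junction is included and linear reads are reported (not
#' NA) in both samples. Enrichment is a treated/control RPM ratio strictly
#' greater than one (a zero control RPM gives +Inf, enriched). Association
#' between junction type and enrichment is tested with [fisher_2x2()].
#'
#' @param junctions data.frame with junction_id, circ_treated, circ_control,
#'   lin_treated, lin_control (raw read counts; linear columns may be NA).
#' @param library_sizes named vector with elements `treated` and `control`.
#' @param min_reads detection threshold on circular reads (default 2).
#' @return list: `per_junction` (data.table with RPM ratios and enrichment
#'   flags for both junction types), `table` (2x2: type x enriched),
#'   `odds_ratio`, `p`, `fraction_enriched` (named: circular, linear).
#' @export
rnase_r_enrichment <- function(junctions, library_sizes, min_reads = 2L) {
  x <- as.data.table(junctions)
  if (!all(c("treated", "control") %in% names(library_sizes))) {
    stop("library_sizes must name 'treated' and 'control'")
  }
  lt <- library_sizes[["treated"]]; lc <- library_sizes[["control"]]
  x <- x[circ_treated >= min_reads & circ_control >= min_reads]
  x[, `:=`(circ_ratio = (circ_treated * 1e6 / lt) / (circ_control * 1e6 / lc))]
  x[, circ_enriched := circ_ratio > 1]
  x[, lin_included := !is.na(lin_treated) & !is.na(lin_control)]
  x[lin_included == TRUE,
    lin_ratio := (lin_treated * 1e6 / lt) / (lin_control * 1e6 / lc)]
  x[lin_included == TRUE, lin_enriched := lin_ratio > 1]
  tab <- matrix(c(sum(x$circ_enriched), sum(!x$circ_enriched),
                  sum(x$lin_enriched[x$lin_included]),
                  sum(!x$lin_enriched[x$lin_included])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("circular", "linear"),
                                c("enriched", "not_enriched")))
  ft <- fisher_2x2(tab)
  list(per_junction = x[], table = tab, odds_ratio = ft$odds_ratio, p = ft$p,
       fraction_enriched = c(
         circular = if (nrow(x)) mean(x$circ_enriched) else NA_real_,
         linear = if (any(x$lin_included)) mean(x$lin_enriched[x$lin_included])
         else NA_real_))
}
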