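# Cohort-level analyses: tissue specificity, cell-fraction localization,
# risk-class differential expression and progression-free survival.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y numeric samples (both non-empty).
#' @param two_sided two-sided test (default TRUE).
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, two_sided = TRUE) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12L) && !ties
  p <- suppressWarnings(
    wilcox.test(x, y, alternative = if (two_sided) "two.sided" else "greater",
                exact = exact, correct = TRUE)$p.value)
  if (is.nan(p)) p <- 1  # zero-variance rank configuration (all values tied)
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j`, clipped at
#' 1, mapped back to the input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Per-tissue expression summaries
#'
#' Tissue-specific expression is the mean RPM over the tissue's samples.
#' A sisRNA is detected in a tissue when its raw junction reads across that
#' tissue's samples reach `min_reads`. Reported per tissue: total
#' expression over detected sisRNAs, the contribution of the top decile
#' (the `ceiling(0.1 n)` most expressed sisRNAs) to the total, and the
#' intronic-circle fraction of detected sisRNAs; plus, per sisRNA, the
#' number of tissues with nonzero mean expression among detections.
#'
#' @param rpm clusters x samples RPM matrix.
#' @param counts matching raw junction-read count matrix.
#' @param metadata sample metadata with sample_id and tissue.
#' @param cls named classification vector (`"stable_lariat"` /
#'   `"intronic_circle"`) for the circle fraction; optional.
#' @param min_reads detection threshold on raw reads per tissue (default 2).
#' @return list: `tissues` (data.table: tissue, n_samples, n_detected,
#'   total_expression, top_decile_contribution, circle_fraction),
#'   `tissue_counts` (named per-sisRNA tissue counts).
#' @export
tissue_summary <- function(rpm, counts, metadata, cls = NULL, min_reads = 2L) {
  md <- as.data.table(metadata)[!is.na(tissue)]
  if (!nrow(md)) stop("metadata has no tissue labels")
  tiss <- sort(unique(md$tissue))
  per <- lapply(tiss, function(tt) {
    sm <- intersect(md[tissue == tt, sample_id], colnames(rpm))
    mexp <- rowMeans(rpm[, sm, drop = FALSE])
    det <- rowSums(counts[, sm, drop = FALSE]) >= min_reads
    mexp[!det] <- 0
    total <- sum(mexp[det])
    topk <- ceiling(0.1 * sum(det))
    contrib <- if (sum(det) && total > 0) {
      sum(sort(mexp[det], decreasing = TRUE)[seq_len(topk)]) / total
    } else NA_real_
    cf <- if (!is.null(cls) && sum(det)) {
      mean(cls[names(mexp)[det]] == "intronic_circle", na.rm = TRUE)
    } else NA_real_
    list(tissue = tt, n_samples = length(sm), n_detected = sum(det),
         total_expression = total, top_decile_contribution = contrib,
         circle_fraction = cf, mean_expr = mexp, detected = det)
  })
  tissues <- rbindlist(lapply(per, `[`, 1:6))
  expr_mat <- do.call(cbind, lapply(per, function(z) z$mean_expr * z$detected))
  tissue_counts <- rowSums(expr_mat > 0)
  list(tissues = tissues[], tissue_counts = tissue_counts)
}

#' Cell-fraction expression summaries
#'
#' Per cell line and fraction: total RPM, detected sisRNA set, and
#' median/IQR of the detected clusters' circle lengths (linear
#' interpolation quartiles); plus the nuclear/cytoplasmic overlap count
#' per cell line.
#'
#' @param rpm clusters x samples RPM matrix.
#' @param metadata sample metadata with sample_id, cell_line, fraction.
#' @param lengths named circle lengths per cluster.
#' @return list: `fractions` (data.table: cell_line, fraction, n_detected,
#'   total_expression, median_length, iqr_length), `overlap` (data.table:
#'   cell_line, n_nuclear, n_cytoplasmic, n_overlap), `detected` (named
#'   list of detected cluster-id sets keyed "cell_line|fraction").
#' @export
fraction_summary <- function(rpm, metadata, lengths) {
  md <- as.data.table(metadata)[!is.na(fraction)]
  if (!nrow(md)) stop("metadata has no fraction labels")
  if (!"cell_line" %in% names(md)) md[, cell_line := "cell_line1"]
  groups <- unique(md[, .(cell_line, fraction)])
  detected <- list()
  fractions <- rbindlist(lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i]
    sm <- intersect(md[cell_line == g$cell_line & fraction == g$fraction, sample_id],
                    colnames(rpm))
    tot <- rowSums(rpm[, sm, drop = FALSE])
    det <- names(tot)[tot > 0]
    detected[[paste0(g$cell_line, "|", g$fraction)]] <<- det
    ln <- lengths[det]
    data.table(cell_line = g$cell_line, fraction = g$fraction,
               n_detected = length(det), total_expression = sum(tot),
               median_length = if (length(ln)) median(ln) else NA_real_,
               iqr_length = if (length(ln))
                 unname(diff(quantile(ln, c(0.25, 0.75)))) else NA_real_)
  }))
  overlap <- rbindlist(lapply(unique(groups$cell_line), function(cl) {
    nuc <- detected[[paste0(cl, "|nuclear")]]
    cyt <- detected[[paste0(cl, "|cytoplasmic")]]
    data.table(cell_line = cl,
               n_nuclear = length(nuc), n_cytoplasmic = length(cyt),
               n_overlap = length(intersect(nuc, cyt)))
  }))
  list(fractions = fractions[], overlap = overlap[], detected = detected)
}

#' Risk-class differential expression
#'
#' Clusters with strictly more than `min_reads` total raw junction reads
#' and detection (nonzero reads) in at least `min_samples` samples are
#' tested. For every pair of risk classes, per-sample RPM values are
#' compared with a two-sided Wilcoxon rank-sum test; BH adjustment is
#' applied within each class-pair family; the logFC is the log2 ratio of
#' class means ([logfc()]).
#'
#' @param rpm clusters x samples RPM matrix.
#' @param counts matching raw count matrix (for the inclusion filter).
#' @param metadata sample metadata with sample_id and risk_class.
#' @param min_reads,min_samples inclusion thresholds (defaults 10/10;
#'   reads strictly greater, samples at least).
#' @param q_threshold significance threshold on q (default 0.1).
#' @return data.table: cluster_id, class_a, class_b, logfc, p, q, pass.
#' @export
differential_expression <- function(rpm, counts, metadata, min_reads = 10L,
                                    min_samples = 10L, q_threshold = 0.1) {
  md <- as.data.table(metadata)[!is.na(risk_class)]
  classes <- sort(unique(md$risk_class))
  if (length(classes) < 2) stop("need >= 2 risk classes")
  keep <- rowSums(counts) > min_reads & rowSums(counts > 0) >= min_samples
  feats <- rownames(rpm)[keep]
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  rbindlist(lapply(pairs, function(pr) {
    sa <- intersect(md[risk_class == pr[1], sample_id], colnames(rpm))
    sb <- intersect(md[risk_class == pr[2], sample_id], colnames(rpm))
    if (length(sa) < 2 || length(sb) < 2) {
      stop("risk classes need >= 2 samples each (", pr[1], " vs ", pr[2], ")")
    }
    res <- rbindlist(lapply(feats, function(f) {
      a <- rpm[f, sa]; b <- rpm[f, sb]
      p <- if (length(unique(c(a, b))) == 1L) 1 else wilcoxon_rank_sum(a, b)
      data.table(cluster_id = f, class_a = pr[1], class_b = pr[2],
                 logfc = logfc(mean(a), mean(b)), p = p)
    }))
    if (nrow(res)) res[, q := bh_adjust(p)][, pass := q < q_threshold]
    res
  }))
}

#' Kaplan-Meier curves and log-rank test for dichotomized expression
#'
#' Samples are split into high (`value > cutoff`) and low (`value <=
#' cutoff`) expression groups -- with the default median cutoff, a median
#' of 0 splits zero-expression versus positive samples -- and
#' progression-free survival is compared with the two-group log-rank test.
#'
#' @param values named per-sample expression values (e.g. one cluster's RPM
#'   or the per-sample total).
#' @param metadata sample metadata with sample_id, surv_time, surv_event
#'   (event 1 = progression; censored observations contribute risk-set
#'   time only).
#' @param cutoff `"median"` or a numeric value.
#' @return list: `cutoff`, `groups` (named factor), `fit`
#'   (`survival::survfit` object), `chisq`, `p`, `curves` (data.table:
#'   group, time, n_risk, n_event, surv).
#' @export
km_logrank <- function(values, metadata, cutoff = "median") {
  md <- as.data.table(metadata)[!is.na(surv_time) & !is.na(surv_event)]
  sm <- intersect(md$sample_id, names(values))
  if (!length(sm)) stop("no samples with both survival data and expression values")
  md <- md[sample_id %in% sm]
  v <- values[md$sample_id]
  cut_val <- if (identical(cutoff, "median")) median(v) else as.numeric(cutoff)
  grp <- factor(ifelse(v > cut_val, "high", "low"), levels = c("low", "high"))
  if (any(table(grp) == 0)) {
    stop("a group is empty after dichotomizing at ", signif(cut_val, 4),
         "; choose a different cutoff")
  }
  s <- survival::Surv(md$surv_time, md$surv_event)
  sd <- survival::survdiff(s ~ grp)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(s ~ grp)
  sf <- summary(fit)
  curves <- data.table(group = sub("^grp=", "", as.character(sf$strata)),
                       time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv)
  list(cutoff = cut_val, groups = setNames(grp, md$sample_id), fit = fit,
       chisq = unname(sd$chisq), p = p, curves = curves[])
}
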