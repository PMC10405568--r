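# Focused generators for single-analysis recovery checks, and the
# truth-comparison report for full pipeline runs.

#' Simulate BP-centred sequence windows with a planted motif
#'
#' Generates 101-nt RNA windows centred on a branch point (offset 0 at
#' position 51). A realized instance of the IUPAC motif is planted with hit
#' start at a lag drawn around `lag_mean` in a `prevalence` fraction of the
#' positive set and `prevalence / enrichment_fold` of the control set.
#'
#' @param n_pos,n_neg numbers of positive (lariat-host) and control windows.
#' @param motif IUPAC motif (RNA).
#' @param prevalence planted prevalence in the positive set.
#' @param enrichment_fold prevalence ratio positive/control.
#' @param lag_mean,lag_sd hit-start offset distribution (bp relative to BP).
#' @param width window width (odd; default 101).
#' @return list: `pos`, `neg` (named character vectors), `truth`
#'   (data.table: sequence_id, set, carrier, lag).
#' @export
simulate_bp_windows <- function(n_pos, n_neg, motif = "AYAUUAUUAAU",
                                prevalence = 0.094, enrichment_fold = 6.2,
                                lag_mean = -24, lag_sd = 8, width = 101L) {
  stopifnot(width %% 2L == 1L)
  half <- (width - 1L) %/% 2L
  k <- nchar(motif)
  gen <- function(n, prev, prefix) {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "U"), width, replace = TRUE), collapse = ""),
      character(1))
    carrier <- runif(n) < prev
    lag <- rep(NA_integer_, n)
    for (i in which(carrier)) {
      lg <- round(rnorm(1, lag_mean, lag_sd))
      lg <- min(max(lg, -half), half - k + 1L)
      inst <- chartr("T", "U", paste(.realize_iupac(motif), collapse = ""))
      idx <- half + 1L + lg
      substr(seqs[i], idx, idx + k - 1L) <- inst
      lag[i] <- lg
    }
    names(seqs) <- paste0(prefix, seq_len(n))
    list(seqs = seqs, truth = data.table(sequence_id = names(seqs),
                                         set = prefix, carrier = carrier,
                                         lag = lag))
  }
  p <- gen(n_pos, prevalence, "pos")
  q <- gen(n_neg, prevalence / enrichment_fold, "neg")
  list(pos = p$seqs, neg = q$seqs, truth = rbind(p$truth, q$truth))
}

#' Motif enrichment test between two window sets
#'
#' Scans both sets for the motif and tests the association between set
#' membership and motif presence (>= 1 hit) with Fisher's exact test.
#'
#' @param pos,neg character vectors of windows (see [simulate_bp_windows()]
#'   or [extract_windows()] sequences).
#' @param motif IUPAC motif.
#' @return list: `table` (2x2), `odds_ratio`, `p`, `summary_pos`,
#'   `summary_neg` ([motif_summary()] of each set).
#' @export
motif_enrichment <- function(pos, neg, motif) {
  # windows are anchor-centred; report offsets relative to the centre (BP)
  centre <- (nchar(pos[[1]]) + 1L) %/% 2L
  hp <- iupac_scan(pos, motif, anchor_index = centre)
  hn <- iupac_scan(neg, motif, anchor_index = centre)
  cp <- attr(hp, "hit_counts"); cn <- attr(hn, "hit_counts")
  tab <- matrix(c(sum(cp > 0), sum(cp == 0), sum(cn > 0), sum(cn == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("positive", "control"), c("hit", "no_hit")))
  ft <- fisher_2x2(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p,
       summary_pos = motif_summary(hp), summary_neg = motif_summary(hn))
}

#' Simulate a two-class count matrix with planted fold changes
#'
#' Negative-binomial junction counts for `n_features` clusters over two
#' risk classes; a fraction of features carries a `2^effect_logfc`-fold
#' mean shift up in class A.
#'
#' @param n_features number of clusters.
#' @param n_a,n_b samples per class.
#' @param fraction_affected fraction of features with the planted shift.
#' @param effect_logfc planted log2 fold change (class A over class B).
#' @param mu_meanlog,mu_sdlog log-normal distribution of baseline means.
#' @param nb_size negative-binomial size (inverse dispersion).
#' @param library_size common library size for the RPM scale.
#' @return list: `counts`, `rpm`, `metadata` (sample_id, library_size,
#'   risk_class), `truth` (data.table: cluster_id, affected).
#' @export
simulate_de_matrix <- function(n_features = 200L, n_a = 90L, n_b = 230L,
                               fraction_affected = 0.1, effect_logfc = 1,
                               mu_meanlog = log(20), mu_sdlog = 0.8,
                               nb_size = 2, library_size = 3e7) {
  feats <- sprintf("C%04d", seq_len(n_features))
  affected <- runif(n_features) < fraction_affected
  mu <- rlnorm(n_features, mu_meanlog, mu_sdlog)
  samples <- c(sprintf("A%03d", seq_len(n_a)), sprintf("B%03d", seq_len(n_b)))
  cls <- rep(c("1", "2"), c(n_a, n_b))
  mu_mat <- outer(mu, rep(1, n_a + n_b))
  mu_mat[affected, seq_len(n_a)] <- mu_mat[affected, seq_len(n_a)] * 2^effect_logfc
  counts <- matrix(rnbinom(length(mu_mat), mu = mu_mat, size = nb_size),
                   nrow = n_features, dimnames = list(feats, samples))
  md <- data.table(sample_id = samples, library_size = library_size,
                   risk_class = cls)
  list(counts = counts,
       rpm = rpm_normalize(counts, setNames(md$library_size, md$sample_id)),
       metadata = md,
       truth = data.table(cluster_id = feats, affected = affected))
}

#' Sensitivity and observed FDR of a differential-expression run
#'
#' @param de output of [differential_expression()] (one class pair).
#' @param truth truth table with cluster_id and affected.
#' @return list: `sensitivity` (affected features passing / affected
#'   features tested), `fdr` (non-affected among passing), `n_pass`.
#' @export
de_recovery <- function(de, truth) {
  x <- as.data.table(de)[as.data.table(truth), on = "cluster_id", nomatch = NULL]
  n_pass <- sum(x$pass)
  list(sensitivity = if (any(x$affected)) mean(x$pass[x$affected]) else NA_real_,
       fdr = if (n_pass) mean(!x$affected[x$pass]) else 0,
       n_pass = n_pass)
}

#' Simulate expression-coupled survival data
#'
#' Per-sample expression values are drawn log-normally; samples above the
#' median form the high-expression group with baseline exponential hazard,
#' the low group has `hazard * hr` (low expression carries the poorer
#' prognosis); censoring is exponential.
#'
#' @param n samples.
#' @param hazard baseline hazard (per month) of the high group.
#' @param hr hazard ratio of the low versus high group.
#' @param censor_rate exponential censoring rate (tuned for roughly 30%
#'   censoring at the defaults).
#' @param max_time administrative censoring horizon (months).
#' @return list: `values` (named expression), `metadata` (sample_id,
#'   library_size, surv_time, surv_event), `truth` (sample_id, group).
#' @export
simulate_survival <- function(n = 200L, hazard = 0.02, hr = 2,
                              censor_rate = 0.012, max_time = 120) {
  ids <- sprintf("P%03d", seq_len(n))
  v <- setNames(rlnorm(n, 0, 1), ids)
  grp <- ifelse(v > median(v), "high", "low")
  t_event <- rexp(n, ifelse(grp == "low", hazard * hr, hazard))
  t_cens <- pmin(rexp(n, censor_rate), max_time)
  md <- data.table(sample_id = ids, library_size = 3e7,
                   surv_time = pmin(t_event, t_cens),
                   surv_event = as.integer(t_event <= t_cens))
  list(values = v, metadata = md,
       truth = data.table(sample_id = ids, group = grp))
}

#' Simulate paired RNase R treated/control junction counts
#'
#' Circular junctions retain their abundance under RNase R treatment while
#' their linear counterparts are depleted by `depletion`-fold.
#'
#' @param n_junctions number of circular/linear junction pairs.
#' @param circ_mu,lin_mu mean control read counts.
#' @param depletion linear depletion factor in the treated sample.
#' @param nb_size negative-binomial size.
#' @param library_size per-sample library size (both samples).
#' @return list: `junctions` (input for [rnase_r_enrichment()]),
#'   `library_sizes`.
#' @export
simulate_rnase_r <- function(n_junctions = 200L, circ_mu = 20, lin_mu = 200,
                             depletion = 10, nb_size = 3, library_size = 3e7) {
  jt <- data.table(
    junction_id = sprintf("J%03d", seq_len(n_junctions)),
    circ_treated = rnbinom(n_junctions, mu = circ_mu * 1.5, size = nb_size),
    circ_control = rnbinom(n_junctions, mu = circ_mu, size = nb_size),
    lin_treated = rnbinom(n_junctions, mu = lin_mu / depletion, size = nb_size),
    lin_control = rnbinom(n_junctions, mu = lin_mu, size = nb_size))
  list(junctions = jt,
       library_sizes = c(treated = library_size, control = library_size))
}

#' Compare pipeline output against simulation ground truth
#'
#' @param clusters classified cluster table ([classify_clusters()]).
#' @param truth_clusters truth table from [simulate_sisrna()] (or read from
#'   `truth_clusters.tsv`).
#' @param min_samples clusters whose emitted reads reached fewer distinct
#'   samples are not expected to be recovered (default 2, matching the
#'   >= 2 samples expression rule).
#' @param de optional [de_recovery()] result to splice into the report.
#' @param motif_p optional motif-enrichment p-value; flagged against
#'   `motif_alpha`.
#' @param survival_p optional log-rank p-value; flagged against `alpha`.
#' @param motif_alpha,alpha detection thresholds (0.01 / 0.05).
#' @return list of class `truth_report`: `n_expected`, `n_recovered`,
#'   `cluster_recovery`, `confusion` (true class x called class),
#'   `class_accuracy`, `circle_recall`, `lariat_recall`, `bp_distances`
#'   (|representative end - true end| for recovered lariats), plus optional
#'   `de`, `motif_detected`, `survival_detected`.
#' @export
truth_compare <- function(clusters, truth_clusters, min_samples = 2L,
                          de = NULL, motif_p = NULL, survival_p = NULL,
                          motif_alpha = 0.01, alpha = 0.05) {
  tr <- as.data.table(truth_clusters)[emitted_samples >= min_samples]
  cl <- as.data.table(clusters)
  missing <- setdiff(cl$cluster_id, c(tr$cluster_id,
                                      as.data.table(truth_clusters)$cluster_id))
  j <- cl[tr, on = "cluster_id"]
  recovered <- !is.na(j$representative_end)
  conf <- table(true = j$true_class[recovered], called = j$cls[recovered],
                useNA = "ifany")
  recall <- function(klass) {
    sel <- j$true_class == klass
    if (!any(sel)) return(NA_real_)
    mean(!is.na(j$cls[sel]) & j$cls[sel] == klass)
  }
  lar <- j[true_class == "stable_lariat" & recovered]
  rep <- list(
    n_expected = nrow(tr),
    n_recovered = sum(recovered),
    n_unexpected = length(missing),
    cluster_recovery = if (nrow(tr)) mean(recovered) else NA_real_,
    confusion = conf,
    class_accuracy = if (sum(recovered))
      mean(j$cls[recovered] == j$true_class[recovered], na.rm = TRUE) else NA_real_,
    circle_recall = recall("intronic_circle"),
    lariat_recall = recall("stable_lariat"),
    bp_distances = abs(lar$representative_end - lar$true_end))
  if (!is.null(de)) rep$de <- de
  if (!is.null(motif_p)) rep$motif_detected <- motif_p < motif_alpha
  if (!is.null(survival_p)) rep$survival_detected <- survival_p < alpha
  structure(rep, class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  cat("truth comparison report\n")
  cat(sprintf("  clusters expected/recovered: %d/%d (recovery %.3f)\n",
              x$n_expected, x$n_recovered, x$cluster_recovery))
  cat(sprintf("  class accuracy %.3f (lariat recall %.3f, circle recall %.3f)\n",
              x$class_accuracy, x$lariat_recall, x$circle_recall))
  if (length(x$bp_distances)) {
    cat(sprintf("  BP distance: median %g, mean %.2f\n",
                median(x$bp_distances), mean(x$bp_distances)))
  }
  if (!is.null(x$de)) {
    cat(sprintf("  DE: sensitivity %.3f, FDR %.3f (n pass %d)\n",
                x$de$sensitivity, x$de$fdr, x$de$n_pass))
  }
  if (!is.null(x$motif_detected))
    cat("  motif enrichment detected:", x$motif_detected, "\n")
  if (!is.null(x$survival_detected))
    cat("  survival association detected:", x$survival_detected, "\n")
  invisible(x)
}
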