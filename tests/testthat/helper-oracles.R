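# Independent oracles used to verify the implementation: brute-force
# scans, exact enumerations, and hand-coded formula evaluations. These
# deliberately avoid the code paths they check.

# O(n) scan over all introns: shortest containing, then smaller start,
# then lexicographic id
oracle_host_scan <- function(q, introns) {
  out <- character(nrow(q))
  for (i in seq_len(nrow(q))) {
    cand <- introns[introns$chrom == q$chrom[i] & introns$strand == q$strand[i] &
                      introns$start <= q$start[i] & introns$end >= q$end[i], ]
    if (!nrow(cand)) { out[i] <- NA_character_; next }
    cand <- cand[order(cand$length, cand$start, cand$intron_id), ]
    out[i] <- cand$intron_id[1]
  }
  out
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of assignments
oracle_wilcoxon_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  lo <- mean(ws <= w_obs); hi <- mean(ws >= w_obs)
  min(1, 2 * min(lo, hi))
}

# two-sided Fisher p by hypergeometric enumeration (minimum-likelihood)
oracle_fisher_exact <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- dhyper(ks, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# BH step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m); q[o] <- q_sorted
  q
}

# Spearman via explicit mid-ranks and the Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# brute-force sliding-window IUPAC matcher (character-by-character)
oracle_motif_scan <- function(seq_rna, motif) {
  map <- Biostrings::IUPAC_CODE_MAP
  codes <- strsplit(chartr("U", "T", toupper(motif)), "")[[1]]
  allowed <- lapply(codes, function(cd) strsplit(map[[cd]], "")[[1]])
  s <- strsplit(chartr("U", "T", seq_rna), "")[[1]]
  k <- length(codes)
  hits <- integer(0)
  if (length(s) >= k) {
    for (st in seq_len(length(s) - k + 1L)) {
      ok <- TRUE
      for (j in seq_len(k)) {
        if (is.na(s[st + j - 1L]) || !(s[st + j - 1L] %in% allowed[[j]])) {
          ok <- FALSE; break
        }
      }
      if (ok) hits <- c(hits, st)
    }
  }
  hits
}

# two-group log-rank statistic from the O-E / hypergeometric-variance formula
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# per-base mean over an explicit position set (track stored as env lookup)
oracle_position_mean <- function(track_df, positions, missing_zero = FALSE) {
  sc <- track_df$score[match(positions, track_df$pos)]
  if (missing_zero) {
    sc[is.na(sc)] <- 0
    mean(sc)
  } else {
    if (all(is.na(sc))) NA_real_ else mean(sc, na.rm = TRUE)
  }
}

# tiny two-gene exon fixture shared across annotation tests
fixture_exons <- function() {
  data.table::data.table(
    chrom = "chr1",
    start = c(0L, 200L, 0L, 250L, 1000L, 1400L, 1800L),
    end = c(100L, 300L, 100L, 300L, 1100L, 1500L, 1900L),
    strand = c("+", "+", "+", "+", "-", "-", "-"),
    gene_id = c("GA", "GA", "GA", "GA", "GB", "GB", "GB"),
    transcript_id = c("GA_T1", "GA_T1", "GA_T2", "GA_T2",
                      "GB_T1", "GB_T1", "GB_T1")
  )
}

# deterministic random intron universe for property tests
fixture_random_introns <- function(n = 200L, seed = 42L) {
  set.seed(seed)
  start <- sample.int(100000L, n)
  len <- sample(50:5000, n, replace = TRUE)
  exons <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    data.table::data.table(
      chrom = sample(c("chr1", "chr2"), 1),
      start = c(start[i] - 50L, start[i] + len[i]),
      end = c(start[i], start[i] + len[i] + 50L),
      strand = sample(c("+", "-"), 1),
      gene_id = sprintf("R%04d", i),
      transcript_id = sprintf("R%04d_T1", i))
  }))
  circsis::build_unique_introns(exons)
}
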