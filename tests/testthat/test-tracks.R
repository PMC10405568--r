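library(data.table)

one_intron <- function(start = 100L, end = 200L, strand = "+",
                       kept = NULL) {
  ks <- if (is.null(kept)) list(start) else list(kept$starts)
  ke <- if (is.null(kept)) list(end) else list(kept$ends)
  data.table(intron_id = "i1", chrom = "chr1", start = start, end = end,
             strand = strand, gene_id = "G", length = end - start,
             kept_starts = ks, kept_ends = ke,
             kept_length = sum(unlist(ke) - unlist(ks)),
             n_blocks = length(unlist(ks)), is_host_candidate = TRUE)
}

test_that("bedGraph writer/reader round-trips per-base scores", {
  tr <- score_track(rep("chr1", 5), c(10L, 11L, 12L, 20L, 21L),
                    c(1, 1, 2, 0.5, 0.5), kind = "phyloP")
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  lines <- readLines(path)
  expect_length(lines, 3)  # runs collapsed: {10,11},{12},{20,21}
  back <- read_bedgraph(path, kind = "phyloP")
  expect_equal(back$pos, tr$pos)
  expect_equal(back$score, tr$score)
})

test_that("read blocks add depth only on kept intronic positions", {
  intr <- one_intron()
  reads <- data.table(read_id = "r1", sample_id = "s1", chrom = "chr1",
                      block_starts = "120", block_sizes = "60")
  d <- intron_depth_from_blocks(reads, intr)
  tr <- d$per_sample$s1
  expect_equal(range(tr$pos), c(120L, 179L))
  expect_true(all(tr$score == 1))
})

test_that("linearly spliced reads across the intron are excluded", {
  intr <- one_intron()
  reads <- data.table(
    read_id = c("spliced", "inside"), sample_id = "s1", chrom = "chr1",
    block_starts = c("80,210", "150"), block_sizes = c("10,20", "10"))
  d <- intron_depth_from_blocks(reads, intr)
  expect_equal(d$per_sample$s1$pos, 150:159)
  # a gap not spanning the whole intron does not exclude the read
  reads2 <- data.table(read_id = "partgap", sample_id = "s1", chrom = "chr1",
                       block_starts = "110,160", block_sizes = "10,10")
  d2 <- intron_depth_from_blocks(reads2, intr)
  expect_equal(d2$per_sample$s1$pos, c(110:119, 160:169))
})

test_that("reads over masked exonic blocks contribute nothing", {
  intr <- one_intron(kept = list(starts = c(100L, 180L), ends = c(140L, 200L)))
  reads <- data.table(read_id = "r", sample_id = "s1", chrom = "chr1",
                      block_starts = "150", block_sizes = "20")
  d <- intron_depth_from_blocks(reads, intr)
  expect_equal(nrow(d$per_sample$s1), 0L)
})

test_that("cross-sample depth averaging counts absent samples as zero", {
  intr <- one_intron()
  reads <- data.table(read_id = c("a", "b"), sample_id = c("s1", "s2"),
                      chrom = "chr1", block_starts = c("120", "120"),
                      block_sizes = c("10", "5"))
  d <- intron_depth_from_blocks(reads, intr)
  expect_equal(d$mean[pos == 121L, score], 1)    # covered in both samples
  expect_equal(d$mean[pos == 126L, score], 0.5)  # covered in s1 only
})

test_that("whole-intron means respect trims, kinds and the position oracle", {
  intr <- one_intron()
  const <- score_track("chr1", 100:199, rep(1, 100), kind = "phyloP")
  expect_equal(whole_intron_mean(const, intr), 1.0)
  # scores only inside the trimmed 10 bp ends -> mean 0 for depth
  edges <- score_track("chr1", c(100:109, 190:199), rep(2, 20), kind = "depth")
  expect_equal(whole_intron_mean(edges, intr), 0)
  # conservation with no scored interior positions is undefined
  edges_p <- score_track("chr1", c(100:109, 190:199), rep(2, 20), kind = "phyloP")
  expect_true(is.na(whole_intron_mean(edges_p, intr)))
  # random sparse fixture equals the brute-force per-base mean
  set.seed(21)
  pos <- sort(sample(100:199, 40))
  tr <- score_track("chr1", pos, rnorm(40), kind = "phyloP")
  expect_equal(whole_intron_mean(tr, intr),
               oracle_position_mean(tr, 110:189))
  trd <- score_track("chr1", pos, abs(rnorm(40)), kind = "depth")
  expect_equal(whole_intron_mean(trd, intr),
               oracle_position_mean(trd, 110:189, missing_zero = TRUE))
  expect_error(whole_intron_mean(const, one_intron(100L, 115L)), "trim")
})

test_that("whole-intron mean is invariant to kept-block splitting", {
  set.seed(22)
  tr <- score_track("chr1", 100:199, rnorm(100), kind = "phyloP")
  whole <- one_intron()
  split2 <- one_intron(kept = list(starts = c(100L, 150L), ends = c(150L, 200L)))
  expect_equal(whole_intron_mean(tr, whole), whole_intron_mean(tr, split2))
})

test_that("anchored profiles average strand-aware offsets", {
  intr <- one_intron()
  const <- score_track("chr1", 100:199, rep(0.5, 100), kind = "phyloP")
  prof <- anchored_profile(const, intr, anchor = "donor", span = c(0L, 10L))
  expect_true(all(prof$mean == 0.5))
  expect_true(all(prof$n == 1))
  # two introns contributing 0 and 1 at an offset average to 0.5
  both <- rbind(one_intron(), one_intron(300L, 400L)[, intron_id := "i2"])
  tr <- score_track("chr1", c(105L, 305L), c(0, 1), kind = "phyloP")
  p2 <- anchored_profile(tr, both, anchor = "donor", span = c(0L, 10L))
  expect_equal(p2[offset == 5, mean], 0.5)
  expect_equal(p2[offset == 5, n], 2L)
  expect_error(anchored_profile(const, intr[0], anchor = "donor"), "empty")
})

test_that("minus-strand profiles mirror genomic direction", {
  # minus intron [100, 200): donor at 199; offset +k maps to genomic 199-k
  intr <- one_intron(strand = "-")
  tr <- score_track("chr1", c(199L, 195L), c(7, 3), kind = "phyloP")
  prof <- anchored_profile(tr, intr, anchor = "donor", span = c(0L, 10L))
  expect_equal(prof[offset == 0, mean], 7)
  expect_equal(prof[offset == 4, mean], 3)
  # 3'SS anchor on minus strand sits at the span start; upstream is negative
  prof3 <- anchored_profile(tr, intr, anchor = "acceptor_3ss", span = c(-99L, 0L))
  expect_equal(prof3[offset == -99, mean], 7)
})

test_that("profile log fold changes behave at boundaries and antisymmetrically", {
  intr <- one_intron()
  trA <- score_track("chr1", 100:199, rep(2, 100), kind = "depth")
  trB <- score_track("chr1", 100:199, rep(1, 100), kind = "depth")
  pA <- anchored_profile(trA, intr, anchor = "donor", span = c(0L, 20L))
  pB <- anchored_profile(trB, intr, anchor = "donor", span = c(0L, 20L))
  same <- profile_logfc(pA, pA)
  expect_true(all(same$logfc == 0))
  expect_equal(attr(same, "fraction_exceeding"), 0)
  dbl <- profile_logfc(pA, pB)
  expect_true(all(abs(dbl$logfc - 1) < 1e-5))
  expect_equal(attr(dbl, "fraction_exceeding"), 0)  # strictly > 1 required
  expect_equal(profile_logfc(pA, pB)$logfc, -profile_logfc(pB, pA)$logfc)
  pC <- anchored_profile(trA, intr, anchor = "donor", span = c(0L, 5L))
  expect_error(profile_logfc(pA, pC), "offsets")
})

test_that("planted conservation elevation around the BP is localized", {
  set.seed(31)
  n <- 40L
  mk_introns <- function(prefix, offset0) {
    rbindlist(lapply(seq_len(n), function(i) {
      st <- offset0 + (i - 1L) * 1200L
      one_intron(st, st + 1000L)[, intron_id := paste0(prefix, i)]
    }))
  }
  lar <- mk_introns("L", 0L)
  ctl <- mk_introns("C", 60000L)
  bp_lar <- data.table(intron_id = lar$intron_id, pos = lar$end - 100L)
  bp_ctl <- data.table(intron_id = ctl$intron_id, pos = ctl$end - 100L)
  mkpos <- function(introns) unlist(mapply(seq.int, introns$start,
                                           introns$end - 1L, SIMPLIFY = FALSE))
  pos_l <- mkpos(lar); pos_c <- mkpos(ctl)
  base_l <- rnorm(length(pos_l), 0.25, 0.25)
  elev <- rep(FALSE, length(pos_l))
  for (i in seq_len(n)) {
    b <- bp_lar$pos[i]
    elev <- elev | (pos_l >= b - 50L & pos_l <= b + 50L)
  }
  tr_l <- score_track("chr1", pos_l, base_l + 1.5 * elev, kind = "phyloP")
  tr_c <- score_track("chr1", pos_c, rnorm(length(pos_c), 0.25, 0.25),
                      kind = "phyloP")
  pl <- anchored_profile(tr_l, lar, anchor = "bp", span = c(-80L, 80L), bp = bp_lar)
  pc <- anchored_profile(tr_c, ctl, anchor = "bp", span = c(-80L, 80L), bp = bp_ctl)
  lfc <- profile_logfc(pl, pc)
  expect_gt(attr(lfc, "fraction_exceeding"), 0.95)  # inside +-50: elevated
  outside <- lfc[abs(offset) > 60]
  expect_true(all(abs(outside$logfc) < 1))          # flat beyond the window
})
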