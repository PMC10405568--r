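library(data.table)

# one plus-strand and one minus-strand intron with a tiny genome whose
# bases are position-decodable (period-4 pattern ACGT)
bp_fixture <- function() {
  ex <- data.table(chrom = "chr1",
                   start = c(0L, 200L, 500L, 800L),
                   end = c(100L, 300L, 600L, 900L),
                   strand = c("+", "+", "-", "-"),
                   gene_id = c("GP", "GP", "GM", "GM"),
                   transcript_id = c("GP_T", "GP_T", "GM_T", "GM_T"))
  introns <- build_unique_introns(ex)  # [100,200)+ and [600,800)-
  genome <- Biostrings::DNAStringSet(
    c(chr1 = paste(rep(c("A", "C", "G", "T"), 250), collapse = "")))
  list(introns = introns, genome = genome)
}

test_that("branch-point assignment keeps the max-support in-span record", {
  fx <- bp_fixture()
  bp_map <- data.table(chrom = "chr1", pos = c(150L, 160L, 50L),
                       strand = "+", support = c(3, 10, 99))
  res <- assign_bp(fx$introns, bp_map)
  plus_id <- fx$introns[strand == "+", intron_id]
  expect_equal(res[intron_id == plus_id, pos], 160L)
  # support tie resolved toward the 3'SS
  tie <- assign_bp(fx$introns,
                   data.table(chrom = "chr1", pos = c(150L, 180L), strand = "+",
                              support = 5))
  expect_equal(tie[intron_id == plus_id, pos], 180L)
  # no in-span BP -> intron absent from result
  none <- assign_bp(fx$introns, data.table(chrom = "chr1", pos = 50L,
                                           strand = "+", support = 1))
  expect_equal(nrow(none), 0L)
})

test_that("BP nucleotides are genome-resolved and strand-complemented", {
  fx <- bp_fixture()
  # pattern ACGT: position p holds c("A","C","G","T")[p %% 4 + 1]
  res <- assign_bp(fx$introns,
                   data.table(chrom = "chr1", pos = c(150L, 700L),
                              strand = c("+", "-"), support = 1),
                   genome = fx$genome)
  expect_equal(res[intron_id == fx$introns[strand == "+", intron_id], nucleotide],
               "G")   # 150 %% 4 = 2 -> G
  expect_equal(res[intron_id == fx$introns[strand == "-", intron_id], nucleotide],
               "U")   # 700 %% 4 = 0 -> A, complement on minus -> T/U
})

test_that("3' tail lengths count bases beyond the BP and flag discards", {
  intr <- data.table(intron_id = "i1", chrom = "chr1", start = 100L, end = 200L,
                     strand = "+")
  expect_equal(tail_length(166L, intr)$tail, 33L)   # bases 167..199
  at_end <- tail_length(199L, intr)
  expect_equal(at_end$tail, 0L)
  expect_true(at_end$discarded)
  expect_true(tail_length(50L, intr)$discarded)     # upstream of the intron
  # minus strand: tail runs toward the span start
  intr_m <- data.table(intron_id = "i2", chrom = "chr1", start = 600L,
                       end = 800L, strand = "-")
  expect_equal(tail_length(633L, intr_m)$tail, 33L)
})

test_that("BP concordance summarizes per-intron distances", {
  a <- data.table(intron_id = c("i1", "i2", "i3"), pos = c(100L, 210L, 350L))
  b <- data.table(intron_id = c("i1", "i2", "i3"), pos = c(100L, 200L, 300L))
  cc <- bp_concordance(a, b)
  expect_equal(cc$distances, c(0L, 10L, 50L))
  expect_equal(cc$median, 10)
  expect_equal(cc$mean, 20)
  expect_equal(cc$fraction_below, 2 / 3)
  empty <- bp_concordance(a[0], b)
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$median))
})

test_that("windows are extracted 5'->3' with strand-aware offsets", {
  fx <- bp_fixture()
  w <- extract_windows(fx$introns, fx$genome, anchor = "donor", span = c(0L, 20L))
  plus <- w$seqs[fx$introns[strand == "+", intron_id], ]
  # + strand: offsets 0..20 map to genomic 100..120, pattern phase 0
  expect_equal(unname(plus[1:4]), c("A", "C", "G", "U"))
  minus <- w$seqs[fx$introns[strand == "-", intron_id], ]
  # - strand donor at 799 (phase 3 -> T), transcript direction descends
  expect_equal(unname(minus[1:2]), c("A", "C"))  # complement of T, G
  expect_equal(ncol(w$seqs), 21L)
})

test_that("BP windows drop short tails and mask near the 3'SS", {
  fx <- bp_fixture()
  bp <- data.table(intron_id = fx$introns$intron_id,
                   pos = c(195L, 700L))  # + intron BP tail 4; - intron tail 100
  w <- extract_windows(fx$introns, fx$genome, anchor = "bp", span = c(-10L, 10L),
                       bp = bp)
  expect_false(fx$introns[strand == "+", intron_id] %in% rownames(w$seqs))
  # masked positions: within 10 bp of the 3'SS (600 on minus strand)
  bp2 <- data.table(intron_id = fx$introns[strand == "-", intron_id], pos = 615L)
  w2 <- extract_windows(fx$introns, fx$genome, anchor = "bp", span = c(-10L, 10L),
                        bp = bp2)
  gpos <- 615L - (-10:10) * 1L  # minus strand: genomic = bp - offset... checked below
  masked <- is.na(w2$seqs[1, ])
  # offsets 6..10 reach genomic 609..605, all within 10 of 600 -> masked
  expect_true(all(masked[as.character(6:10)]))
  expect_false(any(masked[as.character(-10:5)]))
})

test_that("information content matches direct KL evaluation", {
  expect_equal(information_content(c(1, 0, 0, 0)), 2)
  expect_equal(information_content(rep(0.25, 4)), 0)
  expect_equal(information_content(c(0.5, 0.5, 0, 0)), 1)
  expect_error(information_content(c(1, 0, 0, 0), background = c(0.5, 0.5, 0, 0)),
               "positive")
  # strictly increases as mass concentrates
  lambda <- seq(0, 1, by = 0.1)
  bits <- vapply(lambda, function(l)
    information_content((1 - l) * rep(0.25, 4) + l * c(1, 0, 0, 0)), numeric(1))
  expect_true(all(diff(bits) > 0))
})

test_that("position profiles have valid frequencies and bits", {
  fx <- bp_fixture()
  w <- extract_windows(fx$introns, fx$genome, anchor = "donor", span = c(0L, 10L))
  prof <- position_profile(w)
  expect_true(all(abs(rowSums(prof$freq) - 1) < 1e-9))
  expect_true(all(prof$bits >= 0 & prof$bits <= 2))
  expect_equal(unname(prof$n), rep(2L, 11L))
})

test_that("IUPAC scanning matches the sliding-window oracle", {
  expect_equal(nrow(iupac_scan(c(s = "GGACAUUAUUAAUGG"), "AYAUUAUUAAU")), 1L)
  expect_equal(nrow(iupac_scan(c(s = strrep("G", 50)), "AYAUUAUUAAU")), 0L)
  expect_error(iupac_scan(c(s = "ACGU"), "AXU"), "IUPAC")
  set.seed(3)
  for (motif in c("AYAUUAUUAAU", "URAC", "YGCN")) {
    s <- paste(sample(c("A", "C", "G", "U"), 10000, replace = TRUE,
                      prob = c(0.35, 0.15, 0.15, 0.35)), collapse = "")
    hits <- iupac_scan(setNames(s, "x"), motif)
    expect_equal(hits$offset, oracle_motif_scan(s, motif), info = motif)
  }
})

test_that("overlapping motif matches are all reported", {
  hits <- iupac_scan(c(s = "AAAAAA"), "AAA")
  expect_equal(hits$offset, 1:4)
})

test_that("window hit offsets round-trip to genomic coordinates", {
  fx <- bp_fixture()
  # plant an unambiguous motif in both introns at known genomic spots
  chars <- strsplit(as.character(fx$genome[[1]]), "")[[1]]
  chars[141:146] <- c("T", "T", "C", "C", "T", "T")          # + strand, 140..145
  chars[701:706] <- rev(c("A", "A", "G", "G", "A", "A"))     # - strand complement
  genome2 <- Biostrings::DNAStringSet(c(chr1 = paste(chars, collapse = "")))
  bp <- data.table(intron_id = fx$introns$intron_id, pos = c(130L, 720L))
  w <- extract_windows(fx$introns, genome2, anchor = "bp", span = c(-15L, 25L),
                       bp = bp)
  hits <- iupac_scan(w, "UUCCUU")
  plus_id <- fx$introns[strand == "+", intron_id]
  minus_id <- fx$introns[strand == "-", intron_id]
  # + strand: genomic start 140 = BP 130 + offset 10
  expect_equal(hits[sequence_id == plus_id, offset], 10L)
  # - strand: transcript offset o maps to genomic BP - o; hit start at
  # genomic 705 (transcript 5' end of the match) -> offset 720 - 705 = 15
  expect_equal(hits[sequence_id == minus_id, offset], 15L)
})

test_that("masked window positions never contribute motif hits", {
  w <- structure(list(intron_id = "i", offsets = 1:6,
                      seqs = matrix(c("A", "A", NA, "A", "A", "A"), 1,
                                    dimnames = list("i", NULL))),
                 class = "seq_windows")
  expect_equal(iupac_scan(w, "AA")$offset, c(1L, 4L, 5L))  # none touching the NA
})

test_that("BP nucleotide fractions recover planted draws", {
  expect_equal(unname(bp_nucleotide_distribution(c("A", "A", "C", "G"))),
               c(0.5, 0.25, 0.25, 0))
  expect_equal(unname(bp_nucleotide_distribution(rep("A", 5)))[1], 1.0)
  expect_error(bp_nucleotide_distribution(character(0)))
  set.seed(8)
  pr <- c(A = 0.48, C = 0.27, G = 0.10, U = 0.15)
  draws <- sample(names(pr), 1000, replace = TRUE, prob = pr)
  fr <- bp_nucleotide_distribution(draws)
  sigma <- sqrt(pr * (1 - pr) / 1000)
  expect_true(all(abs(fr - pr) <= 3 * sigma))
})
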