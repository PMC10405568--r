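library(data.table)

# a one-gene annotation with a single 500 bp intron [100, 600) on the
# requested strand, plus biotype table
intron_fixture <- function(strand = "+", biotype = "protein_coding",
                           gene_id = "G1") {
  ex <- data.table(chrom = "chr1", start = c(0L, 600L), end = c(100L, 700L),
                   strand = strand, gene_id = gene_id,
                   transcript_id = paste0(gene_id, "_T"))
  list(introns = build_unique_introns(ex),
       genes = data.table(gene_id = gene_id, biotype = biotype,
                          chrom = "chr1", strand = strand))
}

write_bed <- function(rows) {
  path <- tempfile(fileext = ".bed")
  fwrite(rows, path, sep = "\t", col.names = FALSE)
  path
}

test_that("BED dialect resolves donor/acceptor by strand", {
  plus <- read_junction_table(write_bed(data.table(
    "chr1", 100L, 600L, "name", 5L, "+")), "circexplorer2_bed")
  expect_equal(plus$donor_pos, 100L)
  expect_equal(plus$acceptor_pos, 599L)
  expect_equal(plus$read_count, 5L)
  minus <- read_junction_table(write_bed(data.table(
    "chr1", 100L, 600L, "name", 5L, "-")), "circexplorer2_bed")
  expect_equal(minus$donor_pos, 599L)
  expect_equal(minus$acceptor_pos, 100L)
})

test_that("malformed junction rows are rejected and counted", {
  calls <- read_junction_table(write_bed(data.table(
    c("chr1", "chr1"), c(600L, 100L), c(100L, 600L), "n", 2L, "+")),
    "circexplorer2_bed")
  expect_equal(nrow(calls), 1L)
  expect_equal(attr(calls, "n_rejected"), 1L)
})

test_that("junction filters drop chrM, short circles, and ncRNA hosts", {
  fx <- intron_fixture()
  fx2 <- intron_fixture(biotype = "lincRNA", gene_id = "G2")
  nc_introns <- copy(fx2$introns)[, `:=`(start = start + 5000L, end = end + 5000L,
                                         kept_starts = lapply(kept_starts, `+`, 5000L),
                                         kept_ends = lapply(kept_ends, `+`, 5000L))]
  introns <- rbind(fx$introns, nc_introns)
  genes <- rbind(fx$genes, fx2$genes)
  calls <- data.table(
    sample_id = "s1", caller = "c1", chrom = c("chrM", "chr1", "chr1", "chr1"),
    strand = "+",
    donor_pos = c(100L, 150L, 100L, 5100L),
    acceptor_pos = c(400L, 170L, 500L, 5500L),  # lengths 301, 21, 401, 401
    read_count = c(3L, 3L, 3L, 3L))
  filt <- filter_junctions(calls, introns, genes)
  expect_equal(nrow(filt), 1L)
  expect_equal(filt$donor_pos, 100L)
  fc <- attr(filt, "filter_counts")
  expect_equal(unname(fc["removed_chrM"]), 1L)
  expect_equal(unname(fc["removed_length"]), 1L)
  expect_equal(unname(fc["removed_biotype"]), 1L)
  expect_equal(unname(fc["input"]),
               unname(sum(fc[c("removed_zero_reads", "removed_chrM",
                               "removed_length", "removed_no_host",
                               "removed_biotype", "kept")])))
})

test_that("calls with no containing intron are removed and counted", {
  fx <- intron_fixture()
  calls <- data.table(sample_id = "s1", caller = "c1", chrom = "chr1",
                      strand = "+", donor_pos = 2000L, acceptor_pos = 2400L,
                      read_count = 2L)
  filt <- filter_junctions(calls, fx$introns, fx$genes)
  expect_equal(nrow(filt), 0L)
  expect_equal(unname(attr(filt, "filter_counts")["removed_no_host"]), 1L)
})

test_that("collapsing picks the max-read member and conserves reads", {
  fx <- intron_fixture()
  calls <- data.table(
    sample_id = c("s1", "s1", "s2", "s2"), caller = "c1", chrom = "chr1",
    strand = "+", donor_pos = 100L,
    acceptor_pos = c(500L, 498L, 500L, 495L),
    read_count = c(3L, 2L, 2L, 1L))
  filt <- filter_junctions(calls, fx$introns, fx$genes)
  coll <- collapse_junctions(filt, fx$introns)
  expect_equal(nrow(coll$clusters), 1L)
  expect_equal(coll$clusters$representative_end, 500L)
  expect_equal(coll$clusters$total_reads, sum(calls$read_count))
  expect_equal(coll$clusters$n_members, 3L)
  expect_equal(coll$clusters$n_samples_expressed, 2L)
  expect_equal(unname(rowSums(coll$counts)), sum(calls$read_count))
})

test_that("distinct donors in one intron give distinct clusters", {
  fx <- intron_fixture()
  calls <- data.table(sample_id = "s1", caller = "c1", chrom = "chr1",
                      strand = "+", donor_pos = c(100L, 140L),
                      acceptor_pos = c(500L, 500L), read_count = 2L)
  filt <- filter_junctions(calls, fx$introns, fx$genes)
  coll <- collapse_junctions(filt, fx$introns)
  expect_equal(nrow(coll$clusters), 2L)
})

test_that("representative ties break by samples, then 3'SS proximity, then position", {
  fx <- intron_fixture()
  # tie on reads: end 520 seen in two samples beats end 500 in one
  calls <- data.table(
    sample_id = c("s1", "s2", "s3"), caller = "c1", chrom = "chr1",
    strand = "+", donor_pos = 100L, acceptor_pos = c(500L, 520L, 520L),
    read_count = c(5L, 3L, 2L))
  coll <- collapse_junctions(filter_junctions(calls, fx$introns, fx$genes),
                             fx$introns)
  expect_equal(coll$clusters$representative_end, 520L)
  # full tie on reads and samples: closer to the 3'SS (599) wins
  calls2 <- data.table(
    sample_id = c("s1", "s2"), caller = "c1", chrom = "chr1", strand = "+",
    donor_pos = 100L, acceptor_pos = c(480L, 560L), read_count = 4L)
  coll2 <- collapse_junctions(filter_junctions(calls2, fx$introns, fx$genes),
                              fx$introns)
  expect_equal(coll2$clusters$representative_end, 560L)
})

test_that("cluster tables are invariant to row and sample order", {
  fx <- intron_fixture()
  set.seed(5)
  calls <- data.table(
    sample_id = sample(paste0("s", 1:4), 40, replace = TRUE), caller = "c1",
    chrom = "chr1", strand = "+",
    donor_pos = sample(c(100L, 130L), 40, replace = TRUE),
    acceptor_pos = sample(c(500L, 510L, 520L), 40, replace = TRUE),
    read_count = sample(1:5, 40, replace = TRUE))
  filt <- filter_junctions(calls, fx$introns, fx$genes)
  a <- collapse_junctions(filt, fx$introns)
  b <- collapse_junctions(filt[sample(nrow(filt))], fx$introns)
  expect_equal(a$clusters, b$clusters)
  expect_equal(a$counts, b$counts)
})

test_that("classification separates 3'SS-ending circles from lariats", {
  fx <- intron_fixture()  # intron [100, 600), 3'SS at 599
  clusters <- data.table(cluster_id = c("a", "b", "c"),
                         intron_id = fx$introns$intron_id,
                         representative_end = c(599L, 569L, 598L))
  cls0 <- classify_clusters(clusters, fx$introns, tol_3ss = 0L)
  expect_equal(cls0$cls, c("intronic_circle", "stable_lariat", "stable_lariat"))
  cls1 <- classify_clusters(clusters, fx$introns, tol_3ss = 1L)
  expect_equal(cls1$cls, c("intronic_circle", "stable_lariat", "intronic_circle"))
})

test_that("classification is strand-aware (3'SS = span start on minus)", {
  fx <- intron_fixture(strand = "-")
  clusters <- data.table(cluster_id = c("a", "b"),
                         intron_id = fx$introns$intron_id,
                         representative_end = c(100L, 140L))
  cls <- classify_clusters(clusters, fx$introns)
  expect_equal(cls$cls, c("intronic_circle", "stable_lariat"))
})

test_that("representative ends outside the host intron are excluded", {
  fx <- intron_fixture()
  clusters <- data.table(cluster_id = "a", intron_id = fx$introns$intron_id,
                         representative_end = 700L)
  cls <- classify_clusters(clusters, fx$introns)
  expect_true(is.na(cls$cls))
  expect_equal(attr(cls, "n_excluded"), 1L)
})

test_that("RPM normalization scales by library size and is ratio-invariant", {
  m <- matrix(c(2L, 0L, 4L, 6L), 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  ls <- c(s1 = 1e6, s2 = 2e6)
  rpm <- rpm_normalize(m, ls)
  expect_equal(rpm["f1", "s1"], 2.0)
  expect_equal(rpm["f2", "s1"], 0.0)
  expect_equal(rpm["f1", "s2"], 2.0)
  expect_equal(rpm_normalize(2L * m, 2 * ls), rpm)
  expect_error(rpm_normalize(m, c(s1 = 1e6)), "s2")
})

test_that("caller overlap matches a brute-force pairwise matcher", {
  set.seed(11)
  base <- data.table(chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
                     strand = sample(c("+", "-"), 50, replace = TRUE),
                     donor_pos = sample.int(100000L, 50),
                     representative_end = sample.int(100000L, 50))
  jit <- copy(base)[, representative_end := representative_end +
                      sample(-3:3, .N, replace = TRUE)]
  ov <- caller_overlap(list(a = base, b = jit), tol = 3L)
  expect_equal(ov$fraction_supported, 1.0)
  disjoint <- copy(base)[, chrom := "chr9"]
  ov0 <- caller_overlap(list(a = base, b = disjoint), tol = 3L)
  expect_equal(ov0$fraction_supported, 0.0)
  # brute-force oracle at tol = 1 on jittered sets
  ov1 <- caller_overlap(list(a = base, b = jit), tol = 1L)
  oracle <- vapply(seq_len(nrow(base)), function(i) {
    any(jit$chrom == base$chrom[i] & jit$strand == base$strand[i] &
          abs(jit$donor_pos - base$donor_pos[i]) <= 1 &
          abs(jit$representative_end - base$representative_end[i]) <= 1)
  }, logical(1))
  expect_equal(ov1$flags[caller == "a", supported], oracle)
})

test_that("identical caller sets fully overlap", {
  s <- data.table(chrom = "chr1", strand = "+", donor_pos = c(10L, 50L),
                  representative_end = c(200L, 400L))
  expect_equal(caller_overlap(list(a = s, b = copy(s)), tol = 0L)$fraction_supported, 1)
})
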