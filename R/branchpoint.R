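# Branch point assignment, 3' tails, sequence-context windows, information
# content and IUPAC motif scanning.
#
# Branch points (BPs) are 0-based single positions. Two BP sources are
# supported and reported side by side, never merged: caller-inferred BPs
# (the representative 3' end of a stable-lariat cluster) and an external
# experimentally mapped BP table (chrom, pos, strand, support).

#' Assign an external-map branch point to each intron
#'
#' Among map BPs falling inside the intron span (same chrom and strand), the
#' record with maximum support is returned; ties are broken by proximity to
#' the 3' splice site, then by the leftmost genomic position.
#'
#' @param introns intron table ([build_unique_introns()]).
#' @param bp_map data.frame with chrom, pos (0-based), strand, support.
#' @return data.table with one row per intron having an in-span BP:
#'   intron_id, pos, support, nucleotide (NA unless `genome` given).
#' @param genome optional `DNAStringSet` to resolve the BP nucleotide
#'   (reverse-complemented on the minus strand, reported in RNA alphabet).
#' @export
assign_bp <- function(introns, bp_map, genome = NULL) {
  bp <- as.data.table(bp_map)
  if (!nrow(bp)) return(data.table(intron_id = character(), pos = integer(),
                                   support = numeric(), nucleotide = character()))
  igr <- .gr0(introns$chrom, introns$start, introns$end, introns$strand)
  bgr <- .gr0(bp$chrom, bp$pos, bp$pos + 1L, bp$strand)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(bgr, igr, type = "within"))
  h <- data.table(bi = S4Vectors::queryHits(hits), ii = S4Vectors::subjectHits(hits))
  if (!nrow(h)) return(data.table(intron_id = character(), pos = integer(),
                                  support = numeric(), nucleotide = character()))
  h[, `:=`(intron_id = introns$intron_id[ii],
           pos = bp$pos[bi], support = bp$support[bi])]
  i3 <- .three_prime(introns$start, introns$end, introns$strand)
  h[, d3 := abs(pos - i3[ii])]
  setorder(h, intron_id, -support, d3, pos)
  out <- h[, .SD[1], by = intron_id][, .(intron_id, pos, support)]
  out[, nucleotide := if (is.null(genome)) NA_character_ else {
    st <- setNames(introns$strand, introns$intron_id)[intron_id]
    ch <- setNames(introns$chrom, introns$intron_id)[intron_id]
    .genome_base(genome, ch, pos, st)
  }]
  out[]
}

# single-base lookup, strand aware, RNA alphabet
.genome_base <- function(genome, chrom, pos, strand) {
  vapply(seq_along(pos), function(i) {
    b <- as.character(Biostrings::subseq(genome[[chrom[i]]], pos[i] + 1L, pos[i] + 1L))
    if (strand[i] == "-") b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    chartr("T", "U", b)
  }, character(1))
}

#' 3' tail length of a branch point
#'
#' The number of intronic bases strictly 3' of the BP (between the branch
#' point and the 3' splice site). Lengths <= `min_tail_keep` or negative
#' (BP outside the span) are flagged as discarded, as such values can arise
#' from truncated non-exon-overlapping annotations.
#'
#' @param bp_pos BP positions (0-based genomic).
#' @param introns intron rows matched positionally to `bp_pos` (or pass
#'   single-intron tables repeatedly).
#' @param min_tail_keep tails `<=` this value are discarded (default 1).
#' @return data.table: intron_id, tail, discarded.
#' @export
tail_length <- function(bp_pos, introns, min_tail_keep = 1L) {
  x <- as.data.table(introns)
  stopifnot(length(bp_pos) == nrow(x))
  tail <- ifelse(x$strand == "-", bp_pos - x$start, x$end - 1L - bp_pos)
  # BP outside the span on either side counts as negative/invalid
  outside <- bp_pos < x$start | bp_pos >= x$end
  tail[outside & tail > 0] <- -tail[outside & tail > 0]
  data.table(intron_id = x$intron_id, tail = as.integer(tail),
             discarded = tail <= min_tail_keep)
}

#' Concordance between caller-inferred and externally mapped branch points
#'
#' @param caller_bps data.frame with intron_id, pos (caller BPs, e.g.
#'   representative ends of stable-lariat clusters).
#' @param map_bps data.frame with intron_id, pos (external map, e.g.
#'   [assign_bp()] output).
#' @param threshold distance (bp) for the reported fraction (default 20).
#' @return list: `distances` (per shared intron), `median`, `mean`,
#'   `fraction_below` (fraction < threshold), `n`.
#' @export
bp_concordance <- function(caller_bps, map_bps, threshold = 20L) {
  a <- as.data.table(caller_bps)[, .(intron_id, caller_pos = pos)]
  b <- as.data.table(map_bps)[, .(intron_id, map_pos = pos)]
  j <- a[b, on = "intron_id", nomatch = NULL]
  d <- abs(j$caller_pos - j$map_pos)
  list(distances = d,
       median = if (length(d)) median(d) else NA_real_,
       mean = if (length(d)) mean(d) else NA_real_,
       fraction_below = if (length(d)) mean(d < threshold) else NA_real_,
       n = length(d))
}

#' Extract anchored, strand-aware sequence windows
#'
#' Sequences are reported 5'->3' in the direction of transcription (RNA
#' alphabet); offsets are transcript-oriented, negative upstream of the
#' anchor. Positions outside the chromosome or outside the intron span are
#' masked (NA). For `anchor = "bp"`, introns whose BP to 3'SS tail is below
#' `min_tail` are dropped entirely, and in-window positions within
#' `mask_3ss` bases of the 3' splice site are masked to avoid splice-site
#' signal bleeding into BP summaries.
#'
#' @param introns intron table.
#' @param genome named `DNAStringSet`.
#' @param anchor `"donor"` (5'SS), `"acceptor_3ss"` (3'SS) or `"bp"`.
#' @param span integer length-2 vector of offsets, e.g. `c(-10, 10)`.
#' @param bp data.frame intron_id, pos; required for `anchor = "bp"`.
#' @param mask_3ss mask radius around the 3'SS for BP windows (default 10).
#' @param min_tail minimum BP tail for inclusion in BP windows (default 10).
#' @return object of class `seq_windows`: list with `intron_id`, `offsets`,
#'   and `seqs`, a character matrix (introns x offsets) over A/C/G/U with NA
#'   at masked positions.
#' @export
extract_windows <- function(introns, genome, anchor = c("donor", "acceptor_3ss", "bp"),
                            span = c(-10L, 10L), bp = NULL, mask_3ss = 10L,
                            min_tail = 10L) {
  anchor <- match.arg(anchor)
  x <- as.data.table(introns)
  if (anchor == "bp") {
    if (is.null(bp)) stop("anchor = 'bp' requires a bp table (intron_id, pos)")
    bp <- as.data.table(bp)
    x <- x[bp, on = "intron_id", nomatch = NULL]
    tl <- tail_length(x$pos, x, min_tail_keep = 1L)
    keep <- tl$tail >= min_tail
    x <- x[keep]
    apos <- x$pos
  } else if (anchor == "donor") {
    apos <- .five_prime(x$start, x$end, x$strand)
  } else {
    apos <- .three_prime(x$start, x$end, x$strand)
  }
  offsets <- seq.int(span[1], span[2])
  n <- nrow(x)
  seqs <- matrix(NA_character_, n, length(offsets),
                 dimnames = list(x$intron_id, as.character(offsets)))
  if (n) {
    dirsign <- ifelse(x$strand == "-", -1L, 1L)
    chrlen <- setNames(Biostrings::width(genome), names(genome))
    i3 <- .three_prime(x$start, x$end, x$strand)
    for (i in seq_len(n)) {
      gpos <- apos[i] + dirsign[i] * offsets
      ok <- gpos >= 0L & gpos < chrlen[x$chrom[i]] & gpos >= x$start[i] & gpos < x$end[i]
      if (anchor == "bp") ok <- ok & abs(gpos - i3[i]) >= mask_3ss
      if (!any(ok)) next
      lo <- min(gpos[ok]); hi <- max(gpos[ok])
      sub <- strsplit(as.character(
        Biostrings::subseq(genome[[x$chrom[i]]], lo + 1L, hi + 1L)), "")[[1]]
      base <- sub[gpos[ok] - lo + 1L]
      if (x$strand[i] == "-") base <- chartr("ACGT", "TGCA", base)
      seqs[i, ok] <- chartr("T", "U", base)
    }
  }
  structure(list(intron_id = x$intron_id, offsets = offsets, seqs = seqs,
                 anchor = anchor), class = "seq_windows")
}

#' Per-offset nucleotide frequencies and information content
#'
#' Frequencies are computed over unmasked sequences at each offset and the
#' information content in bits via Kullback-Leibler divergence against the
#' background (uniform by default), see [information_content()].
#'
#' @param windows a `seq_windows` object from [extract_windows()].
#' @param background background nucleotide distribution (A, C, G, U).
#' @return list of class `position_profile`: `offsets`, `freq` (offsets x 4
#'   matrix), `bits`, `n` (sequences contributing per offset).
#' @export
position_profile <- function(windows, background = rep(0.25, 4)) {
  nts <- c("A", "C", "G", "U")
  freq <- t(apply(windows$seqs, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(rep(NA_real_, 4))
    tabulate(factor(col, levels = nts), nbins = 4) / length(col)
  }))
  colnames(freq) <- nts
  n <- colSums(!is.na(windows$seqs))
  bits <- apply(freq, 1, information_content, background = background)
  structure(list(offsets = windows$offsets, freq = freq, bits = bits, n = n),
            class = "position_profile")
}

#' Information content of a nucleotide distribution (bits)
#'
#' Kullback-Leibler divergence of the observed frequencies from the
#' background, `sum(p * log2(p / q))` with `0 * log(0) := 0`. Under a
#' uniform background this ranges from 0 (uniform) to 2 bits (single base).
#'
#' @param p frequency vector (sums to 1).
#' @param background background distribution; must have no zero entries.
#' @return bits (scalar; NA if `p` contains NA).
#' @export
information_content <- function(p, background = rep(0.25, length(p))) {
  if (any(background <= 0)) stop("background must have strictly positive entries")
  if (anyNA(p)) return(NA_real_)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / background[nz]))
}

.iupac_regex <- function(motif) {
  map <- Biostrings::IUPAC_CODE_MAP
  codes <- strsplit(chartr("U", "T", toupper(motif)), "")[[1]]
  if (!all(codes %in% names(map))) {
    stop("invalid IUPAC code(s): ",
         paste(unique(codes[!codes %in% names(map)]), collapse = ""))
  }
  paste0(vapply(codes, function(cd) {
    ex <- map[[cd]]
    if (nchar(ex) == 1) ex else paste0("[", ex, "]")
  }, character(1)), collapse = "")
}

#' Scan sequences for a degenerate IUPAC motif
#'
#' Exact degenerate matching on the given strand; all (possibly
#' overlapping) matches are reported. Matches overlapping a masked (NA)
#' position are discarded. Offsets are reported relative to the window
#' anchor (for BP-centred windows: hit start offset relative to the BP,
#' negative upstream).
#'
#' @param windows a `seq_windows` object, or a character vector of RNA
#'   sequences (then offsets are 1-based start positions, or positions
#'   relative to `anchor_index` when given).
#' @param motif IUPAC motif string (RNA codes, e.g. `"AYAUUAUUAAU"`).
#' @param anchor_index for character input only: 1-based position of the
#'   anchor (e.g. the BP at position 51 of a 101-nt window); hit offsets
#'   become `start - anchor_index`, negative upstream.
#' @return data.table of hits: sequence_id, offset, match; per-sequence hit
#'   counts in `attr(, "hit_counts")` (named integer vector covering all
#'   scanned sequences, zeros included).
#' @export
iupac_scan <- function(windows, motif, anchor_index = NULL) {
  if (is.character(windows)) {
    ids <- if (!is.null(names(windows))) names(windows) else
      paste0("seq", seq_along(windows))
    seqs <- lapply(strsplit(windows, ""), chartr, old = "U", new = "T")
    a0 <- if (is.null(anchor_index)) 0L else as.integer(anchor_index)
    offs <- lapply(seqs, function(s) seq_along(s) - a0)
  } else {
    ids <- windows$intron_id
    seqs <- lapply(seq_len(nrow(windows$seqs)), function(i)
      chartr("U", "T", windows$seqs[i, ]))
    offs <- rep(list(windows$offsets), length(seqs))
  }
  k <- nchar(motif)
  rx <- paste0("(?=", .iupac_regex(motif), ")")
  hits <- vector("list", length(seqs))
  counts <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    masked <- is.na(s)
    s[masked] <- "N"
    m <- gregexpr(rx, paste(s, collapse = ""), perl = TRUE)[[1]]
    st <- m[m > 0]
    if (length(st)) {
      # drop matches touching masked positions (N would match any code)
      ok <- vapply(st, function(p) !any(masked[p:(p + k - 1L)]), logical(1))
      st <- st[ok]
    }
    counts[i] <- length(st)
    if (length(st)) {
      hits[[i]] <- data.table(
        sequence_id = ids[i], offset = offs[[i]][st],
        match = vapply(st, function(p)
          chartr("T", "U", paste(s[p:(p + k - 1L)], collapse = "")), character(1)))
    }
  }
  out <- rbindlist(hits)
  if (!nrow(out)) out <- data.table(sequence_id = character(), offset = integer(),
                                    match = character())
  setattr(out, "hit_counts", setNames(counts, ids))
  out[]
}

#' Summarize motif scan results
#'
#' @param hits output of [iupac_scan()].
#' @return list: `n_sequences`, `fraction_with_hit`, `hit_count_table`
#'   (histogram of per-sequence hit counts), `fraction_single_hit` (among
#'   sequences with >= 1 hit), `median_offset` of all hits.
#' @export
motif_summary <- function(hits) {
  counts <- attr(hits, "hit_counts")
  pos <- counts[counts > 0]
  list(n_sequences = length(counts),
       fraction_with_hit = if (length(counts)) mean(counts > 0) else NA_real_,
       hit_count_table = table(counts),
       fraction_single_hit = if (length(pos)) mean(pos == 1) else NA_real_,
       median_offset = if (nrow(hits)) median(hits$offset) else NA_real_)
}

#' Branch point nucleotide distribution
#'
#' @param nucleotides character vector over A/C/G/U.
#' @return named fractions over A, C, G, U (sum to 1).
#' @export
bp_nucleotide_distribution <- function(nucleotides) {
  nts <- c("A", "C", "G", "U")
  x <- nucleotides[!is.na(nucleotides)]
  if (!length(x)) stop("no branch point nucleotides supplied")
  if (!all(x %in% nts)) stop("nucleotides must be A/C/G/U")
  tabulate(factor(x, levels = nts), nbins = 4) |>
    (\(t) setNames(t / sum(t), nts))()
}
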