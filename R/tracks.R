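# Per-base score tracks: read depth and phyloP conservation.
#
# A score track is stored sparsely as a data.table (chrom, pos, score) with
# 0-based positions and an attribute `kind`. For depth tracks an absent
# position means score 0; for conservation (phyloP) tracks an absent
# position is missing and is excluded from means (phyloP is signed, so zero
# is a meaningful value, not a missing one).

#' Construct a score track
#'
#' @param chrom,pos,score parallel vectors (0-based positions).
#' @param kind `"depth"` or `"phyloP"`.
#' @param label optional sample/group label.
#' @return a `score_track` data.table keyed by (chrom, pos).
#' @export
score_track <- function(chrom, pos, score, kind = c("depth", "phyloP"),
                        label = NA_character_) {
  kind <- match.arg(kind)
  if (any(pos < 0)) stop("track positions must be non-negative")
  x <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                  score = as.numeric(score))
  x <- x[, .(score = sum(score)), by = .(chrom, pos)]  # duplicates summed
  setkey(x, chrom, pos)
  setattr(x, "kind", kind)
  setattr(x, "label", label)
  x[]
}

#' Read a bedGraph file into a score track
#'
#' bedGraph intervals (0-based half-open) are expanded to per-base scores.
#' Track definition lines (`track ...`) are skipped.
#'
#' @param path bedGraph file.
#' @param kind,label see [score_track()].
#' @return a `score_track`.
#' @export
read_bedgraph <- function(path, kind = c("depth", "phyloP"), label = NA_character_) {
  kind <- match.arg(kind)
  first <- readLines(path, n = 1L)
  skip <- if (length(first) && grepl("^(track|#)", first)) 1L else 0L
  x <- fread(path, sep = "\t", header = FALSE, skip = skip,
             col.names = c("chrom", "start", "end", "score"))
  if (any(x$end <= x$start)) stop("bedGraph intervals must have end > start")
  per <- x[, .(pos = seq.int(start, end - 1L), score = score),
           by = .(row = seq_len(nrow(x)), chrom)][, row := NULL]
  score_track(per$chrom, per$pos, per$score, kind = kind, label = label)
}

#' Write a score track as bedGraph
#'
#' Consecutive positions with equal score are collapsed into intervals.
#'
#' @param track a `score_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  x <- copy(as.data.table(track))
  setorder(x, chrom, pos)
  x[, run := cumsum(c(1L, diff(pos) != 1L)) , by = chrom]
  x[, run2 := rleid(run, score), by = chrom]
  runs <- x[, .(start = pos[1], end = pos[.N] + 1L, score = score[1]),
            by = .(chrom, run2)][, run2 := NULL]
  fwrite(runs, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# positions of an intron's kept_blocks as an integer vector
.kept_positions <- function(intron_row) {
  ks <- intron_row$kept_starts[[1]]
  ke <- intron_row$kept_ends[[1]]
  if (!length(ks)) return(integer(0))
  unlist(mapply(seq.int, ks, ke - 1L, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Per-sample intron read-depth from aligned read blocks
#'
#' Reads are given as their aligned blocks (alignment gaps between blocks
#' are splices). A read is excluded from an intron when one of its splice
#' gaps spans the whole intron (linearly spliced across it: gap start <=
#' intron start and gap end >= intron end). Remaining reads add +1 to every
#' covered position of the intron's kept (non-exon-overlapping) blocks.
#'
#' @param reads data.frame with read_id, sample_id, chrom, and
#'   `block_starts` / `block_sizes` (comma-separated, 0-based genomic).
#' @param introns intron table.
#' @return list with `per_sample` (named list of depth `score_track`s) and
#'   `mean` (a depth track of position-wise means across samples, absent
#'   positions counting 0).
#' @export
intron_depth_from_blocks <- function(reads, introns) {
  rd <- as.data.table(reads)
  split_int <- function(s) as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  bl <- rd[, {
    bs <- split_int(block_starts); sz <- split_int(block_sizes)
    .(bstart = bs, bend = bs + sz)
  }, by = .(read_id, sample_id, chrom)]
  gaps <- bl[, if (.N >= 2L) .(gstart = head(bend, -1L), gend = tail(bstart, -1L)),
             by = .(read_id, sample_id, chrom)]
  if (!"gstart" %in% names(gaps)) {
    gaps <- data.table(read_id = character(), sample_id = character(),
                       chrom = character(), gstart = integer(), gend = integer())
  }
  samples <- sort(unique(rd$sample_id))
  x <- as.data.table(introns)
  per_sample <- lapply(samples, function(sm) {
    acc <- vector("list", nrow(x))
    for (i in seq_len(nrow(x))) {
      ir <- x[i]
      g <- gaps[sample_id == sm & chrom == ir$chrom &
                  gstart <= ir$start & gend >= ir$end]
      excluded <- unique(g$read_id)
      b <- bl[sample_id == sm & chrom == ir$chrom & !read_id %in% excluded &
                bend > ir$start & bstart < ir$end]
      if (!nrow(b)) next
      kp <- .kept_positions(ir)
      if (!length(kp)) next
      cov <- integer(length(kp))
      for (j in seq_len(nrow(b))) {
        cov <- cov + (kp >= b$bstart[j] & kp < b$bend[j])
      }
      nz <- cov > 0
      if (any(nz)) acc[[i]] <- data.table(chrom = ir$chrom, pos = kp[nz],
                                          score = cov[nz])
    }
    d <- rbindlist(acc)
    if (!nrow(d)) d <- data.table(chrom = character(), pos = integer(),
                                  score = numeric())
    score_track(d$chrom, d$pos, d$score, kind = "depth", label = sm)
  })
  names(per_sample) <- samples
  all <- rbindlist(per_sample)
  mean_track <- if (nrow(all)) {
    m <- all[, .(score = sum(score) / length(samples)), by = .(chrom, pos)]
    score_track(m$chrom, m$pos, m$score, kind = "depth", label = "mean")
  } else score_track(character(), integer(), numeric(), kind = "depth",
                     label = "mean")
  list(per_sample = per_sample, mean = mean_track)
}

#' Mean track score across a whole intron
#'
#' Mean of per-base scores over the intron's kept (non-exon-overlapping)
#' blocks, excluding the first and last `trim` bases of the span (splice
#' site signal). For conservation tracks, unscored positions are excluded
#' from numerator and denominator; for depth tracks they count as 0.
#'
#' @param track a `score_track`.
#' @param intron a single intron row.
#' @param trim bases trimmed at each span end (default 10).
#' @return mean score (NA if no scored position remains).
#' @export
whole_intron_mean <- function(track, intron, trim = 10L) {
  ir <- as.data.table(intron)
  if (nrow(ir) != 1L) stop("whole_intron_mean expects a single intron row")
  if (ir$length <= 2L * trim) stop("intron span must exceed 2 * trim")
  kp <- .kept_positions(ir)
  kp <- kp[kp >= ir$start + trim & kp < ir$end - trim]
  if (!length(kp)) return(NA_real_)
  sc <- track[.(rep(ir$chrom, length(kp)), kp), score, on = c("chrom", "pos")]
  if (identical(attr(track, "kind"), "depth")) {
    sc[is.na(sc)] <- 0
    mean(sc)
  } else {
    if (all(is.na(sc))) NA_real_ else mean(sc, na.rm = TRUE)
  }
}

#' Anchored positional score profile across introns
#'
#' For each transcript-oriented offset relative to the anchor, the mean
#' score over contributing introns. An intron contributes at an offset only
#' where the position lies inside its span (and, for BP anchors, respects
#' the 3'SS mask and minimum-tail rule, mirroring [extract_windows()]).
#' Depth tracks count unscored in-span positions as 0; conservation tracks
#' exclude them.
#'
#' @param track a `score_track`.
#' @param introns intron table (the profile group).
#' @param anchor `"donor"`, `"acceptor_3ss"` or `"bp"`.
#' @param span offset range, e.g. `c(-50, 50)`.
#' @param bp BP table (intron_id, pos) for `anchor = "bp"`.
#' @param mask_3ss,min_tail see [extract_windows()].
#' @param group label stored on the result.
#' @return `profile_matrix`: data.table (offset, mean, n) with attributes
#'   `anchor` and `group`.
#' @export
anchored_profile <- function(track, introns, anchor = c("donor", "acceptor_3ss", "bp"),
                             span = c(-50L, 50L), bp = NULL, mask_3ss = 10L,
                             min_tail = 10L, group = NA_character_) {
  anchor <- match.arg(anchor)
  x <- as.data.table(introns)
  if (!nrow(x)) stop("empty intron group", if (!is.na(group)) paste0(": ", group))
  if (anchor == "bp") {
    if (is.null(bp)) stop("anchor = 'bp' requires a bp table")
    x <- x[as.data.table(bp), on = "intron_id", nomatch = NULL]
    tl <- tail_length(x$pos, x, min_tail_keep = 1L)
    x <- x[tl$tail >= min_tail]
    if (!nrow(x)) stop("no introns pass the BP tail rule",
                       if (!is.na(group)) paste0(" in group ", group))
    apos <- x$pos
  } else if (anchor == "donor") {
    apos <- .five_prime(x$start, x$end, x$strand)
  } else {
    apos <- .three_prime(x$start, x$end, x$strand)
  }
  offsets <- seq.int(span[1], span[2])
  dirsign <- ifelse(x$strand == "-", -1L, 1L)
  i3 <- .three_prime(x$start, x$end, x$strand)
  grid <- data.table(
    intron = rep(seq_len(nrow(x)), each = length(offsets)),
    offset = rep(offsets, nrow(x)))
  grid[, `:=`(chrom = x$chrom[intron],
              pos = apos[intron] + dirsign[intron] * offset)]
  grid <- grid[pos >= x$start[intron] & pos < x$end[intron]]
  if (anchor == "bp") grid <- grid[abs(pos - i3[intron]) >= mask_3ss]
  grid[, score := track[.(grid$chrom, grid$pos), score, on = c("chrom", "pos")]]
  if (identical(attr(track, "kind"), "depth")) {
    grid[is.na(score), score := 0]
  } else {
    grid <- grid[!is.na(score)]
  }
  prof <- grid[, .(mean = mean(score), n = .N), by = offset]
  prof <- prof[data.table(offset = offsets), on = "offset"]
  setattr(prof, "anchor", anchor)
  setattr(prof, "group", group)
  setattr(prof, "class", c("profile_matrix", class(prof)))
  prof[]
}

#' Per-offset log2 fold change between two profiles
#'
#' `log2((meanA + pc) / (meanB + pc))` at each shared offset, plus the
#' fraction of offsets within `exceed_window` (excluding offset 0) whose
#' logFC exceeds `threshold`.
#'
#' @param a,b `profile_matrix` objects on matching offsets.
#' @param pseudocount added to both means (default 1e-6).
#' @param threshold exceedance threshold on logFC (default 1).
#' @param exceed_window offsets considered for the exceedance fraction
#'   (default -50..50 excluding 0, intersected with available offsets).
#' @return data.table (offset, logfc) with attribute `fraction_exceeding`.
#' @export
profile_logfc <- function(a, b, pseudocount = 1e-6, threshold = 1,
                          exceed_window = setdiff(-50:50, 0)) {
  if (!identical(a$offset, b$offset)) stop("profiles have mismatched offsets")
  out <- data.table(offset = a$offset,
                    logfc = log2((a$mean + pseudocount) / (b$mean + pseudocount)))
  w <- out[offset %in% exceed_window & !is.na(logfc)]
  setattr(out, "fraction_exceeding",
          if (nrow(w)) mean(w$logfc > threshold) else NA_real_)
  out[]
}
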