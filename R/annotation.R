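# Intron universe construction and host-intron assignment.
#
# All coordinates in user-facing tables are 0-based half-open (BED
# convention); GTF input (1-based inclusive) is converted on read. GRanges
# objects used internally for interval arithmetic are 1-based closed.

# 0-based half-open table -> GRanges (1-based closed)
.gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand = strand)
}

#' Read gene models from a GTF file
#'
#' Extracts the exon table and per-gene biotypes needed to build the
#' non-exon-overlapping intron universe. Coordinates are converted to
#' 0-based half-open.
#'
#' @param path GTF file (GENCODE-style attributes: `gene_id`,
#'   `transcript_id`, `gene_type` or `gene_biotype`).
#' @return list with `exons` (data.table: chrom, start, end, strand, gene_id,
#'   transcript_id) and `genes` (data.table: gene_id, biotype, chrom, strand).
#' @export
read_gtf <- function(path) {
  g <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(g)
  bio_col <- intersect(c("gene_type", "gene_biotype"), names(mc))[1]
  if (is.na(bio_col)) stop("GTF lacks gene_type/gene_biotype attribute")
  ex <- g[mc$type == "exon"]
  exons <- data.table(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = S4Vectors::mcols(ex)$gene_id,
    transcript_id = S4Vectors::mcols(ex)$transcript_id
  )
  genes <- unique(data.table(
    gene_id = mc$gene_id,
    biotype = mc[[bio_col]],
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g))
  ))
  genes <- genes[!is.na(gene_id)][, .SD[1], by = gene_id]
  list(exons = exons[], genes = genes[])
}

.validate_transcripts <- function(exons) {
  ex <- as.data.table(exons)
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  if (!all(need %in% names(ex))) {
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  }
  setorder(ex, transcript_id, start, end)
  bad <- ex[, {
    over <- .N > 1L && any(head(end, -1L) > tail(start, -1L))
    mixed <- uniqueN(chrom) > 1L || uniqueN(strand) > 1L
    .(bad = over || mixed || any(end <= start))
  }, by = transcript_id][bad == TRUE, transcript_id]
  list(exons = ex[!transcript_id %in% bad], rejected = bad)
}

#' Build the unique non-exon-overlapping intron set
#'
#' Per gene, introns of all isoforms are union-merged when overlapping
#' (isoforms are disregarded by collapsing), and positions overlapped by any
#' exon of the masking scope are subtracted, leaving `kept_blocks`. Intron
#' ids are deterministic: `<gene_id>_i<ordinal>` with the ordinal counted
#' along the direction of transcription.
#'
#' @param exons exon table (0-based half-open: chrom, start, end, strand,
#'   gene_id, transcript_id). Transcripts with overlapping or inconsistent
#'   exons are rejected and reported via `attr(, "rejected_transcripts")`.
#' @param mask_scope `"gene"` (default) masks with exons of the intron's own
#'   gene only (alternative isoforms); `"strand"` masks with all exons on the
#'   same chromosome and strand.
#' @param min_len,max_len span-length bounds for the `is_host_candidate`
#'   flag (introns outside the bounds are kept, flagged FALSE).
#' @return data.table of intron records: intron_id, chrom, start, end,
#'   strand, gene_id, length, kept_starts/kept_ends (list columns, 0-based
#'   half-open), kept_length, n_blocks, is_host_candidate.
#' @export
build_unique_introns <- function(exons, mask_scope = c("gene", "strand"),
                                 min_len = 100L, max_len = 10000L) {
  mask_scope <- match.arg(mask_scope)
  v <- .validate_transcripts(exons)
  ex <- v$exons
  if (!nrow(ex)) {
    out <- data.table(intron_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      gene_id = character(), length = integer(),
                      kept_starts = list(), kept_ends = list(),
                      kept_length = integer(), n_blocks = integer(),
                      is_host_candidate = logical())
    setattr(out, "rejected_transcripts", v$rejected)
    return(out)
  }
  # per-transcript introns: gaps between consecutive exons
  setorder(ex, transcript_id, start)
  intr <- ex[, if (.N >= 2L) .(istart = head(end, -1L), iend = tail(start, -1L),
                               chrom = chrom[1], strand = strand[1],
                               gene_id = gene_id[1]),
             by = transcript_id]
  intr <- intr[iend > istart]  # zero-length gaps (adjacent exons) yield no intron
  if (!nrow(intr)) {
    out <- build_unique_introns(ex[0], mask_scope, min_len, max_len)
    setattr(out, "rejected_transcripts", v$rejected)
    return(out)
  }
  # collapse across isoforms, vectorized across genes via gene_id seqspace
  gi <- GenomicRanges::reduce(.gr0(intr$gene_id, intr$istart, intr$iend))
  spans <- data.table(gene_id = as.character(GenomicRanges::seqnames(gi)),
                      start = GenomicRanges::start(gi) - 1L,
                      end = GenomicRanges::end(gi))
  gmeta <- unique(intr[, .(gene_id, chrom, strand)])
  spans <- gmeta[spans, on = "gene_id"]
  # exon mask in the same seqspace
  if (mask_scope == "gene") {
    mask <- .gr0(ex$gene_id, ex$start, ex$end)
    span_gr <- .gr0(spans$gene_id, spans$start, spans$end)
  } else {
    key <- function(ch, st) paste0(ch, "|", st)
    mask <- .gr0(key(ex$chrom, ex$strand), ex$start, ex$end)
    span_gr <- .gr0(key(spans$chrom, spans$strand), spans$start, spans$end)
  }
  GenomeInfoDb::seqlevels(mask) <- union(GenomeInfoDb::seqlevels(mask),
                                         GenomeInfoDb::seqlevels(span_gr))
  GenomeInfoDb::seqlevels(span_gr) <- GenomeInfoDb::seqlevels(mask)
  kept <- GenomicRanges::setdiff(span_gr, GenomicRanges::reduce(mask))
  hits <- GenomicRanges::findOverlaps(kept, span_gr)
  kb <- data.table(span_idx = S4Vectors::subjectHits(hits),
                   bstart = GenomicRanges::start(kept)[S4Vectors::queryHits(hits)] - 1L,
                   bend = GenomicRanges::end(kept)[S4Vectors::queryHits(hits)])
  kb[, `:=`(bstart = pmax(bstart, spans$start[span_idx]),
            bend = pmin(bend, spans$end[span_idx]))]
  kb <- kb[bend > bstart]
  setorder(kb, span_idx, bstart)
  blocks <- kb[, .(kept_starts = list(bstart), kept_ends = list(bend),
                   kept_length = sum(bend - bstart), n_blocks = .N),
               by = span_idx]
  spans[, span_idx := .I]
  out <- blocks[spans, on = "span_idx"]
  out[is.na(kept_length), `:=`(kept_length = 0L, n_blocks = 0L)]
  empty <- which(vapply(out$kept_starts, is.null, logical(1)))
  for (i in empty) {
    out$kept_starts[[i]] <- integer(0)
    out$kept_ends[[i]] <- integer(0)
  }
  # deterministic ids: ordinal along the direction of transcription
  setorder(out, gene_id, start)
  out[, ord := if (strand[1] == "-") rev(seq_len(.N)) else seq_len(.N), by = gene_id]
  out[, intron_id := paste0(gene_id, "_i", ord)]
  out[, length := end - start]
  out[, is_host_candidate := length >= min_len & length <= max_len]
  out <- out[, .(intron_id, chrom, start, end, strand, gene_id, length,
                 kept_starts, kept_ends, kept_length, n_blocks,
                 is_host_candidate)]
  setorder(out, chrom, start, end, intron_id)
  setattr(out, "rejected_transcripts", v$rejected)
  out[]
}

# 5' splice-site genomic position of an interval (start on +, end-1 on -)
.five_prime <- function(start, end, strand) {
  ifelse(strand == "-", end - 1L, start)
}

# 3' splice-site genomic position (end-1 on +, start on -)
.three_prime <- function(start, end, strand) {
  ifelse(strand == "-", start, end - 1L)
}

#' Assign the host intron of circular sisRNA intervals
#'
#' The host intron is the shortest intron fully containing the query on the
#' same chromosome and strand. Ties on span length are broken by smaller
#' start coordinate, then lexicographic intron id. A separate flag records
#' 5' concordance: whether the query 5' splice site lies within
#' `max_5p_offset` bases of the host intron's 5' splice site.
#'
#' @param queries data.frame with chrom, start, end, strand (0-based
#'   half-open).
#' @param introns intron table from [build_unique_introns()].
#' @param max_5p_offset maximum 5'SS distance (bp) for the high-confidence
#'   concordance flag.
#' @return data.table with one row per query: query_index, intron_id (NA if
#'   no containing intron), host_start, host_end, host_gene, concordant_5p.
#' @export
assign_host_intron <- function(queries, introns, max_5p_offset = 10L) {
  q <- as.data.table(queries)
  res <- data.table(query_index = seq_len(nrow(q)), intron_id = NA_character_,
                    host_start = NA_integer_, host_end = NA_integer_,
                    host_gene = NA_character_, concordant_5p = NA)
  if (!nrow(q) || !nrow(introns)) return(res[])
  qgr <- .gr0(q$chrom, q$start, q$end, q$strand)
  igr <- .gr0(introns$chrom, introns$start, introns$end, introns$strand)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(qgr, igr, type = "within"))
  if (!length(hits)) return(res[])
  h <- data.table(qi = S4Vectors::queryHits(hits), ii = S4Vectors::subjectHits(hits))
  h[, `:=`(ilen = introns$length[ii], istart = introns$start[ii],
           iid = introns$intron_id[ii])]
  setorder(h, qi, ilen, istart, iid)
  h <- h[, .SD[1], by = qi]
  q5 <- .five_prime(q$start, q$end, q$strand)[h$qi]
  i5 <- .five_prime(introns$start[h$ii], introns$end[h$ii], introns$strand[h$ii])
  res[h$qi, `:=`(intron_id = h$iid,
                 host_start = introns$start[h$ii],
                 host_end = introns$end[h$ii],
                 host_gene = introns$gene_id[h$ii],
                 concordant_5p = abs(q5 - i5) <= max_5p_offset)]
  res[]
}

#' Write an intron set as a BED12-like TSV
#'
#' kept_blocks are encoded as blockSizes/blockStarts (starts relative to the
#' span start, BED12 convention); `gene_id` and `is_host_candidate` ride
#' along as extra columns.
#'
#' @param introns intron table from [build_unique_introns()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intron_bed <- function(introns, path) {
  x <- as.data.table(introns)
  bed <- data.table(
    chrom = x$chrom, start = x$start, end = x$end, name = x$intron_id,
    score = 0L, strand = x$strand, thickStart = x$start, thickEnd = x$end,
    itemRgb = "0,0,0", blockCount = x$n_blocks,
    blockSizes = mapply(function(s, e) paste(e - s, collapse = ","),
                        x$kept_starts, x$kept_ends),
    blockStarts = mapply(function(s, st) paste(s - st, collapse = ","),
                         x$kept_starts, x$start),
    gene_id = x$gene_id, is_host_candidate = x$is_host_candidate
  )
  write_tsv_schema(bed, path)
}

#' Read an intron set written by [write_intron_bed()]
#'
#' @param path file path.
#' @return intron table in the [build_unique_introns()] layout.
#' @export
read_intron_bed <- function(path) {
  bed <- read_tsv_schema(path)
  split_int <- function(s) if (is.na(s) || s == "") integer(0) else
    as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
  ks <- mapply(function(bs, st) split_int(bs) + st,
               as.character(bed$blockStarts), bed$start, SIMPLIFY = FALSE)
  sz <- lapply(as.character(bed$blockSizes), split_int)
  ke <- mapply(`+`, ks, sz, SIMPLIFY = FALSE)
  out <- data.table(
    intron_id = bed$name, chrom = bed$chrom, start = bed$start, end = bed$end,
    strand = bed$strand, gene_id = bed$gene_id, length = bed$end - bed$start,
    kept_starts = ks, kept_ends = ke,
    kept_length = vapply(sz, sum, integer(1)),
    n_blocks = bed$blockCount, is_host_candidate = bed$is_host_candidate
  )
  out[]
}
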