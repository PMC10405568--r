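# Circular junction call parsing, filtering, collapsing and classification.
#
# A junction call records the 5' splice site (donor) and the 3'-most
# circularized base (acceptor: inferred branch point for stable lariats, or
# the 3' splice site for full-length intronic circles). On the minus strand
# the donor is the interval end - 1 and the acceptor the interval start.

#' Read a circular junction call table
#'
#' Two dialects are supported. `circexplorer2_bed`: BED-like columns chrom,
#' start, end, name, score (junction read count), strand. `generic_tsv`: a
#' schema-headed TSV with columns chrom, start, end, strand, read_count.
#' Rows with `end <= start` or negative coordinates are rejected; the number
#' of rejected rows is recorded in `attr(, "n_rejected")`.
#'
#' @param path input file.
#' @param dialect input dialect.
#' @param sample_id sample identifier attached to every call.
#' @param caller caller label attached to every call.
#' @return data.table of junction calls: sample_id, chrom, strand, donor_pos,
#'   acceptor_pos, read_count, caller.
#' @export
read_junction_table <- function(path, dialect = c("circexplorer2_bed", "generic_tsv"),
                                sample_id = "sample1", caller = "caller1") {
  dialect <- match.arg(dialect)
  empty <- data.table(sample_id = character(), chrom = character(),
                      strand = character(), donor_pos = integer(),
                      acceptor_pos = integer(), read_count = integer(),
                      caller = character())
  if (dialect == "circexplorer2_bed") {
    if (file.size(path) == 0) {
      setattr(empty, "n_rejected", 0L)
      return(empty[])
    }
    x <- fread(path, sep = "\t", header = FALSE)
    if (ncol(x) < 6) stop("BED junction file needs >= 6 columns: ", path)
    x <- x[, 1:6]
    setnames(x, c("chrom", "start", "end", "name", "read_count", "strand"))
  } else {
    x <- read_tsv_schema(path)
    need <- c("chrom", "start", "end", "strand", "read_count")
    if (!all(need %in% names(x))) {
      stop("generic junction TSV needs columns: ", paste(need, collapse = ", "))
    }
  }
  ok <- x$end > x$start & x$start >= 0 & x$strand %in% c("+", "-")
  n_rejected <- sum(!ok)
  x <- x[ok]
  calls <- data.table(
    sample_id = sample_id,
    chrom = as.character(x$chrom),
    strand = x$strand,
    donor_pos = .five_prime(x$start, x$end, x$strand),
    acceptor_pos = .three_prime(x$start, x$end, x$strand),
    read_count = as.integer(x$read_count),
    caller = caller
  )
  setattr(calls, "n_rejected", n_rejected)
  calls[]
}

.circle_length <- function(donor, acceptor) abs(acceptor - donor) + 1L

#' Filter circular junction calls
#'
#' Applies the inclusion rules for circular sisRNA calls: not on the
#' mitochondrial genome, host gene protein-coding, circle length within
#' `[min_len, max_len]`, and a host intron assignable (shortest containing
#' intron, see [assign_host_intron()]). Calls with zero reads are dropped as
#' evidence-free. The "expressed in at least two samples" rule is applied
#' later, at cluster level.
#'
#' @param calls junction call table ([read_junction_table()]; calls from
#'   several samples may be rbind-ed).
#' @param introns intron table ([build_unique_introns()]).
#' @param genes gene table with gene_id and biotype (from [read_gtf()]).
#' @param min_len,max_len circle length bounds (bp).
#' @param chrM_names chromosome names treated as mitochondrial.
#' @param max_5p_offset passed to [assign_host_intron()] for the
#'   high-confidence 5' concordance flag.
#' @return filtered calls with columns intron_id, host_gene, concordant_5p
#'   added; filter counts in `attr(, "filter_counts")` (named integer vector
#'   input = kept + removed_chrM + removed_length + removed_no_host +
#'   removed_biotype + removed_zero_reads).
#' @export
filter_junctions <- function(calls, introns, genes, min_len = 30L,
                             max_len = 10000L, chrM_names = c("chrM", "MT"),
                             max_5p_offset = 10L) {
  x <- as.data.table(calls)
  n_input <- nrow(x)
  zero <- x$read_count <= 0L
  x <- x[!zero]
  is_m <- x$chrom %in% chrM_names
  x <- x[!is_m]
  len <- .circle_length(x$donor_pos, x$acceptor_pos)
  bad_len <- len < min_len | len > max_len
  x <- x[!bad_len]
  # host assignment on the full circle interval
  iv_start <- pmin(x$donor_pos, x$acceptor_pos)
  iv_end <- pmax(x$donor_pos, x$acceptor_pos) + 1L
  host <- assign_host_intron(
    data.frame(chrom = x$chrom, start = iv_start, end = iv_end, strand = x$strand),
    introns, max_5p_offset = max_5p_offset)
  x[, `:=`(intron_id = host$intron_id, host_gene = host$host_gene,
           concordant_5p = host$concordant_5p)]
  no_host <- is.na(x$intron_id)
  x <- x[!no_host]
  gb <- setNames(genes$biotype, genes$gene_id)
  noncoding <- is.na(gb[x$host_gene]) | gb[x$host_gene] != "protein_coding"
  x <- x[!noncoding]
  counts <- c(input = n_input, removed_zero_reads = sum(zero),
              removed_chrM = sum(is_m), removed_length = sum(bad_len),
              removed_no_host = sum(no_host), removed_biotype = sum(noncoding),
              kept = nrow(x))
  setattr(x, "filter_counts", counts)
  x[]
}

#' Collapse same-5'SS junctions into sisRNA clusters
#'
#' Junction calls annotated to the same host intron and the same 5' splice
#' site but with differing 3' ends (branch point uncertainty from reverse
#' transcriptase errors) are collapsed into one cluster, represented by the
#' member end with the highest number of supporting junction-spanning reads.
#' Representative ties are broken by the member seen in more samples, then
#' by smaller distance to the annotated 3' splice site, then by the leftmost
#' end.
#'
#' @param calls filtered calls from [filter_junctions()] (multiple samples).
#' @param introns intron table (for 3'SS positions used in tie-breaks).
#' @param samples optional character vector fixing the sample (column) order
#'   of the count matrix; defaults to sorted unique sample ids.
#' @return list with `clusters` (data.table: cluster_id, intron_id, chrom,
#'   strand, donor_pos, representative_end, circle_length, total_reads,
#'   n_members, n_samples_expressed, high_confidence, member_ends /
#'   member_reads / member_samples list columns) and `counts` (integer
#'   matrix clusters x samples of junction reads summed over members).
#' @export
collapse_junctions <- function(calls, introns, samples = NULL) {
  x <- as.data.table(calls)
  if (is.null(samples)) samples <- sort(unique(x$sample_id))
  i3 <- setNames(.three_prime(introns$start, introns$end, introns$strand),
                 introns$intron_id)
  x[, cluster_id := paste0(intron_id, ":", donor_pos)]
  # member summaries (per distinct acceptor end within a cluster)
  mem <- x[, .(reads = sum(read_count), n_samples = uniqueN(sample_id)),
           by = .(cluster_id, intron_id, chrom, strand, donor_pos, acceptor_pos)]
  mem[, d3 := abs(acceptor_pos - i3[intron_id])]
  setorder(mem, cluster_id, -reads, -n_samples, d3, acceptor_pos)
  rep_mem <- mem[, .SD[1], by = cluster_id]
  agg <- mem[, .(total_reads = sum(reads), n_members = .N,
                 member_ends = list(acceptor_pos), member_reads = list(reads),
                 member_samples = list(n_samples)), by = cluster_id]
  clusters <- rep_mem[, .(cluster_id, intron_id, chrom, strand, donor_pos,
                          representative_end = acceptor_pos)]
  clusters <- agg[clusters, on = "cluster_id"]
  clusters[, circle_length := .circle_length(donor_pos, representative_end)]
  # per-sample counts summed over members
  cs <- x[, .(n = sum(read_count)), by = .(cluster_id, sample_id)]
  # copy the id vector: setorder() below sorts columns in place and must not
  # reach the matrix dimnames
  counts <- matrix(0L, nrow = nrow(clusters), ncol = length(samples),
                   dimnames = list(copy(clusters$cluster_id), samples))
  counts[cbind(match(cs$cluster_id, clusters$cluster_id),
               match(cs$sample_id, samples))] <- cs$n
  clusters[, n_samples_expressed := rowSums(counts[cluster_id, , drop = FALSE] > 0L)]
  if ("concordant_5p" %in% names(x)) {
    hc <- x[, .(hc = any(concordant_5p)), by = cluster_id]
    clusters[hc, high_confidence := i.hc, on = "cluster_id"]
  } else {
    clusters[, high_confidence := NA]
  }
  setorder(clusters, chrom, donor_pos, cluster_id)
  counts <- counts[clusters$cluster_id, , drop = FALSE]
  setcolorder(clusters, c("cluster_id", "intron_id", "chrom", "strand",
                          "donor_pos", "representative_end", "circle_length",
                          "total_reads", "n_members", "n_samples_expressed",
                          "high_confidence"))
  list(clusters = clusters[], counts = counts)
}

#' Classify sisRNA clusters as stable lariats or intronic circles
#'
#' A cluster is a full-length intronic circle when its representative 3' end
#' lies within `tol_3ss` bases of the host intron's 3' splice site (the last
#' intron base on the plus strand, the span start on the minus strand);
#' otherwise it is a stable lariat whose 3' end marks an internal branch
#' point. Clusters whose representative end falls outside the host intron
#' span are flagged and excluded (`cls = NA`), with the count reported in
#' `attr(, "n_excluded")`.
#'
#' @param clusters cluster table from [collapse_junctions()].
#' @param introns intron table.
#' @param tol_3ss tolerance (bp) on the distance to the 3'SS; default 0.
#' @return the cluster table with a `cls` column
#'   (`"stable_lariat"` / `"intronic_circle"` / NA).
#' @export
classify_clusters <- function(clusters, introns, tol_3ss = 0L) {
  x <- copy(as.data.table(clusters))
  idx <- match(x$intron_id, introns$intron_id)
  if (anyNA(idx)) stop("clusters reference unknown introns")
  i3 <- .three_prime(introns$start, introns$end, introns$strand)[idx]
  inside <- x$representative_end >= introns$start[idx] &
    x$representative_end < introns$end[idx]
  x[, cls := fifelse(abs(representative_end - i3) <= tol_3ss,
                     "intronic_circle", "stable_lariat")]
  x[!inside, cls := NA_character_]
  setattr(x, "n_excluded", sum(!inside))
  x[]
}

#' Reads-per-million normalization
#'
#' @param counts features x samples count matrix.
#' @param library_sizes named vector of total mapped reads per sample
#'   (sequencing depth, not junction-read totals).
#' @return RPM matrix: `count * 1e6 / library_size`.
#' @export
rpm_normalize <- function(counts, library_sizes) {
  missing <- setdiff(colnames(counts), names(library_sizes))
  if (length(missing)) stop("missing library size for sample(s): ",
                            paste(missing, collapse = ", "))
  ls <- library_sizes[colnames(counts)]
  if (any(ls <= 0)) stop("library sizes must be positive")
  sweep(counts, 2, ls, "/") * 1e6
}

#' Cross-caller cluster overlap
#'
#' For each cluster of each caller, flags whether another caller reports a
#' cluster with the same chrom/strand whose donor and representative end
#' both match within `tol` bases, and summarizes the fraction of clusters
#' supported by at least two callers.
#'
#' @param cluster_sets named list (>= 2 callers) of cluster tables, each
#'   with chrom, strand, donor_pos, representative_end.
#' @param tol coordinate tolerance (bp).
#' @return list with `flags` (data.table: caller, cluster row, one logical
#'   column per other caller, supported) and `fraction_supported` (fraction
#'   of all clusters supported by >= 2 callers, i.e. by at least one other).
#' @export
caller_overlap <- function(cluster_sets, tol = 0L) {
  if (length(cluster_sets) < 2) stop("need cluster sets from >= 2 callers")
  nms <- names(cluster_sets)
  match_any <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      any(b$chrom == a$chrom[i] & b$strand == a$strand[i] &
            abs(b$donor_pos - a$donor_pos[i]) <= tol &
            abs(b$representative_end - a$representative_end[i]) <= tol)
    }, logical(1))
  }
  flags <- rbindlist(lapply(nms, function(ca) {
    a <- as.data.table(cluster_sets[[ca]])
    others <- setdiff(nms, ca)
    cols <- lapply(others, function(cb)
      match_any(a, as.data.table(cluster_sets[[cb]])))
    names(cols) <- paste0("in_", others)
    do.call(data.table, c(list(caller = rep(ca, nrow(a)), row = seq_len(nrow(a))),
                          cols, list(supported = Reduce(`|`, cols))))
  }), fill = TRUE)
  list(flags = flags[],
       fraction_supported = mean(flags$supported))
}
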