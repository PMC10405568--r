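# End-to-end pipeline driver tying the modules together.

#' Pipeline run configuration
#'
#' Bundles input paths and analysis thresholds with their defaults: circle
#' length 30-10000 bp, host-candidate intron length 100-10000 bp, clusters
#' expressed in >= 2 samples, exact 3'SS classification (tol_3ss = 0), DE
#' inclusion > 10 reads across >= 10 samples, q < 0.1, pseudocount 1e-6,
#' 10 bp splice-site trims and masks, 101-nt BP windows.
#'
#' @param gtf,junctions_dir,metadata required input paths (`junctions_dir`
#'   holds one `<sample_id>.bed` per sample, CIRCexplorer2-style dialect).
#' @param genome,bp_map,conservation optional inputs enabling the sequence
#'   and conservation stages.
#' @param outdir output directory.
#' @param ... threshold overrides (see the returned list).
#' @return a `run_config` list.
#' @export
run_config <- function(gtf, junctions_dir, metadata, genome = NULL,
                       bp_map = NULL, conservation = NULL,
                       outdir = tempfile("circsis_run"), ...) {
  cfg <- list(
    gtf = gtf, junctions_dir = junctions_dir, metadata = metadata,
    genome = genome, bp_map = bp_map, conservation = conservation,
    outdir = outdir,
    min_circle_len = 30L, max_circle_len = 10000L,
    min_intron_len = 100L, max_intron_len = 10000L,
    min_samples_expressed = 2L, tol_3ss = 0L, max_5p_offset = 10L,
    mask_scope = "gene",
    de_min_reads = 10L, de_min_samples = 10L, q_threshold = 0.1,
    pseudocount = 1e-6, trim = 10L, bp_window = c(-50L, 50L),
    motif = "AYAUUAUUAAU")
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown run_config field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Run the circular sisRNA pipeline
#'
#' Stages run in dependency order: annotation (intron universe), junction
#' reading/filtering/collapsing/classification, RPM normalization, then --
#' when their inputs are configured -- branch-point assignment and
#' concordance, motif scanning, and cohort statistics (risk-class DE and
#' survival, when metadata carries the labels). Outputs and a
#' machine-readable manifest (stage, parameters, record counts per filter)
#' are written under `config$outdir`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the main result objects (`introns`,
#'   `clusters`, `counts`, `rpm`, `de`, `survival`, `bp`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  for (f in c("gtf", "junctions_dir", "metadata")) {
    if (is.null(cfg[[f]]) || !file.exists(cfg[[f]])) {
      stop("missing required input '", f, "': ", cfg[[f]])
    }
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema = SCHEMA_VERSION,
                   parameters = cfg[!vapply(cfg, is.null, logical(1))])

  # annotation
  ann <- read_gtf(cfg$gtf)
  introns <- build_unique_introns(ann$exons, mask_scope = cfg$mask_scope,
                                  min_len = cfg$min_intron_len,
                                  max_len = cfg$max_intron_len)
  write_intron_bed(introns, file.path(cfg$outdir, "introns.bed"))
  manifest$annotation <- list(n_genes = nrow(ann$genes), n_introns = nrow(introns),
                              n_host_candidates = sum(introns$is_host_candidate),
                              rejected_transcripts =
                                length(attr(introns, "rejected_transcripts")))

  # junctions
  md <- read_metadata(cfg$metadata)
  files <- list.files(cfg$junctions_dir, pattern = "\\.bed$", full.names = TRUE)
  if (!length(files)) stop("no .bed junction tables under ", cfg$junctions_dir)
  calls <- rbindlist(lapply(files, function(f)
    read_junction_table(f, "circexplorer2_bed",
                        sample_id = sub("\\.bed$", "", basename(f)))))
  cand <- introns[introns$is_host_candidate == TRUE]
  filt <- filter_junctions(calls, cand, ann$genes,
                           min_len = cfg$min_circle_len,
                           max_len = cfg$max_circle_len,
                           max_5p_offset = cfg$max_5p_offset)
  manifest$filters <- as.list(attr(filt, "filter_counts"))
  coll <- collapse_junctions(filt, cand, samples = md$sample_id)
  clusters <- classify_clusters(coll$clusters, cand, tol_3ss = cfg$tol_3ss)
  manifest$clusters <- list(
    n_clusters = nrow(clusters),
    n_excluded_outside = attr(clusters, "n_excluded"),
    n_expressed_ge2 = sum(clusters$n_samples_expressed >= cfg$min_samples_expressed))
  clusters <- clusters[clusters$n_samples_expressed >= cfg$min_samples_expressed &
                         !is.na(clusters$cls)]
  counts <- coll$counts[clusters$cluster_id, , drop = FALSE]
  rpm <- rpm_normalize(counts, setNames(md$library_size, md$sample_id))
  write_tsv_schema(clusters, file.path(cfg$outdir, "clusters.tsv"),
                   list_cols = c("member_ends", "member_reads", "member_samples"))
  write_matrix_tsv(counts, file.path(cfg$outdir, "cluster_counts.tsv"))
  write_matrix_tsv(rpm, file.path(cfg$outdir, "cluster_rpm.tsv"))
  manifest$classes <- as.list(table(clusters$cls))

  res <- list(introns = introns, clusters = clusters, counts = counts, rpm = rpm)

  # branch points
  if (!is.null(cfg$bp_map)) {
    bp_map <- read_tsv_schema(cfg$bp_map)
    genome <- if (!is.null(cfg$genome)) Biostrings::readDNAStringSet(cfg$genome)
    if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
    bp <- assign_bp(introns, bp_map, genome = genome)
    caller_bp <- clusters[clusters$cls == "stable_lariat",
                          c("intron_id", "representative_end")]
    names(caller_bp)[2] <- "pos"
    conc <- bp_concordance(caller_bp, bp)
    res$bp <- bp
    res$bp_concordance <- conc
    manifest$branchpoint <- list(n_map_assigned = nrow(bp),
                                 n_caller = nrow(caller_bp),
                                 concordance_median = conc$median,
                                 concordance_mean = conc$mean)
    write_tsv_schema(bp, file.path(cfg$outdir, "bp_assigned.tsv"))
  }

  # cohort statistics
  if ("risk_class" %in% names(md) && sum(!is.na(md$risk_class)) > 0) {
    cmd <- md[!is.na(md$risk_class)]
    de <- differential_expression(rpm[, cmd$sample_id, drop = FALSE],
                                  counts[, cmd$sample_id, drop = FALSE], cmd,
                                  min_reads = cfg$de_min_reads,
                                  min_samples = cfg$de_min_samples,
                                  q_threshold = cfg$q_threshold)
    write_tsv_schema(de, file.path(cfg$outdir, "de_results.tsv"))
    res$de <- de
    manifest$de <- list(n_tested = length(unique(de$cluster_id)),
                        n_pass = sum(de$pass))
    if (all(c("surv_time", "surv_event") %in% names(md)) &&
        any(!is.na(cmd$surv_time))) {
      total <- colSums(rpm[, cmd$sample_id, drop = FALSE])
      km <- km_logrank(total, cmd)
      write_tsv_schema(km$curves, file.path(cfg$outdir, "survival_curves.tsv"))
      res$survival <- km
      manifest$survival <- list(cutoff = km$cutoff, chisq = km$chisq, p = km$p)
    }
  }

  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
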