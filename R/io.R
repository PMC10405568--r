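#' @import data.table
#' @importFrom stats median p.adjust pchisq quantile rbinom rgeom rlnorm rnbinom
#'   rnorm rpois runif rexp setNames cor fisher.test wilcox.test complete.cases
#' @importFrom utils head tail
NULL

SCHEMA_VERSION <- "circsis/1"

#' Write a table with a schema header line
#'
#' All tabular outputs carry a first line of the form
#' `#circsis/1 col1 col2 ...` so that files are self-describing and can be
#' round-tripped losslessly by [read_tsv_schema()]. List columns are
#' JSON-encoded.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param list_cols character vector of column names to JSON-encode.
#' @return `path`, invisibly.
#' @export
write_tsv_schema <- function(x, path, list_cols = NULL) {
  x <- as.data.table(copy(as.data.frame(x)))
  for (cc in intersect(names(x), list_cols)) {
    x[[cc]] <- vapply(x[[cc]], function(v) as.character(jsonlite::toJSON(v, digits = NA)),
                      character(1))
  }
  hdr <- paste0("#", SCHEMA_VERSION, "\t", paste(names(x), collapse = "\t"))
  writeLines(hdr, path)
  if (nrow(x)) {
    fwrite(x, path, sep = "\t", col.names = FALSE, append = TRUE, quote = FALSE)
  }
  invisible(path)
}

#' Read a table written by [write_tsv_schema()]
#'
#' @param path file path.
#' @param list_cols columns to decode from JSON back into list columns.
#' @return data.table.
#' @export
read_tsv_schema <- function(path, list_cols = NULL) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#")) stop("missing schema header line in ", path)
  fields <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1]]
  if (fields[1] != SCHEMA_VERSION) {
    warning("schema version ", fields[1], " read by ", SCHEMA_VERSION)
  }
  cols <- fields[-1]
  x <- fread(path, sep = "\t", skip = 1L, header = FALSE,
             colClasses = list(character = which(cols %in% list_cols)))
  if (ncol(x) != length(cols)) stop("column count mismatch in ", path)
  setnames(x, cols)
  for (cc in intersect(cols, list_cols)) {
    x[[cc]] <- lapply(x[[cc]], function(s) unlist(jsonlite::fromJSON(s)))
  }
  x[]
}

#' Write a numeric matrix as a features x samples TSV
#'
#' @param m matrix with rownames (features) and colnames (samples).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  dt <- data.table(feature_id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  write_tsv_schema(dt, path)
}

#' Read a features x samples matrix TSV written by [write_matrix_tsv()]
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  dt <- read_tsv_schema(path)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt$feature_id
  m
}

#' Read sample metadata
#'
#' Expected columns: `sample_id`, `library_size`, and optionally `tissue`,
#' `cell_line`, `fraction`, `risk_class`, `surv_time`, `surv_event`.
#'
#' @param path metadata TSV path (schema-headed, see [write_tsv_schema()]).
#' @return data.table keyed by `sample_id`.
#' @export
read_metadata <- function(path) {
  md <- read_tsv_schema(path)
  if (!all(c("sample_id", "library_size") %in% names(md))) {
    stop("metadata must contain sample_id and library_size columns")
  }
  if ("risk_class" %in% names(md)) md[, risk_class := as.character(risk_class)]
  if (all(c("surv_time", "surv_event") %in% names(md))) {
    bad <- md[xor(is.na(surv_time), is.na(surv_event))]
    if (nrow(bad)) stop("survival time/event must be jointly present or missing: ",
                        paste(bad$sample_id, collapse = ", "))
  }
  setkey(md, sample_id)
  md[]
}
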