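#' Construct a taxon-by-sample count table
#'
#' The basic data container: a non-negative integer matrix with taxa as rows
#' and timestamped samples as columns. Column sums are the per-sample
#' sequencing depth.
#'
#' @param counts non-negative integer matrix, taxa in rows, samples in columns.
#' @param taxon_ids unique row labels; defaults to `rownames(counts)`.
#' @param sample_ids unique column labels; defaults to `colnames(counts)`.
#' @param times optional per-sample sampling time in hours.
#' @return an object of class `count_table` with elements `counts`,
#'   `taxon_ids`, `sample_ids` and `times`.
#' @export
count_table <- function(counts, taxon_ids = rownames(counts),
                        sample_ids = colnames(counts), times = NULL) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(counts)))
  taxon_ids <- as.character(taxon_ids)
  sample_ids <- as.character(sample_ids)
  if (length(taxon_ids) != nrow(counts))
    stop("taxon_ids length (", length(taxon_ids), ") does not match rows (",
         nrow(counts), ")")
  if (length(sample_ids) != ncol(counts))
    stop("sample_ids length (", length(sample_ids), ") does not match columns (",
         ncol(counts), ")")
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon id: ", taxon_ids[duplicated(taxon_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (any(!is.finite(counts)))
    stop("counts contain non-finite entries")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at taxon '", taxon_ids[bad[1L]], "', sample '",
         sample_ids[bad[2L]], "'")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop("non-integer count at taxon '", taxon_ids[bad[1L]], "', sample '",
         sample_ids[bad[2L]], "'")
  }
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != ncol(counts))
      stop("times length does not match number of samples")
    if (any(!is.finite(times))) stop("times contain non-finite values")
  }
  dimnames(counts) <- list(taxon_ids, sample_ids)
  structure(list(counts = counts, taxon_ids = taxon_ids,
                 sample_ids = sample_ids, times = times),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("depth range: ", paste(range(colSums(x$counts)), collapse = " - "), "\n",
      sep = "")
  if (!is.null(x$times))
    cat("times (h): ", paste(utils::head(x$times, 6), collapse = ", "),
        if (length(x$times) > 6) ", ...", "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

.delim <- function(csv) if (csv) "," else "\t"

#' Read a count table from TSV
#'
#' Expects a header row of sample IDs and a first column of taxon IDs; cells
#' must be non-negative integers. Round-trips losslessly with
#' [write_count_table()].
#'
#' @param path file path.
#' @param metadata optional path of a sample-metadata table (columns
#'   `sample_id`, `time_hours`) used to attach sampling times.
#' @param csv read comma-separated instead of tab-separated input.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, metadata = NULL, csv = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = .delim(csv),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  if (ncol(df) < 2L) stop("count table needs a taxon-id column plus >= 1 sample")
  taxon_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop("non-numeric cell in column '", colnames(df)[-1L][bad[1L, 2L]], "'")
  }
  times <- NULL
  if (!is.null(metadata)) {
    md <- read_sample_metadata(metadata, csv = csv)
    idx <- match(colnames(m), md$sample_id)
    if (anyNA(idx))
      stop("sample '", colnames(m)[is.na(idx)][1L], "' missing from metadata")
    times <- md$time_hours[idx]
  }
  count_table(m, taxon_ids = taxon_ids, sample_ids = colnames(m), times = times)
}

#' Write a count table to TSV
#'
#' @param table a [count_table()].
#' @param path output file path.
#' @param csv write comma-separated output.
#' @export
write_count_table <- function(table, path, csv = FALSE) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(taxon_id = table$taxon_ids,
                   table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = .delim(csv), quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read sample metadata
#'
#' Sampling times come either from a numeric `time_hours` column or from
#' ISO-8601 timestamps in a `timestamp` column, converted to hours since the
#' first sample.
#'
#' @param path metadata table with a `sample_id` column.
#' @param csv read comma-separated input.
#' @return data.frame with columns `sample_id`, `time_hours` (and any others
#'   present in the file).
#' @export
read_sample_metadata <- function(path, csv = FALSE) {
  md <- utils::read.table(path, header = TRUE, sep = .delim(csv),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(md)) stop("metadata needs a 'sample_id' column")
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1L])
  if (!"time_hours" %in% colnames(md)) {
    if (!"timestamp" %in% colnames(md))
      stop("metadata needs a 'time_hours' or 'timestamp' column")
    tt <- as.POSIXct(md$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    if (anyNA(tt)) stop("unparseable timestamp: ", md$timestamp[is.na(tt)][1L])
    md$time_hours <- as.numeric(difftime(tt, min(tt), units = "hours"))
  }
  md$time_hours <- as.numeric(md$time_hours)
  if (any(!is.finite(md$time_hours))) stop("non-finite time_hours in metadata")
  md
}

#' Write a labeled numeric matrix to TSV at full precision
#'
#' @param matrix numeric matrix with (optional) dimnames; entries must be
#'   finite.
#' @param path output path.
#' @param csv write comma-separated output.
#' @export
write_matrix <- function(matrix, path, csv = FALSE) {
  m <- as.matrix(matrix)
  if (any(!is.finite(m))) stop("matrix contains non-finite entries")
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("col", seq_len(ncol(m)))
  df <- data.frame(id = rownames(m),
                   apply(m, 2, function(x) format(x, digits = 17,
                                                  scientific = TRUE,
                                                  trim = TRUE)),
                   check.names = FALSE)
  colnames(df) <- c("id", colnames(m))
  utils::write.table(df, path, sep = .delim(csv), quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a labeled numeric matrix written by [write_matrix()]
#'
#' @param path file path.
#' @param csv read comma-separated input.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path, csv = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = .delim(csv),
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  m
}
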