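#' Read a delimited expression matrix
#'
#' Expects UTF-8 delimited text with gene identifiers in the first column
#' and sample identifiers in the header row. The delimiter is auto-detected
#' between tab and comma (tab wins when both occur) unless given.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` (default) auto-detects.
#' @param log2_transform apply `log2(x + 1)` to the values on load.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_matrix <- function(path, sep = NULL, log2_transform = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("expression matrix needs a gene-id column plus at least one sample",
         call. = FALSE)
  }
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- as.character(df[[1L]])
  if (log2_transform) {
    if (any(x < 0, na.rm = TRUE)) {
      stop("log2(x + 1) requires non-negative values", call. = FALSE)
    }
    x <- log2(x + 1)
  }
  validate_expression_matrix(x, what = paste0("matrix read from ", path))
  x
}

#' Write an expression matrix as delimited text
#'
#' Values are written with 15 significant digits so a write-then-read
#' round trip reproduces them to at least 12 significant digits.
#'
#' @param x numeric matrix with gene row names and sample column names.
#' @param path output file path.
#' @param sep delimiter (default tab).
#' @export
write_expression_matrix <- function(x, path, sep = "\t") {
  validate_expression_matrix(x)
  df <- data.frame(gene_id = rownames(x),
                   apply(x, 2L, function(col) sprintf("%.15g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(x))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Tab- or comma-delimited with required columns `sample_id`, `subject_id`,
#' `time` and `group`; `group` must be one of `baseline`, `case`, `normal`.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` auto-detects as in [read_expression_matrix()].
#' @return Data frame with the four columns as character.
#' @export
read_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  md <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  validate_metadata(md)
}

#' Validate a sample-metadata table
#'
#' @param md data frame with columns `sample_id`, `subject_id`, `time`,
#'   `group`.
#' @return The validated data frame (columns coerced to character),
#'   invisibly usable.
#' @export
validate_metadata <- function(md) {
  required <- c("sample_id", "subject_id", "time", "group")
  missing <- setdiff(required, names(md))
  if (length(missing)) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  md <- as.data.frame(lapply(md[required], as.character),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(md$group), c("baseline", "case", "normal"))
  if (length(bad)) {
    stop("metadata `group` must be baseline/case/normal; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  md
}

#' Collapse probe-level rows to gene level by averaging
#'
#' Each gene's expression is the mean of its probes' rows. Probes without a
#' gene mapping are dropped with a warning reporting the count.
#'
#' @param probe_matrix numeric matrix, probes in rows.
#' @param probe_map data frame with columns `probe_id` and `gene_id`.
#' @return Gene-level numeric matrix, rows sorted by gene id.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  validate_expression_matrix(probe_matrix, what = "probe matrix")
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    stop("`probe_map` needs columns probe_id and gene_id", call. = FALSE)
  }
  map <- probe_map[!is.na(probe_map$gene_id) & nzchar(probe_map$gene_id), ]
  idx <- match(rownames(probe_matrix), map$probe_id)
  mapped <- !is.na(idx)
  n_dropped <- sum(!mapped)
  if (!any(mapped)) {
    stop("no probe in the matrix has a gene mapping", call. = FALSE)
  }
  if (n_dropped > 0L) {
    warning("dropping ", n_dropped, " unmapped probe(s) of ",
            nrow(probe_matrix), call. = FALSE)
  }
  genes <- map$gene_id[idx[mapped]]
  sums <- rowsum(probe_matrix[mapped, , drop = FALSE], group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Average case samples within each stage
#'
#' Cross-sectional cohorts (e.g. tumor stages) are turned into a
#' single-sample-per-stage course: every gene's stage expression is its
#' mean over all case samples at that stage. Stage order is numeric when
#' the labels parse as numbers, else taken from `stage_order`, else from
#' first appearance in the metadata.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @param metadata metadata table (see [validate_metadata()]); only
#'   `group == "case"` samples are averaged — baseline/normal columns are
#'   left to the caller (typically [compute_baseline()] on the
#'   baseline-group columns).
#' @param stage_order optional character vector giving the stage ordering
#'   (needed for labels like `"IIA"`).
#' @return Numeric matrix with one column per stage, in stage order.
#' @export
average_by_stage <- function(x, metadata, stage_order = NULL) {
  md <- validate_metadata(metadata)
  validate_expression_matrix(x)
  md <- md[md$group == "case", , drop = FALSE]
  md <- md[md$sample_id %in% colnames(x), , drop = FALSE]
  if (nrow(md) == 0L) stop("no case samples to average", call. = FALSE)
  stages <- sort_time_labels(md$time, stage_order)
  out <- vapply(stages, function(st) {
    ids <- md$sample_id[md$time == st]
    if (length(ids) == 0L) stop("stage ", st, " has no samples", call. = FALSE)
    rowMeans(x[, ids, drop = FALSE])
  }, numeric(nrow(x)))
  dimnames(out) <- list(rownames(x), stages)
  out
}

#' Write a score series (or several) as TSV
#'
#' Columns: `subject`, `time`, `S`, `deltaS`.
#'
#' @param series an `spcr_score_series` or a list of them.
#' @param path output file path.
#' @export
write_score_series <- function(series, path) {
  if (inherits(series, "spcr_score_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    sid <- attr(s, "subject_id")
    data.frame(subject = if (is.null(sid)) NA_character_ else sid,
               time = s$time, S = s$score, deltaS = s$ranking_score,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated study to a directory
#'
#' Emits the standard delimited artifacts: `expression.tsv` (normal pool
#' and course columns side by side), `metadata.tsv`, and `truth.json`
#' (ground-truth transition index and DNB gene ids).
#'
#' @param study an `spcr_sim_study`.
#' @param dir output directory (created if absent).
#' @param subject_id subject identifier used in the metadata (default
#'   `"sim01"`).
#' @return The directory path, invisibly.
#' @export
write_sim_study <- function(study, dir, subject_id = "sim01") {
  stopifnot(inherits(study, "spcr_sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  course <- study$course
  case_ids <- paste0(subject_id, "_t", colnames(course))
  mat <- cbind(study$normal_matrix, course)
  colnames(mat) <- c(colnames(study$normal_matrix), case_ids)
  write_expression_matrix(mat, file.path(dir, "expression.tsv"))
  md <- data.frame(
    sample_id = colnames(mat),
    subject_id = c(rep(subject_id, ncol(study$normal_matrix)), rep(subject_id, ncol(course))),
    time = c(rep("baseline", ncol(study$normal_matrix)), colnames(course)),
    group = c(rep("baseline", ncol(study$normal_matrix)), rep("case", ncol(course))),
    stringsAsFactors = FALSE
  )
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(truth_transition_index = study$truth_transition_index,
         dnb_gene_ids = study$dnb_gene_ids,
         config = unclass(study$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a GEO series-matrix file (convenience)
#'
#' Minimal ingester for an (uncompressed) GEO `series_matrix.txt` file:
#' extracts the expression table between the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers, with
#' probe ids as row names and GSM accessions as column names. Provided as a
#' convenience for desk validation on downloaded files; nothing else in the
#' package depends on it.
#'
#' @param path path to an uncompressed series-matrix text file.
#' @return Numeric matrix, probes in rows, samples in columns.
#' @export
read_geo_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop("no series-matrix table found in ", path, call. = FALSE)
  }
  con <- textConnection(lines[(beg + 1L):(end - 1L)])
  on.exit(close(con))
  df <- read.delim(con, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- gsub('^"|"$', "", as.character(df[[1L]]))
  colnames(x) <- gsub('^"|"$', "", colnames(x))
  x
}
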