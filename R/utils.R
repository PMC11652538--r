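# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Validate a genes x samples expression matrix. Returns the matrix invisibly.
validate_expression_matrix <- function(x, min_genes = 2L, min_samples = 1L,
                                       what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix (genes in rows, samples in columns)",
         call. = FALSE)
  }
  if (nrow(x) < min_genes || ncol(x) < min_samples) {
    stop(what, " must have at least ", min_genes, " genes and ",
         min_samples, " sample(s); got ", nrow(x), " x ", ncol(x),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)) ||
      any(!nzchar(rownames(x)))) {
    stop(what, " must have unique, non-empty gene identifiers as row names",
         call. = FALSE)
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)) ||
      any(!nzchar(colnames(x)))) {
    stop(what, " must have unique, non-empty sample identifiers as column names",
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- rownames(x)[apply(!is.finite(x), 1L, any)]
    stop(what, " contains missing or non-finite values for gene(s): ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "",
         call. = FALSE)
  }
  invisible(x)
}

# Order time labels: numerically when all parse as numbers, otherwise by an
# explicit ordering vector; error on duplicates or (numeric) disorder.
check_time_labels <- function(labels, time_order = NULL) {
  if (anyDuplicated(labels)) {
    stop("duplicate time labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) {
    if (is.unsorted(num, strictly = TRUE)) {
      stop("numeric time labels must be strictly increasing; got: ",
           paste(labels, collapse = ", "), call. = FALSE)
    }
  } else if (!is.null(time_order)) {
    if (!all(labels %in% time_order)) {
      stop("time label(s) absent from `time_order`: ",
           paste(setdiff(labels, time_order), collapse = ", "), call. = FALSE)
    }
    pos <- match(labels, time_order)
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("time labels are not in the order given by `time_order`",
           call. = FALSE)
    }
  }
  invisible(labels)
}

# Sort a vector of time labels (numeric-aware, else by `time_order`,
# else by first appearance).
sort_time_labels <- function(labels, time_order = NULL) {
  u <- unique(labels)
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) return(u[order(num)])
  if (!is.null(time_order)) {
    missing <- setdiff(u, time_order)
    if (length(missing)) {
      stop("time label(s) absent from `time_order`: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(time_order[time_order %in% u])
  }
  u
}
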