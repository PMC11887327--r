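# Internal helpers shared across modules.

# Coerce a counts object (wide tibble with an id column, or numeric matrix with
# rownames) to a taxa x samples numeric matrix.
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) {
      stop("count matrix must have taxon rownames", call. = FALSE)
    }
    m <- counts
    storage.mode(m) <- "double"
    return(m)
  }
  if (!is.data.frame(counts)) {
    stop("`counts` must be a data frame or matrix", call. = FALSE)
  }
  if (ncol(counts) < 2L) stop("`counts` has no sample columns", call. = FALSE)
  m <- as.matrix(counts[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(counts[[1L]])
  m
}

matrix_to_counts <- function(m, id_col = "taxon_id") {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
}

# Return output in the same container type as the input.
restore_counts_type <- function(m, template, id_col = NULL) {
  if (is.matrix(template)) return(m)
  matrix_to_counts(m, id_col = if (is.null(id_col)) names(template)[1L] else id_col)
}

check_counts_values <- function(m) {
  if (anyNA(m)) stop("counts contain missing values", call. = FALSE)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  invisible(m)
}

round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
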