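#' Read the study input files
#'
#' Readers for the plain-text interchange formats: a counts TSV
#' (rows = taxa, first column `taxon_id`, remaining columns = sample ids), a
#' two-column taxonomy TSV (`taxon_id`, `genus`), a sample metadata TSV
#' (`sample_id`, `subject_id`, `visit`, phenotype, covariates), and a Newick
#' tree. `read_inputs()` reads all four and cross-validates them: every
#' count-table sample must appear in the metadata and every taxon must have a
#' tree leaf and a genus assignment. When the metadata lacks a `visit` column
#' but sample ids look like `subject_visit`, the visit index is recovered from
#' the sample id.
#'
#' @param path File path.
#' @return `read_count_table()`, `read_taxonomy()` and
#'   `read_sample_metadata()` return tibbles; `read_newick()` returns a
#'   validated `phylo`; `read_inputs()` returns a list with elements
#'   `counts`, `tree`, `taxonomy`, `metadata`.
#' @name io
NULL

#' @rdname io
#' @export
read_count_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1L] <- "taxon_id"
  if (anyDuplicated(x$taxon_id)) {
    stop("duplicate taxon ids in ", path, call. = FALSE)
  }
  x
}

#' @rdname io
#' @export
read_taxonomy <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(x) < 2L) stop("taxonomy map needs two columns", call. = FALSE)
  names(x)[1:2] <- c("taxon_id", "genus")
  x
}

#' @rdname io
#' @export
read_sample_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname io
#' @param resolve Non-binary node policy, see [parse_tree()].
#' @export
read_newick <- function(path, resolve = c("error", "multi2di")) {
  parse_tree(file = path, resolve = match.arg(resolve))
}

#' @rdname io
#' @param counts,tree,taxonomy,metadata File paths.
#' @param phenotype Phenotype column that must be present in the metadata.
#' @export
read_inputs <- function(counts, tree, taxonomy, metadata,
                        phenotype = "phenotype",
                        resolve = c("error", "multi2di")) {
  ct <- read_count_table(counts)
  tr <- read_newick(tree, resolve = match.arg(resolve))
  tx <- read_taxonomy(taxonomy)
  md <- read_sample_metadata(metadata)

  req <- c("sample_id", "subject_id", phenotype)
  miss <- setdiff(req, names(md))
  if (length(miss)) {
    stop("missing required metadata columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  if (!"visit" %in% names(md)) {
    if (all(grepl("[0-9]+$", md$sample_id))) {
      md$visit <- as.integer(sub("^.*?([0-9]+)$", "\\1", md$sample_id))
      message("metadata has no `visit` column; visit index recovered from ",
              "sample ids")
    } else {
      stop("metadata needs a `visit` column (or `subject_visit` sample ids)",
           call. = FALSE)
    }
  }
  samp <- setdiff(names(ct)[-1L], md$sample_id)
  if (length(samp)) {
    stop("count-table samples missing from metadata: ",
         paste(samp, collapse = ", "), call. = FALSE)
  }
  no_leaf <- setdiff(ct$taxon_id, tr$tip.label)
  if (length(no_leaf)) {
    stop("taxa absent from the tree: ", paste(no_leaf, collapse = ", "),
         call. = FALSE)
  }
  no_gen <- setdiff(ct$taxon_id, tx$taxon_id)
  if (length(no_gen)) {
    stop("taxa absent from the taxonomy map: ",
         paste(no_gen, collapse = ", "), call. = FALSE)
  }
  list(counts = ct, tree = tr, taxonomy = tx, metadata = md)
}

#' Write / read back a results table
#'
#' Results are written as TSV with full precision (15 significant digits);
#' list-columns of per-node p-values are serialised as comma-separated
#' strings.
#'
#' @param x An `mtmat_result` or plain tibble.
#' @param path Output file.
#' @return `write_results()` returns `x` invisibly; `read_results()` returns
#'   a tibble.
#' @export
write_results <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        paste(formatC(unname(v), digits = 15, format = "g"), collapse = ",")
      }, character(1))
    }
  }
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(x)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
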