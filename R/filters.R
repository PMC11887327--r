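#' Filter rare taxa by mean relative abundance
#'
#' Computes each taxon's proportion of the per-sample total, averages the
#' proportions across all samples (subject-visits pooled), and drops taxa whose
#' mean falls below `min_mean_prop`. The original per-sample library sizes are
#' attached to the result as attribute `"library_size"` so that the log-CPM
#' normalisation can keep using the pre-filter denominators (the default; see
#' [log_cpm()]).
#'
#' @param counts Wide counts table: a tibble whose first column is the taxon id
#'   and remaining columns are samples, or a taxa x samples matrix.
#' @param min_mean_prop Exclusion threshold on the mean proportion
#'   (default 0.001).
#' @return Filtered counts in the same container type as the input.
#' @examples
#' m <- matrix(c(10, 990, 0, 1000), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' filter_taxa(m, min_mean_prop = 0.001)
#' @export
filter_taxa <- function(counts, min_mean_prop = 0.001) {
  m <- check_counts_values(as_count_matrix(counts))
  lib <- attr(counts, "library_size") %||% colSums(m)
  samp_tot <- colSums(m)
  if (any(samp_tot == 0)) {
    stop("samples with zero total counts: ",
         paste(colnames(m)[samp_tot == 0], collapse = ", "), call. = FALSE)
  }
  mean_prop <- rowMeans(sweep(m, 2L, samp_tot, "/"))
  keep <- mean_prop >= min_mean_prop
  if (!any(keep)) stop("all taxa filtered out", call. = FALSE)
  out <- restore_counts_type(m[keep, , drop = FALSE], counts)
  attr(out, "library_size") <- lib
  out
}

#' Filter samples by read count
#'
#' Drops samples whose library size (total read count) is below `min_reads`.
#' A sample with exactly `min_reads` reads is kept; the exclusion rule is
#' "read count < min_reads". Subjects that lose every visit simply disappear
#' from the table.
#'
#' @inheritParams filter_taxa
#' @param min_reads Minimum library size (default 3000).
#' @return Filtered counts in the same container type as the input; warns when
#'   every sample is dropped.
#' @export
filter_samples <- function(counts, min_reads = 3000) {
  m <- check_counts_values(as_count_matrix(counts))
  lib <- attr(counts, "library_size") %||% colSums(m)
  keep <- lib >= min_reads
  if (!any(keep)) warning("all samples filtered out", call. = FALSE)
  out <- restore_counts_type(m[, keep, drop = FALSE], counts)
  attr(out, "library_size") <- lib[keep]
  out
}
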