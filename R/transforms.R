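#' Log counts-per-million normalisation
#'
#' Transforms counts to log2 counts-per-million with a per-sample pseudo-count,
#' the same normalisation used by edgeR's `cpm(log = TRUE)`:
#' \deqn{r_{ijm} = \log_2\!\left(\frac{c_{ijm} + c_{ij\cdot}/2}
#'   {\sum_m c_{ijm} + c_{ij\cdot}} \times 10^6 + 1\right)}
#' where \eqn{c_{ij\cdot}} is the pseudo-count of sample \eqn{(i,j)}. Under the
#' default `prior = "constant"` policy \eqn{c_{ij\cdot} = 1} for every sample
#' (i.e. prior count 0.5 in the numerator); `prior = "library_scaled"` uses
#' \eqn{c_{ij\cdot} = L_{ij}/\bar L}, scaling the pseudo-count with library
#' size as edgeR does. The `+ 1` inside the log keeps every value strictly
#' positive, which the downstream log-ratio covariates rely on.
#'
#' @inheritParams filter_taxa
#' @param prior Pseudo-count policy, `"constant"` (default) or
#'   `"library_scaled"`.
#' @param library_size Optional per-sample denominators \eqn{\sum_m c_{ijm}}.
#'   Defaults to the `"library_size"` attribute left by [filter_taxa()] (the
#'   pre-filter totals), else to the column sums of `counts`.
#' @return Normalised values in the same container type as the input.
#' @examples
#' m <- matrix(c(0, 1000), 2, 1, dimnames = list(c("t1", "t2"), "s1"))
#' log_cpm(m)
#' @export
log_cpm <- function(counts, prior = c("constant", "library_scaled"),
                    library_size = NULL) {
  prior <- match.arg(prior)
  m <- check_counts_values(as_count_matrix(counts))
  lib <- library_size %||% attr(counts, "library_size") %||% colSums(m)
  lib <- unname(lib)
  if (length(lib) != ncol(m)) {
    stop("`library_size` must have one entry per sample", call. = FALSE)
  }
  if (any(lib <= 0)) {
    stop("zero library size; filter samples before normalising", call. = FALSE)
  }
  cdot <- switch(prior, constant = rep(1, ncol(m)),
                 library_scaled = lib / mean(lib))
  r <- log2(sweep(sweep(m, 2L, cdot / 2, "+"), 2L, lib + cdot, "/") * 1e6 + 1)
  restore_counts_type(r, counts)
}

#' Per-node log-ratio covariate
#'
#' For a test node with left and right leaf sets \eqn{L_k}, \eqn{R_k}, the
#' covariate of sample \eqn{(i,j)} is the natural log of the ratio of pooled
#' log-CPM values, \eqn{x^{(k)}_{ij} = \log(C_{ij}/D_{ij})} with
#' \eqn{C_{ij} = \sum_{m \in L_k} r_{ijm}} and
#' \eqn{D_{ij} = \sum_{m \in R_k} r_{ijm}}. Swapping the two leaf sets negates
#' the covariate; the test statistic is invariant to the sign.
#'
#' @param r Log-CPM table from [log_cpm()] (tibble or matrix).
#' @param left,right Character vectors of taxon ids (the node's leaf sets).
#' @return Named numeric vector, one value per sample.
#' @export
node_covariate <- function(r, left, right) {
  m <- as_count_matrix(r)
  miss <- setdiff(c(left, right), rownames(m))
  if (length(miss)) {
    stop("taxa not in table: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!length(left) || !length(right)) {
    stop("both leaf sets must be non-empty", call. = FALSE)
  }
  C <- colSums(m[left, , drop = FALSE])
  D <- colSums(m[right, , drop = FALSE])
  if (any(C <= 0) || any(D <= 0)) {
    stop("non-positive pooled log-CPM; input is not a valid log-CPM table",
         call. = FALSE)
  }
  log(C / D)
}

#' Pooled genus-level log-ratio covariate
#'
#' The node-0 covariate tests all genus taxa jointly:
#' \eqn{x^{(0)}_{ij} = \log(E_{ij}/G_{ij})} with
#' \eqn{E_{ij} = \sum_{m \in \mathrm{genus}} r_{ijm}}. The reference
#' \eqn{G_{ij}} is, by `denominator`:
#' * `"other_taxa"` (default) — the pooled log-CPM of all taxa outside the
#'   genus;
#' * `"alr"` — the pooled log-CPM \eqn{E^{(t)}_{ij}} of a named reference
#'   genus (additive log-ratio);
#' * `"clr"` — the geometric mean of the genus-level sums over all genera
#'   (centered log-ratio).
#'
#' @inheritParams node_covariate
#' @param partition A `genus_partition` (see [enumerate_test_nodes()]).
#' @param denominator Reference mode; see Details.
#' @param reference Reference genus name, required for `"alr"` and distinct
#'   from the tested genus.
#' @param genus_sets Named list of taxon-id vectors, one per genus; required
#'   for `"alr"`/`"clr"`.
#' @return Named numeric vector, one value per sample.
#' @export
pooled_covariate <- function(r, partition,
                             denominator = c("other_taxa", "alr", "clr"),
                             reference = NULL, genus_sets = NULL) {
  denominator <- match.arg(denominator)
  m <- as_count_matrix(r)
  E <- colSums(m[partition$member_taxa, , drop = FALSE])
  G <- switch(denominator,
    other_taxa = {
      if (!length(partition$other_taxa)) {
        stop("no taxa outside the genus for the default denominator",
             call. = FALSE)
      }
      colSums(m[partition$other_taxa, , drop = FALSE])
    },
    alr = {
      if (is.null(reference) || is.null(genus_sets) ||
          !reference %in% names(genus_sets)) {
        stop("`reference` must name a genus in `genus_sets`", call. = FALSE)
      }
      if (identical(reference, partition$genus)) {
        stop("ALR reference must differ from the tested genus", call. = FALSE)
      }
      colSums(m[genus_sets[[reference]], , drop = FALSE])
    },
    clr = {
      if (is.null(genus_sets)) {
        stop("`genus_sets` is required for the CLR denominator", call. = FALSE)
      }
      if (length(genus_sets) < 2L) {
        warning("CLR with a single genus gives an identically zero covariate",
                call. = FALSE)
      }
      Es <- vapply(genus_sets,
                   function(tx) colSums(m[tx, , drop = FALSE]),
                   numeric(ncol(m)))
      if (is.null(dim(Es))) Es <- matrix(Es, nrow = 1L)
      exp(rowMeans(log(Es)))
    })
  if (any(E <= 0) || any(G <= 0)) {
    stop("non-positive pooled log-CPM; input is not a valid log-CPM table",
         call. = FALSE)
  }
  log(E / G)
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles \eqn{\Phi^{-1}((\mathrm{rank} - 0.5)/n)}
#' with offset 0.5, using average ranks so tied values map to the same
#' transformed value. Used for the `IM` variant of the test, which makes the
#' node statistics robust to heavy tails and zero-inflation at small n.
#'
#' @param x Numeric vector (all samples pooled), length >= 2.
#' @return Numeric vector of the same length.
#' @examples
#' inverse_normal_transform(c(2.1, 5.3, 0.7))
#' @export
inverse_normal_transform <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two values", call. = FALSE)
  if (anyNA(x)) stop("missing values in covariate", call. = FALSE)
  if (length(unique(x)) == 1L) {
    warning("all values identical; transform is identically zero",
            call. = FALSE)
  }
  qnorm((rank(x, ties.method = "average") - 0.5) / n)
}
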