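#' Combine per-node p-values by the minimum p-value
#'
#' The node statistics of a genus are asymptotically independent, so under the
#' global null the minimum of `M1` node p-values follows a Beta(1, M1)
#' distribution. The combined p-value is its upper-tail transform,
#' \eqn{1 - (1 - \min p)^{M_1}}, which is again Uniform(0,1) under the null.
#'
#' @param p Vector of per-node p-values in (0, 1].
#' @param m1 Beta parameter; defaults to `length(p)`. Passing the nominal
#'   node count while supplying only the valid p-values gives the
#'   conservative variant of the node-failure policy.
#' @return The combined p-value (scalar).
#' @examples
#' combine_min_p(c(0.01, 0.8, 0.9, 0.7, 0.6)) # 1 - 0.99^5
#' @export
combine_min_p <- function(p, m1 = length(p)) {
  if (!length(p)) stop("no p-values to combine", call. = FALSE)
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m1 < length(p)) stop("`m1` cannot be below the number of p-values",
                           call. = FALSE)
  -expm1(m1 * log1p(-min(p)))
}

# Build the full covariate matrix (pooled node 0 plus one column per test
# node) for a genus from a log-CPM table.
genus_covariates <- function(r, partition,
                             denominator = "other_taxa", reference = NULL,
                             genus_sets = NULL) {
  x0 <- pooled_covariate(r, partition, denominator = denominator,
                         reference = reference, genus_sets = genus_sets)
  tn <- partition$test_nodes
  xs <- lapply(seq_len(nrow(tn)), function(i) {
    node_covariate(r, tn$left[[i]], tn$right[[i]])
  })
  X <- do.call(cbind, c(list(x0), xs))
  colnames(X) <- paste0("x", c(0L, tn$k))
  X
}

#' Test one genus
#'
#' Builds the pooled covariate \eqn{x^{(0)}} and the per-node log-ratio
#' covariates of a genus, optionally applies the rank-based inverse normal
#' transform to each covariate (variant `"IM"`), runs the GEE score or Wald
#' test per node, and combines the node p-values by [combine_min_p()]. The
#' pooled node always participates in the minimum, so a single-taxon genus is
#' testable (`M1 = 1` and the combined p-value is the node-0 p-value).
#'
#' @param r Log-CPM table ([log_cpm()]), samples in the same order as
#'   `y`/`id`/`visit`.
#' @param partition A `genus_partition` (see [enumerate_test_nodes()]).
#' @param y,id,visit,Z,small_sample,control As in [gee_node_test()].
#' @param variant `"IM"` (inverse-normal transformed covariates, default) or
#'   `"M"` (raw covariates).
#' @param statistic `"score"` (default) or `"wald"`.
#' @param wc Working correlation structure.
#' @param denominator,reference,genus_sets Reference mode for the pooled
#'   covariate; see [pooled_covariate()].
#' @param node_failure When a node's GEE fit fails numerically: `"drop"`
#'   (default) removes it and uses the realized number of valid nodes as the
#'   beta parameter; `"keep_m1"` keeps the nominal `M1` (conservative).
#' @return One-row tibble: `genus`, `m1`, `n_nodes` (valid nodes tested),
#'   `node_p` (list-column of per-node p-values), `min_p`, `combined_p`,
#'   `beta_min` (Wald effect estimate at the most significant node; `NA` for
#'   the score statistic), plus the options used.
#' @export
test_genus <- function(r, partition, y, id, visit = NULL, Z = NULL,
                       variant = c("IM", "M"),
                       statistic = c("score", "wald"),
                       wc = c("identity", "cs", "ar1", "un"),
                       denominator = c("other_taxa", "alr", "clr"),
                       reference = NULL, genus_sets = NULL,
                       small_sample = TRUE,
                       node_failure = c("drop", "keep_m1"),
                       control = gee_control()) {
  variant <- match.arg(variant)
  statistic <- match.arg(statistic)
  wc <- match.arg(wc)
  denominator <- match.arg(denominator)
  node_failure <- match.arg(node_failure)

  X <- genus_covariates(r, partition, denominator, reference, genus_sets)
  if (variant == "IM") X <- apply(X, 2L, inverse_normal_transform)

  fits <- lapply(seq_len(ncol(X)), function(j) {
    tryCatch(
      gee_node_test(X[, j], y, id, visit = visit, Z = Z, wc = wc,
                    statistic = statistic, small_sample = small_sample,
                    control = control),
      error = function(e) e)
  })
  failed <- vapply(fits, inherits, TRUE, what = "error")
  if (all(failed)) {
    stop("all node tests failed for genus ", partition$genus, ": ",
         conditionMessage(fits[[1L]]), call. = FALSE)
  }
  if (any(failed)) {
    warning(sum(failed), " node test(s) failed for genus ", partition$genus,
            " and were dropped", call. = FALSE)
  }
  ok <- fits[!failed]
  pvals <- vapply(ok, function(f) {
    if (statistic == "score") f$p_score else f$p_wald
  }, numeric(1))
  names(pvals) <- colnames(X)[!failed]
  betas <- vapply(ok, function(f) f$beta_hat %||% NA_real_, numeric(1))

  m1_eff <- if (node_failure == "drop") length(pvals) else partition$M1
  imin <- which.min(pvals)
  tibble::tibble(
    genus = partition$genus,
    m1 = partition$M1,
    n_nodes = length(pvals),
    node_p = list(pvals),
    min_p = unname(pvals[imin]),
    min_node = names(pvals)[imin],
    combined_p = combine_min_p(pvals, m1 = m1_eff),
    beta_min = unname(betas[imin]),
    variant = variant, statistic = statistic, wc = wc,
    denominator = denominator)
}

#' Genus-level association study
#'
#' The full pipeline: cross-validate the inputs, apply the sample and taxon
#' filters, normalise to log-CPM, enumerate each genus' test nodes on the
#' phylogeny, run the per-node GEE tests, combine per genus, and adjust the
#' combined p-values across genera.
#'
#' @param counts Wide counts tibble (first column taxon ids) or taxa x samples
#'   matrix; column names are sample ids.
#' @param metadata Data frame with columns `sample_id`, `subject_id`, `visit`,
#'   and the phenotype column, plus any covariates.
#' @param tree Rooted binary `phylo` tree (see [parse_tree()]) whose tips
#'   cover the count-table taxa.
#' @param taxonomy Data frame with columns `taxon_id`, `genus`.
#' @param phenotype Name of the phenotype column (default `"phenotype"`).
#' @param covariates Character vector of covariate columns (default none; the
#'   model always includes an intercept).
#' @param min_mean_prop,min_reads Filter thresholds; see [filter_taxa()] and
#'   [filter_samples()]. Use `0` to disable.
#' @param monophyly Genus/tree disagreement policy; see
#'   [enumerate_test_nodes()].
#' @param prior Pseudo-count policy for [log_cpm()].
#' @param p_adjust Multiple-testing correction across genera (`"BH"` default,
#'   or `"bonferroni"`).
#' @inheritParams test_genus
#' @return A tibble of class `mtmat_result`, one row per genus, with the
#'   columns of [test_genus()] plus `fdr_p`. Options are stored in
#'   `attr(x, "options")`.
#' @export
run_study <- function(counts, metadata, tree, taxonomy,
                      phenotype = "phenotype", covariates = NULL,
                      variant = c("IM", "M"),
                      statistic = c("score", "wald"),
                      wc = c("identity", "cs", "ar1", "un"),
                      denominator = c("other_taxa", "alr", "clr"),
                      reference = NULL,
                      min_mean_prop = 0.001, min_reads = 3000,
                      monophyly = c("strict", "lenient"),
                      prior = c("constant", "library_scaled"),
                      small_sample = TRUE, p_adjust = "BH",
                      node_failure = c("drop", "keep_m1"),
                      control = gee_control()) {
  variant <- match.arg(variant)
  statistic <- match.arg(statistic)
  wc <- match.arg(wc)
  denominator <- match.arg(denominator)
  monophyly <- match.arg(monophyly)
  prior <- match.arg(prior)
  node_failure <- match.arg(node_failure)

  m <- check_counts_values(as_count_matrix(counts))
  req <- c("sample_id", "subject_id", "visit", phenotype, covariates)
  miss <- setdiff(req, names(metadata))
  if (length(miss)) {
    stop("missing metadata columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  unmatched <- setdiff(colnames(m), metadata$sample_id)
  if (length(unmatched)) {
    stop("count-table samples missing from metadata: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  no_tree <- setdiff(rownames(m), tree$tip.label)
  if (length(no_tree)) {
    stop("taxa absent from the tree: ", paste(no_tree, collapse = ", "),
         call. = FALSE)
  }
  no_genus <- setdiff(rownames(m), taxonomy$taxon_id)
  if (length(no_genus)) {
    stop("taxa absent from the taxonomy map: ",
         paste(no_genus, collapse = ", "), call. = FALSE)
  }

  # filters: sample read-count filter, then rare-taxon filter; the CPM
  # denominators keep the pre-taxon-filter library sizes
  if (min_reads > 0) m2 <- as_count_matrix(filter_samples(m, min_reads))
  else m2 <- m
  lib0 <- colSums(m2)
  if (min_mean_prop > 0) {
    m2 <- as_count_matrix(filter_taxa(m2, min_mean_prop))
  }
  if (ncol(m2) == 0L) stop("no samples left after filtering", call. = FALSE)

  meta <- metadata[match(colnames(m2), metadata$sample_id), , drop = FALSE]
  ord <- order(match(meta$subject_id, unique(meta$subject_id)), meta$visit)
  meta <- meta[ord, , drop = FALSE]
  m2 <- m2[, meta$sample_id, drop = FALSE]
  lib0 <- lib0[meta$sample_id]

  r <- log_cpm(m2, prior = prior, library_size = lib0)
  taxonomy <- taxonomy[taxonomy$taxon_id %in% rownames(m2), , drop = FALSE]
  tree <- prune_tree_to(tree, rownames(m2))
  parts <- genus_partitions(tree, taxonomy, monophyly = monophyly)
  genus_sets <- lapply(parts, function(p) p$member_taxa)

  y <- as.numeric(meta[[phenotype]])
  Z <- cbind(`(Intercept)` = rep(1, nrow(meta)))
  if (length(covariates)) Z <- cbind(Z, as.matrix(meta[covariates]))

  res <- purrr::map_dfr(parts, function(pt) {
    test_genus(r, pt, y = y, id = meta$subject_id, visit = meta$visit,
               Z = Z, variant = variant, statistic = statistic, wc = wc,
               denominator = denominator, reference = reference,
               genus_sets = genus_sets, small_sample = small_sample,
               node_failure = node_failure, control = control)
  })
  res$fdr_p <- p.adjust(res$combined_p, method = p_adjust)
  res <- res[order(res$combined_p), , drop = FALSE]

  structure(res,
            class = c("mtmat_result", class(res)),
            options = list(variant = variant, statistic = statistic, wc = wc,
                           denominator = denominator, reference = reference,
                           phenotype = phenotype, covariates = covariates,
                           min_mean_prop = min_mean_prop,
                           min_reads = min_reads, prior = prior,
                           small_sample = small_sample, p_adjust = p_adjust,
                           n_samples = ncol(m2),
                           n_subjects = length(unique(meta$subject_id)),
                           n_taxa = nrow(m2)))
}

#' @method tidy mtmat_result
#' @export
tidy.mtmat_result <- function(x, ...) {
  tibble::as_tibble(x)[, c("genus", "m1", "n_nodes", "min_p", "min_node",
                           "combined_p", "fdr_p", "beta_min")]
}

#' @method glance mtmat_result
#' @export
glance.mtmat_result <- function(x, ...) {
  opt <- attr(x, "options")
  tibble::tibble(n_genera = nrow(x),
                 n_significant = sum(x$fdr_p < 0.05),
                 n_samples = opt$n_samples, n_subjects = opt$n_subjects,
                 n_taxa = opt$n_taxa, variant = opt$variant,
                 statistic = opt$statistic, wc = opt$wc)
}

#' Plot genus-level association results
#'
#' Bar chart of \eqn{-\log_{10}} combined p-values per genus with the nominal
#' and FDR significance cut-offs.
#'
#' @param object An `mtmat_result` from [run_study()].
#' @param alpha Significance level for the reference line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtmat_result
#' @export
autoplot.mtmat_result <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  df$genus <- factor(df$genus, levels = df$genus[order(df$combined_p)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genus,
                                   y = -log10(.data$combined_p),
                                   fill = .data$fdr_p < alpha)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#c0392b"),
                               name = paste0("FDR < ", alpha)) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
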