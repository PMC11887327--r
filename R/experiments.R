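# Permutation-based spike-in experiments: empirical type-1 error, power, and
# the compositional-bias study. Each replicate subsamples subjects without
# replacement from the base table, assigns a permuted case/control status at
# the requested ratio (cases rounded down, controls rounded up), spikes the
# causal taxa of a randomly chosen test node, and runs the genus test.

ratio_case_count <- function(n_subjects, ratio = c("1:1", "1:3")) {
  ratio <- match.arg(ratio)
  floor(n_subjects * switch(ratio, "1:1" = 1 / 2, "1:3" = 1 / 4))
}

# Apply the standard cohort filters to a base table before an experiment,
# keeping the pre-taxon-filter library sizes for the CPM denominator. The
# permutation base is complete-case: subjects losing any visit to the read
# filter are dropped, so every retained subject has the full visit grid (as
# in a cohort restricted to subjects observed in all phases).
filter_base <- function(m, meta, min_reads, min_mean_prop) {
  if (min_reads > 0) m <- as_count_matrix(filter_samples(m, min_reads))
  meta <- meta[meta$sample_id %in% colnames(m), , drop = FALSE]
  full <- max(table(meta$subject_id))
  keep_subj <- names(which(table(meta$subject_id) == full))
  meta <- meta[meta$subject_id %in% keep_subj, , drop = FALSE]
  m <- m[, meta$sample_id, drop = FALSE]
  lib0 <- colSums(m)
  if (min_mean_prop > 0) m <- as_count_matrix(filter_taxa(m, min_mean_prop))
  list(m = m, meta = meta, lib0 = lib0)
}

# Per-node p-values with the drop-on-failure policy; returns NULL when no
# node is testable.
node_pvalues <- function(X, y, id, visit, wc, statistic, small_sample) {
  ps <- rep(NA_real_, ncol(X))
  for (j in seq_len(ncol(X))) {
    f <- tryCatch(
      gee_node_test(X[, j], y, id, visit = visit, wc = wc,
                    statistic = statistic, small_sample = small_sample),
      error = function(e) NULL)
    if (!is.null(f)) {
      ps[j] <- if (statistic == "score") f$p_score else f$p_wald
    }
  }
  ps[!is.na(ps)]
}

#' Type-1 error / power experiment
#'
#' Runs the permutation-based spike-in design on a base study: per replicate,
#' `n_subjects` subjects are drawn without replacement, case status is
#' assigned at random at the requested case:control ratio (independent of the
#' counts, so `beta = 0` replicates estimate the type-1 error), a test node of
#' the target genus is chosen at random, causal taxa are drawn from its
#' descendant leaves, case counts are spiked by \eqn{\delta = \beta
#' \hat\sigma_{mm}}, and the genus is tested with each requested working
#' correlation structure.
#'
#' @param sim A base study: an `mtmat_sim` from [generate_synthetic()] or a
#'   list with `counts`, `tree`, `taxonomy`, `metadata`.
#' @param genus Target genus. The default (`NULL`) draws a random multi-taxon
#'   genus per replicate, mirroring the random test-node selection of the
#'   permutation design; pass a genus name to fix the target.
#' @param n_subjects Subjects per replicate (default 50).
#' @param ratio Case:control ratio, `"1:1"` or `"1:3"`; for `"1:3"` cases are
#'   rounded down and controls up so the total stays `n_subjects`.
#' @param betas Effect multipliers; 0 gives the null (type-1) arm.
#' @param p_causal Causal fraction of the chosen node's leaves (`"single"`,
#'   `0.5`, `0.9`).
#' @param n_replicates Replicates per beta (default 500).
#' @param wc Character vector of working correlation structures to run on the
#'   same replicates.
#' @param variant,statistic,denominator,small_sample As in [test_genus()].
#' @param min_reads,min_mean_prop Cohort filters applied to the base table
#'   before the experiment (defaults as in [run_study()]); genera whose taxa
#'   are all filtered out are never drawn.
#' @param seed Optional integer seed (global RNG state untouched).
#' @return Tibble with one row per (replicate, beta, wc): columns
#'   `replicate`, `beta`, `wc`, `genus`, `combined_p`, `min_p`, `m1`
#'   (`combined_p` is `NA` when no node of the drawn genus was testable).
#'   Summarise with [rejection_rates()].
#' @export
run_type1_power <- function(sim, genus = NULL, n_subjects = 50,
                            ratio = c("1:1", "1:3"), betas = 0,
                            p_causal = 0.5, n_replicates = 500,
                            wc = "identity", variant = "IM",
                            statistic = "score",
                            denominator = "other_taxa", small_sample = TRUE,
                            min_reads = 3000, min_mean_prop = 0.001,
                            seed = NULL) {
  ratio <- match.arg(ratio)
  if (!is.null(seed)) return(withr::with_seed(seed, run_type1_power(
    sim, genus, n_subjects, ratio, betas, p_causal, n_replicates, wc,
    variant, statistic, denominator, small_sample, min_reads,
    min_mean_prop, seed = NULL)))

  fb <- filter_base(as_count_matrix(sim$counts), sim$metadata,
                    min_reads, min_mean_prop)
  m <- fb$m
  meta <- fb$meta
  tax <- sim$taxonomy[sim$taxonomy$taxon_id %in% rownames(m), , drop = FALSE]
  parts <- genus_partitions(prune_tree_to(sim$tree, rownames(m)), tax)
  multi <- names(parts)[vapply(parts, function(p) p$M1 > 1L, TRUE)]
  if (!is.null(genus)) multi <- genus # fixed target instead of random draws
  if (!length(multi)) stop("no genus to test", call. = FALSE)
  genus_sets <- lapply(parts, function(p) p$member_taxa)
  subjects <- unique(meta$subject_id)
  if (n_subjects > length(subjects)) {
    stop("`n_subjects` exceeds the base table", call. = FALSE)
  }
  n_cases <- ratio_case_count(n_subjects, ratio)
  sigma_mm <- taxon_variances(m)

  # order metadata subject/visit once; covariates for the unspiked table are
  # computed once per genus and subset per replicate
  meta <- meta[order(match(meta$subject_id, subjects), meta$visit), ]
  m <- m[, meta$sample_id, drop = FALSE]
  lib0 <- fb$lib0[meta$sample_id]
  r_base <- log_cpm(m, library_size = lib0)
  X_cache <- list()
  base_covariates <- function(g) {
    if (is.null(X_cache[[g]])) {
      X_cache[[g]] <<- genus_covariates(r_base, parts[[g]],
                                        denominator = denominator,
                                        genus_sets = genus_sets)
    }
    X_cache[[g]]
  }

  out <- vector("list", length(betas) * n_replicates * length(wc))
  row <- 0L
  for (beta in betas) {
    for (rep_i in seq_len(n_replicates)) {
      # the tested genus is drawn per replicate, like the random test-node
      # selection of the permutation design
      g <- if (length(multi) == 1L) multi else sample(multi, 1L)
      pt <- parts[[g]]
      drawn <- sample(subjects, n_subjects)
      cases <- drawn[seq_len(n_cases)]
      keep <- meta$subject_id %in% drawn
      meta_s <- meta[keep, , drop = FALSE]
      y <- as.numeric(meta_s$subject_id %in% cases)

      if (beta > 0) {
        causal <- choose_causal_taxa(pt, p_causal)
        msub <- m[, keep, drop = FALSE]
        ms <- spike_in(msub, case_samples = meta_s$sample_id[y == 1],
                       causal_taxa = causal$taxa, beta = beta,
                       sigma_mm = sigma_mm)
        lib_s <- lib0[keep] + colSums(ms) - colSums(msub)
        X <- genus_covariates(log_cpm(ms, library_size = lib_s), pt,
                              denominator = denominator,
                              genus_sets = genus_sets)
      } else {
        X <- base_covariates(g)[keep, , drop = FALSE]
      }
      if (variant == "IM") {
        X <- suppressWarnings(apply(X, 2L, inverse_normal_transform))
      }

      for (w in wc) {
        pv <- node_pvalues(X, y, meta_s$subject_id, meta_s$visit, w,
                           statistic, small_sample)
        row <- row + 1L
        out[[row]] <- tibble::tibble(
          replicate = rep_i, beta = beta, wc = w, genus = g,
          combined_p = if (length(pv)) combine_min_p(pv) else NA_real_,
          min_p = if (length(pv)) min(pv) else NA_real_,
          m1 = length(pv))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Empirical rejection rates
#'
#' Summarises per-replicate p-values into rejection rates with binomial
#' standard errors. When `null_p` is supplied (p-values from a matched
#' `beta = 0` run), the rejection threshold for each `(wc, alpha)` is the
#' empirical `alpha`-quantile of the null p-values instead of `alpha` itself
#' — the adjusted-threshold power comparison.
#'
#' @param p_tbl Output of [run_type1_power()].
#' @param alpha_levels Nominal significance levels.
#' @param null_p Optional tibble of null p-values (same format) for adjusted
#'   thresholds.
#' @return Tibble with columns `beta`, `wc`, `alpha`, `threshold`,
#'   `rejection`, `se`, `n_reps`.
#' @export
rejection_rates <- function(p_tbl, alpha_levels = c(0.1, 0.05, 0.01, 0.005),
                            null_p = NULL) {
  grid <- tidyr::expand_grid(
    dplyr::distinct(p_tbl, .data$beta, .data$wc),
    alpha = alpha_levels)
  purrr::pmap_dfr(grid, function(beta, wc, alpha) {
    ps <- p_tbl$combined_p[p_tbl$beta == beta & p_tbl$wc == wc]
    ps <- ps[!is.na(ps)]
    thr <- alpha
    if (!is.null(null_p)) {
      nps <- null_p$combined_p[null_p$wc == wc]
      nps <- nps[!is.na(nps)]
      if (!length(nps)) stop("no null p-values for wc = ", wc, call. = FALSE)
      thr <- unname(quantile(nps, alpha, type = 1))
    }
    rej <- mean(ps < thr)
    tibble::tibble(beta = beta, wc = wc, alpha = alpha, threshold = thr,
                   rejection = rej,
                   se = sqrt(rej * (1 - rej) / length(ps)),
                   n_reps = length(ps))
  })
}

#' Compositional-bias experiment
#'
#' Quantifies how a signal in a taxon outside the tested genus leaks into the
#' genus effect estimate through the shared reference of the pooled log-ratio
#' covariate. Per replicate the target genus is spiked as in the power design
#' (`beta`, `p_causal`); one external taxon is chosen at random and made
#' phenotype-associated, with its case-sample counts increased by its
#' standard deviation times each `multiplier` (multiplier 0 is the control
#' arm with no external effect); the pooled-node effect \eqn{\hat\beta_0} is
#' then estimated (robust Wald fit) under each reference mode. The bias
#' estimate of a replicate is the paired difference against the same
#' replicate with no external effect, so the mean and interquartile range of
#' the bias isolate the leakage through the reference.
#'
#' @inheritParams run_type1_power
#' @param beta Effect multiplier for the genus spike (default 0.15).
#' @param multipliers External-taxon inflation factors
#'   (default `c(0, 1, 5, 10, 50, 100)`).
#' @param denominators Reference modes to compare.
#' @param reference Reference genus for the `"alr"` mode; by default a
#'   random genus other than the tested one is drawn per replicate.
#' @return Tibble with one row per (replicate, multiplier, denominator):
#'   `beta_hat` is the pooled-node effect estimate, `beta_ref` the paired
#'   estimate for the same replicate without any external-taxon effect, and
#'   `bias_hat` their difference. Summarise with [bias_summary()].
#' @export
run_bias_experiment <- function(sim, genus = NULL, n_subjects = 50,
                                ratio = "1:3", beta = 0.15, p_causal = 0.5,
                                multipliers = c(0, 1, 5, 10, 50, 100),
                                denominators = c("other_taxa", "alr", "clr"),
                                reference = NULL, n_replicates = 2000,
                                wc = "identity", variant = "IM",
                                small_sample = TRUE, min_reads = 3000,
                                min_mean_prop = 0.001, seed = NULL) {
  if (!is.null(seed)) return(withr::with_seed(seed, run_bias_experiment(
    sim, genus, n_subjects, ratio, beta, p_causal, multipliers,
    denominators, reference, n_replicates, wc, variant, small_sample,
    min_reads, min_mean_prop, seed = NULL)))

  fb <- filter_base(as_count_matrix(sim$counts), sim$metadata,
                    min_reads, min_mean_prop)
  m <- fb$m
  meta <- fb$meta
  tax <- sim$taxonomy[sim$taxonomy$taxon_id %in% rownames(m), , drop = FALSE]
  parts <- genus_partitions(prune_tree_to(sim$tree, rownames(m)), tax)
  if (length(parts) < 2L) stop("need at least two genera", call. = FALSE)
  multi <- names(parts)[vapply(parts, function(p) p$M1 > 1L, TRUE)]
  if (!is.null(genus)) multi <- genus
  if (!length(multi)) stop("no multi-taxon genus in the base table",
                           call. = FALSE)
  genus_sets <- lapply(parts, function(p) p$member_taxa)
  subjects <- unique(meta$subject_id)
  n_cases <- ratio_case_count(n_subjects,
                              match.arg(ratio, c("1:1", "1:3")))
  sigma_mm <- taxon_variances(m)
  sd_mm <- sqrt(sigma_mm)
  meta <- meta[order(match(meta$subject_id, subjects), meta$visit), ]
  m <- m[, meta$sample_id, drop = FALSE]
  lib0 <- fb$lib0[meta$sample_id]

  out <- vector("list", n_replicates * length(multipliers) *
                  length(denominators))
  row <- 0L
  for (rep_i in seq_len(n_replicates)) {
    # drawn per replicate: the tested genus, the ALR reference genus (unless
    # fixed) and the external taxon
    g <- if (length(multi) == 1L) multi else sample(multi, 1L)
    pt <- parts[[g]]
    ref_g <- if (!is.null(reference)) reference else {
      others <- setdiff(names(parts), g)
      if (length(others) == 1L) others else sample(others, 1L)
    }
    drawn <- sample(subjects, n_subjects)
    cases <- drawn[seq_len(n_cases)]
    keep <- meta$subject_id %in% drawn
    meta_s <- meta[keep, , drop = FALSE]
    y <- as.numeric(meta_s$subject_id %in% cases)
    case_samp <- meta_s$sample_id[y == 1]

    msub <- m[, keep, drop = FALSE]
    causal <- choose_causal_taxa(pt, p_causal)
    ms_ref <- spike_in(msub, case_samp, causal$taxa,
                       beta = beta, sigma_mm = sigma_mm)
    # one random taxon outside the genus is also phenotype-associated; the
    # multiplier scales its case-sample abundance shift in units of its
    # standard deviation
    ext <- sample(setdiff(rownames(m), pt$member_taxa), 1L)

    fit_pooled <- function(ms, den) {
      lib_s <- lib0[keep] + colSums(ms) - colSums(msub)
      x0 <- pooled_covariate(log_cpm(ms, library_size = lib_s), pt,
                             denominator = den,
                             reference = if (den == "alr") ref_g,
                             genus_sets = genus_sets)
      if (variant == "IM") {
        x0 <- suppressWarnings(inverse_normal_transform(x0))
      }
      tryCatch(
        gee_node_test(x0, y, meta_s$subject_id, visit = meta_s$visit,
                      wc = wc, statistic = "wald",
                      small_sample = small_sample),
        error = function(e) NULL)
    }
    # paired reference: the same replicate with no external-taxon effect
    ref_betas <- vapply(denominators, function(den) {
      f <- fit_pooled(ms_ref, den)
      if (is.null(f)) NA_real_ else f$beta_hat
    }, numeric(1))

    for (mult in multipliers) {
      ms <- ms_ref
      if (mult > 0) {
        ms[ext, case_samp] <-
          round_half_up(ms[ext, case_samp] + mult * sd_mm[[ext]])
      }
      for (den in denominators) {
        f <- fit_pooled(ms, den)
        row <- row + 1L
        out[[row]] <- tibble::tibble(
          replicate = rep_i, multiplier = mult, denominator = den,
          genus = g,
          beta_hat = if (is.null(f)) NA_real_ else f$beta_hat,
          beta_ref = ref_betas[[den]],
          bias_hat = if (is.null(f)) NA_real_ else {
            f$beta_hat - ref_betas[[den]]
          },
          p_wald = if (is.null(f)) NA_real_ else f$p_wald)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Summarise the compositional-bias experiment
#'
#' The bias estimate of a replicate is the paired difference between the
#' pooled-node effect with and without the external-taxon manipulation
#' (`bias_hat = beta_hat - beta_ref`).
#'
#' @param bias_tbl Output of [run_bias_experiment()].
#' @return Tibble per (denominator, multiplier): `mean_bias`, `iqr_bias`
#'   (interquartile range of the bias estimate), `mean_beta` (mean effect
#'   estimate), and the number of valid replicates.
#' @export
bias_summary <- function(bias_tbl) {
  bias_tbl |>
    dplyr::group_by(.data$denominator, .data$multiplier) |>
    dplyr::summarise(mean_bias = mean(.data$bias_hat, na.rm = TRUE),
                     iqr_bias = stats::IQR(.data$bias_hat, na.rm = TRUE),
                     mean_beta = mean(.data$beta_hat, na.rm = TRUE),
                     n_reps = sum(!is.na(.data$bias_hat)),
                     .groups = "drop")
}
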