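# Synthetic longitudinal 16S count generator. Latent Gaussian log-abundances
# with a subject-level correlation structure are pushed through a softmax and
# thinned to a log-normal library size (Poisson sampling). The softmax
# temperature is calibrated numerically so the expected zero fraction of the
# table hits the requested sparsity.

# Random rooted binary tree in which every genus is a clade. Recursive random
# splits; reproducible from the RNG state.
random_binary_newick <- function(tips) {
  build <- function(v) {
    if (length(v) == 1L) return(v)
    k <- if (length(v) == 2L) 1L else sample(length(v) - 1L, 1L)
    paste0("(", build(v[seq_len(k)]), ",", build(v[-seq_len(k)]), ")")
  }
  build(sample(tips))
}

genus_tree <- function(genus_sets) {
  subs <- vapply(genus_sets, random_binary_newick, character(1))
  build <- function(v) {
    if (length(v) == 1L) return(v)
    k <- if (length(v) == 2L) 1L else sample(length(v) - 1L, 1L)
    paste0("(", build(v[seq_len(k)]), ",", build(v[-seq_len(k)]), ")")
  }
  parse_tree(paste0(build(sample(subs)), ";"))
}

# Unit-variance within-subject noise for one taxon: n_subjects x n_visits.
latent_noise <- function(n_subjects, n_visits, correlation, rho) {
  switch(correlation,
    identity = matrix(rnorm(n_subjects * n_visits), n_subjects),
    cs = sqrt(rho) * matrix(rnorm(n_subjects), n_subjects, n_visits) +
      sqrt(1 - rho) * matrix(rnorm(n_subjects * n_visits), n_subjects),
    ar1 = {
      m <- matrix(0, n_subjects, n_visits)
      m[, 1L] <- rnorm(n_subjects)
      for (j in seq_len(n_visits)[-1L]) {
        m[, j] <- rho * m[, j - 1L] +
          sqrt(1 - rho^2) * rnorm(n_subjects)
      }
      m
    })
}

#' Generate a synthetic longitudinal microbiome study
#'
#' Emulates the structure of a repeatedly measured 16S profiling study:
#' several genera of different sizes, each a clade on a random rooted binary
#' tree; up to `n_visits` samples per subject with a chosen within-subject
#' correlation structure on the latent log-abundance scale; sparse counts
#' obtained by Poisson thinning to a log-normal library size; and a binary
#' phenotype independent of the counts (a null phenotype — association is
#' introduced separately by [spike_in()]).
#'
#' The softmax temperature of the latent abundances is calibrated by
#' root-finding so that the expected fraction of zero cells equals `sparsity`.
#'
#' @param n_subjects Number of subjects (default 50).
#' @param n_visits Visits per subject (default 3, balanced).
#' @param genus_sizes Integer vector of taxa per genus. The default — 24
#'   genera of sizes 1 to 20, 168 taxa in total — mirrors a filtered
#'   species-level 16S cohort where a few hundred species share libraries of
#'   a few thousand to a few tens of thousands of reads, so typical per-taxon
#'   counts are in the tens.
#' @param sparsity Target zero fraction of the count table (default 0.64).
#' @param correlation Within-subject latent correlation structure:
#'   `"identity"`, `"cs"`, or `"ar1"`.
#' @param rho Correlation parameter for `"cs"`/`"ar1"` (default 0.4).
#' @param taxon_sd Standard deviation of taxon baseline log-abundances
#'   (default 1).
#' @param noise_sd Standard deviation of the within-subject latent noise
#'   (default 1).
#' @param lib_meanlog,lib_sdlog Log-normal library-size parameters (defaults
#'   `log(1e4)` and 0.5, spanning roughly 3000-30000 reads).
#' @param case_fraction Fraction of subjects labelled cases (default 0.5).
#' @param seed Optional integer seed; the output is reproducible from it and
#'   the global RNG state is left untouched.
#' @return A list of class `mtmat_sim` with elements `counts` (wide tibble),
#'   `tree` (`phylo`), `taxonomy`, `metadata` (tibbles), and `config`.
#' @examples
#' sim <- generate_synthetic(n_subjects = 10, seed = 1)
#' dim(as.matrix(sim$counts[-1]))
#' @export
generate_synthetic <- function(n_subjects = 50, n_visits = 3,
                               genus_sizes = rep(c(1L, 2L, 3L, 4L, 6L, 8L,
                                                   12L, 20L), 3),
                               sparsity = 0.64,
                               correlation = c("identity", "cs", "ar1"),
                               rho = 0.4, taxon_sd = 1, noise_sd = 1,
                               lib_meanlog = log(1e4), lib_sdlog = 0.5,
                               case_fraction = 0.5, seed = NULL) {
  correlation <- match.arg(correlation)
  if (!is.null(seed)) return(withr::with_seed(seed, generate_synthetic(
    n_subjects, n_visits, genus_sizes, sparsity, correlation, rho,
    taxon_sd, noise_sd, lib_meanlog, lib_sdlog, case_fraction, seed = NULL)))

  M <- sum(genus_sizes)
  Tg <- length(genus_sizes)
  genus <- rep(paste0("g", seq_len(Tg)), genus_sizes)
  taxa <- paste0(genus, "_t", unlist(lapply(genus_sizes, seq_len)))
  genus_sets <- split(taxa, genus)[paste0("g", seq_len(Tg))]

  n_samp <- n_subjects * n_visits
  z <- rnorm(M, 0, taxon_sd)
  noise <- matrix(0, M, n_samp) # taxa x samples, visit-within-subject order
  for (m in seq_len(M)) {
    u <- latent_noise(n_subjects, n_visits, correlation, rho)
    noise[m, ] <- noise_sd * as.vector(t(u))
  }
  lib <- round_half_up(rlnorm(n_samp, lib_meanlog, lib_sdlog))

  # Calibrate the spread of the taxon baselines to the target sparsity.
  # Only the between-taxon baseline is scaled: zeros arise from rare taxa,
  # while the within-taxon temporal dispersion stays at noise_sd on the log
  # scale (about one log unit, as in real 16S profiles).
  zero_frac <- function(s) {
    w <- exp(s * z + noise)
    p <- sweep(w, 2L, colSums(w), "/")
    mean(exp(-sweep(p, 2L, lib, "*")))
  }
  s <- uniroot(function(s) zero_frac(s) - sparsity,
               lower = 0.05, upper = 25, tol = 1e-4)$root
  w <- exp(s * z + noise)
  p <- sweep(w, 2L, colSums(w), "/")
  counts <- matrix(rpois(M * n_samp, sweep(p, 2L, lib, "*")), M, n_samp)

  subj <- paste0("s", sprintf("%03d", seq_len(n_subjects)))
  sample_id <- paste0(rep(subj, each = n_visits), "_v",
                      rep(seq_len(n_visits), n_subjects))
  dimnames(counts) <- list(taxa, sample_id)

  n_cases <- round_half_up(n_subjects * case_fraction)
  pheno_subj <- setNames(rep(0L, n_subjects), subj)
  pheno_subj[sample(subj, n_cases)] <- 1L

  metadata <- tibble::tibble(
    sample_id = sample_id,
    subject_id = rep(subj, each = n_visits),
    visit = rep(seq_len(n_visits), n_subjects),
    phenotype = as.integer(pheno_subj[rep(subj, each = n_visits)]))
  taxonomy <- tibble::tibble(taxon_id = taxa, genus = genus)

  structure(
    list(counts = matrix_to_counts(counts),
         tree = genus_tree(genus_sets),
         taxonomy = taxonomy,
         metadata = metadata,
         config = list(n_subjects = n_subjects, n_visits = n_visits,
                       genus_sizes = genus_sizes, sparsity = sparsity,
                       correlation = correlation, rho = rho,
                       taxon_sd = taxon_sd, noise_sd = noise_sd,
                       lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
                       case_fraction = case_fraction, softmax_scale = s)),
    class = "mtmat_sim")
}

#' @export
print.mtmat_sim <- function(x, ...) {
  cfg <- x$config
  m <- as_count_matrix(x$counts)
  cat("<mtmat_sim> ", cfg$n_subjects, " subjects x ", cfg$n_visits,
      " visits, ", nrow(m), " taxa in ", length(cfg$genus_sizes),
      " genera; realized sparsity ", sprintf("%.2f", mean(m == 0)), "\n",
      sep = "")
  invisible(x)
}

#' Per-taxon sample variances of the absolute abundances
#'
#' Computed once over all samples of the base table (subjects and visits
#' pooled); the spike increment for a causal taxon is `beta` times this
#' variance.
#'
#' @inheritParams filter_taxa
#' @return Named numeric vector of variances.
#' @export
taxon_variances <- function(counts) {
  m <- as_count_matrix(counts)
  apply(m, 1L, var)
}

#' Choose causal taxa for a spike-in replicate
#'
#' Picks a test node uniformly at random among the genus' internal nodes and
#' draws the causal taxa from that node's descendant leaves: a single taxon
#' (`p_causal = "single"`), or a fraction of the leaves (e.g. `0.5`, `0.9`),
#' rounded half-up with a minimum of one. A single-taxon genus has no internal
#' node; the single leaf is used (with a warning when a fraction was asked
#' for).
#'
#' @param partition A `genus_partition`.
#' @param p_causal `"single"` or a fraction in (0, 1].
#' @param node Optional fixed node index `k` (bypasses the random choice).
#' @return List with `node` (k or `NA`) and `taxa` (character vector).
#' @export
choose_causal_taxa <- function(partition, p_causal = 0.5, node = NULL) {
  tn <- partition$test_nodes
  if (nrow(tn) == 0L) {
    if (!identical(p_causal, "single")) {
      warning("single-taxon genus: falling back to its only leaf",
              call. = FALSE)
    }
    return(list(node = NA_integer_, taxa = partition$member_taxa))
  }
  k <- node %||% sample(tn$k, 1L)
  desc <- c(tn$left[[match(k, tn$k)]], tn$right[[match(k, tn$k)]])
  if (identical(p_causal, "single")) {
    return(list(node = k, taxa = sample(desc, 1L)))
  }
  n_causal <- max(1L, round_half_up(p_causal * length(desc)))
  list(node = k, taxa = sample(desc, n_causal))
}

#' Spike an association into case samples
#'
#' Adds the increment \eqn{\delta = \beta \hat\sigma_{mm}} (effect multiplier
#' times the taxon's sample variance in the base table) to each case sample's
#' count of every causal taxon, rounding the result half-up to keep the table
#' count-valued. Controls and non-causal taxa are untouched; with
#' `beta = 0` the table is returned unchanged.
#'
#' @inheritParams filter_taxa
#' @param case_samples Character vector of case sample ids (columns).
#' @param causal_taxa Character vector of causal taxon ids (rows).
#' @param beta Effect multiplier (e.g. 0, 0.01, 0.02, 0.04).
#' @param sigma_mm Optional named per-taxon variances (see
#'   [taxon_variances()]); computed from `counts` when missing.
#' @return Spiked counts in the same container type as the input.
#' @export
spike_in <- function(counts, case_samples, causal_taxa, beta,
                     sigma_mm = NULL) {
  m <- as_count_matrix(counts)
  if (beta == 0) return(restore_counts_type(m, counts))
  if (is.null(sigma_mm)) sigma_mm <- taxon_variances(m)
  stopifnot(all(causal_taxa %in% rownames(m)),
            all(case_samples %in% colnames(m)))
  delta <- beta * sigma_mm[causal_taxa]
  m[causal_taxa, case_samples] <-
    round_half_up(m[causal_taxa, case_samples, drop = FALSE] + delta)
  restore_counts_type(m, counts)
}
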