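test_that("generator hits the sparsity target and is seed-reproducible", {
  for (sp in c(0.52, 0.64, 0.73)) {
    sim <- generate_synthetic(n_subjects = 40, sparsity = sp, seed = 50)
    m <- as.matrix(sim$counts[-1])
    expect_gt(mean(m == 0), sp - 0.05)
    expect_lt(mean(m == 0), sp + 0.05)
  }
  a <- generate_synthetic(n_subjects = 15, seed = 51)
  b <- generate_synthetic(n_subjects = 15, seed = 51)
  expect_identical(a$counts, b$counts)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  d <- generate_synthetic(n_subjects = 15, seed = 52)
  expect_false(identical(a$counts, d$counts))
  # generating with a seed leaves the global RNG stream untouched
  set.seed(1); r1 <- rnorm(1)
  set.seed(1); invisible(generate_synthetic(n_subjects = 5, seed = 3))
  expect_identical(rnorm(1), r1)
})

test_that("generator output is structurally consistent", {
  sim <- generate_synthetic(n_subjects = 12, n_visits = 2,
                            genus_sizes = c(1L, 4L, 7L), seed = 53)
  m <- as.matrix(sim$counts[-1])
  expect_equal(dim(m), c(12, 24))
  expect_true(all(m >= 0 & m == round(m)))
  expect_equal(nrow(sim$metadata), 24)
  expect_equal(sort(unique(sim$taxonomy$genus)), c("g1", "g2", "g3"))
  expect_true(ape::is.binary(sim$tree))
  # every genus is a clade on the generated tree
  parts <- genus_partitions(sim$tree, sim$taxonomy)
  expect_equal(vapply(parts, function(p) p$M1, integer(1)),
               c(g1 = 1L, g2 = 4L, g3 = 7L))
})

test_that("latent correlation structure shows up in the residuals", {
  lag1_cor <- function(sim) {
    m <- as.matrix(sim$counts[-1])
    rownames(m) <- sim$counts$taxon_id
    r <- log_cpm(m)
    rc <- r - rowMeans(r) # centre per taxon
    J <- sim$config$n_visits
    v1 <- as.vector(rc[, seq(1, ncol(rc), by = J)])
    v2 <- as.vector(rc[, seq(2, ncol(rc), by = J)])
    cor(v1, v2)
  }
  id_cor <- lag1_cor(generate_synthetic(n_subjects = 300, n_visits = 2,
                                        correlation = "identity",
                                        seed = 54))
  cs_cor <- lag1_cor(generate_synthetic(n_subjects = 300, n_visits = 2,
                                        correlation = "cs", rho = 0.7,
                                        seed = 54))
  expect_lt(abs(id_cor), 0.05)
  expect_gt(cs_cor, id_cor + 0.1)
})

test_that("spike-in adds beta times the taxon variance to cases only", {
  m <- tiny_counts(c(10, 20, 30, 40,
                     5,  5,  5,  5), c("t1", "t2"), paste0("s", 1:4))
  out <- spike_in(m, case_samples = c("s1", "s3"), causal_taxa = "t1",
                  beta = 0.04, sigma_mm = c(t1 = 250, t2 = 100))
  # delta = 0.04 * 250 = 10 added to cases of the causal taxon
  expect_equal(out["t1", ], c(s1 = 20, s2 = 20, s3 = 40, s4 = 40))
  # non-causal rows and control columns bit-exact
  expect_identical(out["t2", ], m["t2", ])
  expect_identical(out[, c("s2", "s4")], m[, c("s2", "s4")])
  # beta = 0 leaves the table untouched
  expect_identical(spike_in(m, c("s1", "s3"), "t1", beta = 0), m)
  # fractional deltas round half-up to stay count-valued
  out2 <- spike_in(m, "s1", "t1", beta = 0.01, sigma_mm = c(t1 = 250))
  expect_equal(out2["t1", "s1"], 13) # 10 + 2.5 -> 13
})

test_that("causal-taxon selection respects the fraction and the node", {
  tr <- parse_tree("(((A,B),(C,D)),E);")
  gp <- enumerate_test_nodes(tr, c("A", "B", "C", "D"), genus = "g")
  # node k = 1 has 4 descendant leaves: 50% -> 2, 90% -> 4
  withr::with_seed(55, {
    c50 <- choose_causal_taxa(gp, 0.5, node = 1L)
    c90 <- choose_causal_taxa(gp, 0.9, node = 1L)
    cs <- choose_causal_taxa(gp, "single", node = 1L)
  })
  expect_length(c50$taxa, 2)
  expect_length(c90$taxa, 4)
  expect_length(cs$taxa, 1)
  expect_true(all(c50$taxa %in% c("A", "B", "C", "D")))
  # single-taxon genus falls back to its only leaf with a warning
  gp1 <- enumerate_test_nodes(tr, "E")
  expect_warning(c1 <- choose_causal_taxa(gp1, 0.5), "single-taxon")
  expect_equal(c1$taxa, "E")
})

test_that("case counts follow the rounding convention of the ratio", {
  expect_equal(mtmat:::ratio_case_count(50, "1:1"), 25)
  expect_equal(mtmat:::ratio_case_count(50, "1:3"), 12) # 12 cases, 38 controls
  expect_equal(mtmat:::ratio_case_count(30, "1:3"), 7)
  expect_equal(mtmat:::ratio_case_count(100, "1:3"), 25)
})

test_that("experiment harness is reproducible and summarised correctly", {
  sim <- small_study()
  p1 <- run_type1_power(sim, n_subjects = 15, betas = 0, n_replicates = 8,
                        wc = c("identity", "cs"), seed = 56)
  p2 <- run_type1_power(sim, n_subjects = 15, betas = 0, n_replicates = 8,
                        wc = c("identity", "cs"), seed = 56)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 8 * 2)
  expect_true(all(p1$combined_p > 0 & p1$combined_p <= 1))

  rates <- rejection_rates(p1, alpha_levels = c(0.5, 0.05))
  expect_equal(nrow(rates), 4)
  got <- rates$rejection[rates$wc == "identity" & rates$alpha == 0.5]
  ps <- p1$combined_p[p1$wc == "identity"]
  expect_equal(got, mean(ps < 0.5))

  # adjusted thresholds come from the null quantiles
  null_p <- p1
  rates_adj <- rejection_rates(p1, alpha_levels = 0.5, null_p = null_p)
  thr <- unname(quantile(ps, 0.5, type = 1))
  expect_equal(rates_adj$threshold[rates_adj$wc == "identity"], thr)
})

test_that("bias summary reports paired means and IQRs per multiplier", {
  set.seed(60)
  ref <- rnorm(40, 1)
  tbl <- tibble::tibble(
    replicate = rep(1:10, 4),
    multiplier = rep(c(0, 0, 100, 100), each = 10),
    denominator = rep(c("other_taxa", "alr"), times = 20),
    beta_ref = ref,
    beta_hat = ref + c(rnorm(20, 0, 0.01), rnorm(10, 0.1), rnorm(10, 0.5)))
  tbl$bias_hat <- tbl$beta_hat - tbl$beta_ref
  s <- bias_summary(tbl)
  expect_equal(nrow(s), 4)
  expect_true(all(c("mean_bias", "iqr_bias", "mean_beta") %in% names(s)))
  got <- s$mean_bias[s$denominator == "alr" & s$multiplier == 100]
  want <- mean(tbl$bias_hat[tbl$denominator == "alr" &
                              tbl$multiplier == 100])
  expect_equal(got, want)
})
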