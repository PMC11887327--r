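test_that("log-CPM matches the closed-form values", {
  # zero count in a library of 1000 with unit pseudo-count
  m <- tiny_counts(c(0, 1000), c("t1", "t2"), "s1")
  r <- log_cpm(m)
  expect_equal(r["t1", 1], log_cpm_formula(0, 1000), tolerance = 1e-12)
  expect_equal(r["t1", 1], 8.9674, tolerance = 1e-4)

  # a single taxon carrying the whole library of 1e4
  m2 <- tiny_counts(c(10000, 0), c("t1", "t2"), "s1")
  r2 <- log_cpm(m2)
  expect_equal(r2["t1", 1], log_cpm_formula(10000, 10000), tolerance = 1e-12)
  expect_equal(r2["t1", 1], 19.9315, tolerance = 1e-4)

  # strictly positive and monotone in the count at fixed library size
  cnt <- c(0, 1, 5, 50, 500)
  m3 <- tiny_counts(c(cnt, 1000 - cnt), paste0("t", 1:2),
                    paste0("s", seq_along(cnt)))
  r3 <- log_cpm(m3, library_size = rep(1000, 5))
  expect_true(all(r3 > 0))
  expect_true(all(diff(r3["t1", ]) > 0))

  expect_error(log_cpm(tiny_counts(c(0, 0), c("t1", "t2"), "s1")),
               "zero library")
})

test_that("library-scaled pseudo-count policy follows the library sizes", {
  m <- tiny_counts(c(100, 300, 900, 2700), c("t1", "t2"),
                   c("s1", "s2")) # libraries 1000 and 3000, mean 2000
  r <- log_cpm(m, prior = "library_scaled")
  expect_equal(r["t1", "s1"], log_cpm_formula(100, 1000, cdot = 0.5),
               tolerance = 1e-12)
  expect_equal(r["t1", "s2"], log_cpm_formula(300, 3000, cdot = 1.5),
               tolerance = 1e-12)
})

test_that("node covariate is the natural-log ratio of pooled values", {
  r <- tiny_counts(c(3, 4, 2, 1,
                     1, 2, 1, 2,
                     2, 2, 3, 3), paste0("t", 1:3), paste0("s", 1:4))
  x <- node_covariate(r, left = c("t1", "t2"), right = "t3")
  expect_equal(unname(x),
               unname(log(colSums(r[1:2, ]) / r[3, ])), tolerance = 1e-12)
  # equal pools give zero, doubled numerator gives log 2
  r2 <- tiny_counts(c(2, 4, 2, 2), c("a", "b"), c("s1", "s2"))
  expect_equal(unname(node_covariate(r2, "a", "b")), c(0, log(2)))
  # swapping the leaf sets negates the covariate
  expect_equal(node_covariate(r, c("t1", "t2"), "t3"),
               -node_covariate(r, "t3", c("t1", "t2")))
  expect_error(node_covariate(r, character(0), "t3"), "non-empty")
  expect_error(node_covariate(r, "t9", "t3"), "not in table")
})

test_that("pooled covariate supports default, ALR and CLR references", {
  tr <- parse_tree("(((A,B),C),(D,E));")
  gp <- enumerate_test_nodes(tr, c("A", "B", "C"), genus = "g1")
  gsets <- list(g1 = c("A", "B", "C"), g2 = c("D", "E"))
  r <- tiny_counts(c(1, 2,
                     1, 2,
                     1, 2,
                     2, 4,
                     1, 2), c("A", "B", "C", "D", "E"), c("s1", "s2"))
  # default: log(E/G) exactly
  x0 <- pooled_covariate(r, gp)
  expect_equal(unname(x0), log(c(3, 6) / c(3, 6)))
  # ALR against g2
  xa <- pooled_covariate(r, gp, denominator = "alr", reference = "g2",
                         genus_sets = gsets)
  expect_equal(unname(xa), log(c(3, 6) / c(3, 6)))
  # CLR: all genus sums equal makes the covariate zero
  req <- tiny_counts(rep(1, 10), c("A", "B", "C", "D", "E"),
                     c("s1", "s2"))
  gsets_eq <- list(g1 = c("A", "B", "C"), g2 = c("D", "E"))
  req["D", ] <- 2 # g2 sum = 3 = g1 sum
  xc <- pooled_covariate(req, gp, denominator = "clr",
                         genus_sets = gsets_eq)
  expect_equal(unname(xc), c(0, 0), tolerance = 1e-12)
  # degenerate configurations
  expect_error(pooled_covariate(r, gp, denominator = "alr",
                                reference = "g1", genus_sets = gsets),
               "differ from the tested genus")
  expect_error(pooled_covariate(r, gp, denominator = "alr",
                                genus_sets = gsets), "must name a genus")
})

test_that("inverse normal transform uses offset-0.5 average ranks", {
  z <- inverse_normal_transform(c(2.1, 5.3, 0.7))
  expect_equal(z, qnorm(c(1.5, 2.5, 0.5) / 3), tolerance = 1e-12)
  expect_equal(z, c(0, 0.9674, -0.9674), tolerance = 1e-4)

  # ties map to the same value through average ranks
  zt <- inverse_normal_transform(c(1, 1, 2))
  expect_equal(zt, qnorm(c(1, 1, 2.5) / 3), tolerance = 1e-12)
  expect_equal(zt[1], zt[2])

  # rank preserving and near-zero mean for tie-free input
  set.seed(5)
  v <- rnorm(101)
  zv <- inverse_normal_transform(v)
  expect_equal(order(v), order(zv))
  expect_lt(abs(mean(zv)), 1e-10)
  expect_equal(sort(zv), qnorm((seq_along(v) - 0.5) / length(v)),
               tolerance = 1e-12)

  expect_warning(zall <- inverse_normal_transform(rep(3, 4)),
                 "identical")
  expect_equal(zall, rep(0, 4))
  expect_error(inverse_normal_transform(1), "at least two")
})

test_that("covariates are nearly invariant to sequencing-depth changes", {
  sim <- generate_synthetic(n_subjects = 15, genus_sizes = c(3L, 5L, 8L),
                            sparsity = 0.55, lib_meanlog = log(5e4),
                            lib_sdlog = 0.1, seed = 9)
  m <- as.matrix(sim$counts[-1])
  rownames(m) <- sim$counts$taxon_id
  parts <- genus_partitions(sim$tree, sim$taxonomy)
  gp <- parts[[2]]

  # rescaling one sample's depth: with the library-scaled pseudo-count the
  # factor cancels from its log-CPM up to the shared-mean drift, so the
  # node covariate moves by less than 1e-2 even on sparse data
  for (s in c(0.5, 2)) {
    ms <- m
    ms[, 7] <- ms[, 7] * s
    x1 <- node_covariate(log_cpm(m, prior = "library_scaled"),
                         gp$test_nodes$left[[1]], gp$test_nodes$right[[1]])
    x2 <- node_covariate(log_cpm(ms, prior = "library_scaled"),
                         gp$test_nodes$left[[1]], gp$test_nodes$right[[1]])
    expect_lt(max(abs(x1 - x2)), 1e-2)
  }

  # on zero-free data the property holds for every sample at once under the
  # default pseudo-count: counts dominate the prior everywhere
  withr::with_seed(11, {
    nt <- nrow(m)
    p0 <- matrix(rexp(nt * 45), nt) + 0.25
    p0 <- sweep(p0, 2L, colSums(p0), "/")
    lib <- round(rlnorm(45, log(5e4), 0.1))
    md <- matrix(rpois(nt * 45, sweep(p0, 2L, lib, "*")), nt,
                 dimnames = list(rownames(m), paste0("d", 1:45)))
    s <- runif(45, 0.5, 2)
  })
  expect_equal(min(md) > 0, TRUE)
  x1 <- node_covariate(log_cpm(md), gp$test_nodes$left[[1]],
                       gp$test_nodes$right[[1]])
  x2 <- node_covariate(log_cpm(sweep(md, 2L, s, "*")),
                       gp$test_nodes$left[[1]], gp$test_nodes$right[[1]])
  expect_lt(max(abs(x1 - x2)), 1e-3)
})
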