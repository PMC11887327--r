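test_that("identity working correlation reduces to OLS", {
  set.seed(21)
  n <- 40
  id <- rep(1:10, each = 4)
  Z <- cbind(1, rnorm(n))
  y <- rep(rbinom(10, 1, 0.5), each = 4)
  x <- drop(Z %*% c(1, 0.5)) + 0.3 * y + rnorm(n)
  f <- gee_node_test(x, y, id, Z = Z, wc = "identity", statistic = "both")
  # null-model alpha is the OLS fit of x on Z
  expect_equal(unname(f$score$alpha), unname(coef(lm(x ~ Z[, 2]))),
               tolerance = 1e-10)
  # full-model (alpha, beta) is OLS on [Z y]
  ols <- coef(lm(x ~ Z[, 2] + y))
  expect_equal(f$beta_hat, unname(ols[3]), tolerance = 1e-10)
})

test_that("one visit per subject collapses every structure to identity", {
  set.seed(22)
  n <- 30
  id <- seq_len(n)
  y <- rbinom(n, 1, 0.5)
  x <- rnorm(n) + 0.2 * y
  f_id <- gee_node_test(x, y, id, wc = "identity", statistic = "both")
  for (w in c("cs", "ar1")) {
    f <- gee_node_test(x, y, id, wc = w, statistic = "both")
    expect_equal(f$T_score, f_id$T_score, tolerance = 1e-8)
    expect_equal(f$T_wald, f_id$T_wald, tolerance = 1e-8)
  }
})

test_that("engine matches the dense-matrix transcription of the formulas", {
  set.seed(23)
  for (wcx in c("identity", "cs", "ar1")) {
    for (ss in c(TRUE, FALSE)) {
      inst <- random_gee_instance(p_extra = sample(0:2, 1))
      f <- gee_node_test(inst$x, inst$y, inst$id, visit = inst$visit,
                         Z = inst$Z, wc = wcx, statistic = "both",
                         small_sample = ss)
      osc <- oracle_gee(inst$x, inst$y, inst$Z, inst$id, inst$visit, wcx,
                        params = list(sigma = f$score$sigma,
                                      rho = f$score$rho, R = f$score$R),
                        small_sample = ss)
      expect_equal(f$T_score, osc$T_score, tolerance = 1e-8)
      expect_equal(unname(f$score$alpha), unname(osc$alpha),
                   tolerance = 1e-8)
      if (ss) {
        owd <- oracle_gee(inst$x, inst$y, inst$Z, inst$id, inst$visit, wcx,
                          params = list(sigma = f$wald$sigma,
                                        rho = f$wald$rho, R = f$wald$R))
        expect_equal(f$T_wald, owd$T_wald, tolerance = 1e-8)
        expect_equal(f$beta_hat, owd$beta, tolerance = 1e-8)
        expect_equal(f$V_hat, owd$V, tolerance = 1e-8)
      }
    }
  }
})

test_that("unadjusted Wald equals the classical cluster-robust sandwich", {
  set.seed(24)
  n <- 36
  id <- seq_len(n) # one visit per subject, identity wc
  y <- rbinom(n, 1, 0.5)
  x <- rnorm(n) + 0.4 * y
  f <- gee_node_test(x, y, id, wc = "identity", statistic = "wald",
                     small_sample = FALSE)
  # direct HC0 sandwich on the joint design (sigma cancels between the
  # bread and the meat for singleton subjects under identity)
  fit <- lm(x ~ y)
  e <- residuals(fit)
  D <- cbind(1, y)
  bread <- solve(crossprod(D))
  meat <- crossprod(D * e)
  V <- (bread %*% meat %*% bread)[2, 2]
  expect_equal(f$beta_hat, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(f$V_hat, V, tolerance = 1e-10)
})

test_that("score statistic vanishes when the phenotype is orthogonal", {
  # y orthogonal to the centered response: the score at the null root is 0
  x <- c(1, 2, 3, 4, 5, 6)
  xc <- x - mean(x)
  y0 <- c(1, 0, 1, 0, 1, 0)
  y <- y0 - drop(crossprod(y0, xc)) / drop(crossprod(xc)) * xc
  f <- gee_node_test(x, y, id = 1:6, wc = "identity", statistic = "score",
                     small_sample = FALSE)
  expect_equal(f$T_score, 0, tolerance = 1e-16)
  expect_equal(f$p_score, 1)
})

test_that("statistic is invariant to affine rescaling and relabeling", {
  set.seed(25)
  inst <- random_gee_instance()
  f1 <- gee_node_test(inst$x, inst$y, inst$id, visit = inst$visit,
                      Z = inst$Z, wc = "cs", statistic = "both")
  f2 <- gee_node_test(5 * inst$x - 2, inst$y, inst$id, visit = inst$visit,
                      Z = inst$Z, wc = "cs", statistic = "both")
  expect_equal(f1$T_score, f2$T_score, tolerance = 1e-8)
  expect_equal(f1$T_wald, f2$T_wald, tolerance = 1e-8)
  # relabeling subjects (same blocks, new ids) changes nothing
  relab <- paste0("S", match(inst$id, unique(inst$id)) + 100)
  f3 <- gee_node_test(inst$x, inst$y, relab, visit = inst$visit,
                      Z = inst$Z, wc = "cs", statistic = "both")
  expect_equal(f1$T_score, f3$T_score, tolerance = 1e-12)
})

test_that("degenerate inputs raise informative errors", {
  x <- rnorm(12)
  expect_error(gee_node_test(x, rep(1, 12), rep(1:4, each = 3),
                             statistic = "wald"), "no variance")
  Zbad <- cbind(1, 1)[rep(1, 12), ]
  expect_error(gee_node_test(x, rep(0:1, 6), rep(1:4, each = 3), Z = Zbad),
               "rank deficient")
  expect_error(gee_node_test(x, rep(0:1, 6), rep(1:4, each = 3), wc = "un",
                             visit = c(rep(1:3, 3), 1, 1, 2)),
               "contiguous|balanced|ascending")
})

test_that("score and Wald p-values agree asymptotically", {
  set.seed(26)
  diffs <- replicate(40, {
    N <- 150
    id <- rep(seq_len(N), each = 2)
    y <- rep(rbinom(N, 1, 0.5), each = 2)
    x <- rnorm(2 * N) + rep(rnorm(N, 0, 0.5), each = 2)
    f <- gee_node_test(x, y, id, wc = "cs", statistic = "both")
    abs(f$p_score - f$p_wald)
  })
  expect_lt(median(diffs), 0.01)
})

test_that("tidy and glance summaries carry the fit information", {
  set.seed(27)
  inst <- random_gee_instance()
  f <- gee_node_test(inst$x, inst$y, inst$id, visit = inst$visit,
                     Z = inst$Z, wc = "ar1", statistic = "both")
  td <- tidy(f)
  expect_setequal(td$test, c("score", "wald"))
  expect_true(all(td$p.value > 0 & td$p.value <= 1))
  gl <- glance(f)
  expect_equal(gl$wc, "ar1")
  expect_true(gl$converged)
  expect_equal(gl$n, length(inst$x))
})
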