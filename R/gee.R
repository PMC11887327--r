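# Marginal-model engine: GLS fitting under a working correlation, with the
# small-sample-adjusted generalized score statistic (Boos-type, with
# Mancl-DeRouen leverage inflation of the middle matrix) and the robust Wald
# statistic. Subject blocks are assumed contiguous and visit-ordered; the
# public wrappers take care of ordering.

#' Control parameters for the GEE engine
#'
#' @param tol Convergence tolerance on the coefficients and the working
#'   correlation parameter between iterations.
#' @param max_iter Maximum number of estimation iterations.
#' @export
gee_control <- function(tol = 1e-8, max_iter = 200L) {
  list(tol = tol, max_iter = as.integer(max_iter))
}

# Partition row indices into subject blocks (contiguous, visit-ordered).
make_blocks <- function(id, visit = NULL) {
  n <- length(id)
  f <- factor(id, levels = unique(id))
  idx <- split(seq_len(n), f)
  if (is.null(visit)) {
    vis <- lapply(idx, seq_along)
  } else {
    vis <- split(as.integer(visit), f)
  }
  if (!all(unlist(idx, use.names = FALSE) == seq_len(n))) {
    stop("subject rows must be contiguous", call. = FALSE)
  }
  if (any(vapply(vis, is.unsorted, TRUE))) {
    stop("visits must be ascending within subject", call. = FALSE)
  }
  sizes <- lengths(idx)
  balanced <- length(unique(sizes)) == 1L && sizes[[1L]] >= 1L &&
    all(vapply(vis, identical, TRUE, y = vis[[1L]]))
  list(idx = idx, visit = vis, N = length(idx), n = n, sizes = sizes,
       balanced = balanced, J = if (balanced) sizes[[1L]] else NA_integer_)
}

# Working correlation matrix for one subject's visit vector.
wc_matrix <- function(wc, visit, rho = 0, R = NULL) {
  J <- length(visit)
  switch(wc,
         identity = diag(J),
         cs = { m <- matrix(rho, J, J); diag(m) <- 1; m },
         ar1 = rho ^ abs(outer(visit, visit, "-")),
         un = {
           if (length(visit) != nrow(R)) {
             stop("unstructured working correlation requires balanced data",
                  call. = FALSE)
           }
           R
         })
}

# Moment estimators for the dispersion and correlation parameters from raw
# residuals; q is the number of mean parameters in the fitted model.
estimate_wc <- function(res, blocks, wc, q) {
  sigma <- sum(res^2) / (blocks$n - q)
  if (!is.finite(sigma) || sigma <= 1e-12) {
    stop("response has no residual variance", call. = FALSE)
  }
  e <- res / sqrt(sigma)
  rho <- 0
  R <- NULL
  if (wc == "cs") {
    num <- 0; den <- 0
    for (i in seq_len(blocks$N)) {
      ei <- e[blocks$idx[[i]]]
      Ji <- length(ei)
      if (Ji < 2L) next
      num <- num + (sum(ei)^2 - sum(ei^2))
      den <- den + Ji * (Ji - 1)
    }
    rho <- if (den > 0) num / den else 0
    lo <- -1 / (max(blocks$sizes) - 1) + 1e-6
    rho <- min(max(rho, max(lo, -0.99)), 0.99)
  } else if (wc == "ar1") {
    num <- 0; den <- 0
    for (i in seq_len(blocks$N)) {
      ii <- blocks$idx[[i]]
      if (length(ii) < 2L) next
      vi <- blocks$visit[[i]]
      lag1 <- which(diff(vi) == 1L)
      if (!length(lag1)) next
      num <- num + sum(e[ii[lag1]] * e[ii[lag1 + 1L]])
      den <- den + length(lag1)
    }
    rho <- if (den > 0) num / den else 0
    rho <- min(max(rho, -0.99), 0.99)
  } else if (wc == "un") {
    if (!blocks$balanced) {
      stop("unstructured working correlation requires balanced data",
           call. = FALSE)
    }
    E <- matrix(e, nrow = blocks$J)
    Rhat <- tcrossprod(E) / blocks$N
    R <- stats::cov2cor(Rhat)
    # floor the spectrum: with few subjects (or tie-degenerate responses)
    # the estimated correlation can be near-singular, which blows up the
    # weighted statistic; a 0.05 eigenvalue floor keeps Sigma stably
    # invertible while leaving a well-conditioned estimate untouched
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < 0.05) {
      R <- ev$vectors %*% diag(pmax(ev$values, 0.05)) %*% t(ev$vectors)
      R <- stats::cov2cor(R)
    }
    dimnames(R) <- NULL
  }
  list(sigma = sigma, rho = rho, R = R)
}

# Build an applier v -> Sigma^{-1} v together with per-block inverses.
# D = I by default; visit_var gives a per-visit variance diagonal (balanced
# designs only).
make_sinv <- function(blocks, wc, est, dvar = NULL) {
  if (blocks$balanced) {
    Rb <- wc_matrix(wc, blocks$visit[[1L]], est$rho, est$R)
    if (!is.null(dvar)) {
      hd <- sqrt(dvar)
      Rb <- Rb * tcrossprod(hd)
    }
    Sbi <- solve(est$sigma * Rb)
    J <- blocks$J
    apply_fun <- function(V) {
      V <- as.matrix(V)
      out <- Sbi %*% matrix(V, nrow = J)
      dim(out) <- dim(V)
      out
    }
    block_fun <- function(i) Sbi
  } else {
    Sbis <- lapply(seq_len(blocks$N), function(i) {
      solve(est$sigma * wc_matrix(wc, blocks$visit[[i]], est$rho, est$R))
    })
    apply_fun <- function(V) {
      V <- as.matrix(V)
      out <- V
      for (i in seq_len(blocks$N)) {
        ii <- blocks$idx[[i]]
        out[ii, ] <- Sbis[[i]] %*% V[ii, , drop = FALSE]
      }
      out
    }
    block_fun <- function(i) Sbis[[i]]
  }
  list(apply = apply_fun, block = block_fun)
}

# Iterated GLS: alternate closed-form coefficients with moment re-estimation
# of (sigma, rho) until the coefficients and correlation parameter settle.
gls_fit <- function(X, x, blocks, wc, control = gee_control(),
                    visit_var = FALSE) {
  q <- ncol(X)
  coef <- qr.coef(qr(X), x)
  est <- estimate_wc(x - X %*% coef, blocks, wc, q)
  dvar <- NULL
  if (visit_var) {
    if (!blocks$balanced) {
      stop("per-visit variances require balanced data", call. = FALSE)
    }
    Em <- matrix(as.vector(x - X %*% coef), nrow = blocks$J)
    dvar <- rowMeans(Em^2)
    dvar <- dvar / mean(dvar)
  }
  sinv <- make_sinv(blocks, wc, est, dvar)
  iter <- 1L
  converged <- wc == "identity" && !visit_var
  if (!converged) {
    repeat {
      SX <- sinv$apply(X)
      coef_new <- solve(crossprod(X, SX), crossprod(SX, x))
      res <- x - X %*% coef_new
      est_new <- estimate_wc(res, blocks, wc, q)
      if (visit_var) {
        Em <- matrix(as.vector(res), nrow = blocks$J)
        dvar <- rowMeans(Em^2)
        dvar <- dvar / mean(dvar)
      }
      dpar <- if (wc == "un") {
        max(abs(est_new$R - (est$R %||% est_new$R)))
      } else {
        abs(est_new$rho - est$rho)
      }
      delta <- max(abs(coef_new - coef), dpar)
      coef <- coef_new
      est <- est_new
      sinv <- make_sinv(blocks, wc, est, dvar)
      iter <- iter + 1L
      if (delta < control$tol) { converged <- TRUE; break }
      if (iter >= control$max_iter) break
    }
    if (!converged) {
      stop("GEE estimation did not converge in ", control$max_iter,
           " iterations", call. = FALSE)
    }
    # one last coefficient update so coef is the exact GLS solution at the
    # reported (sigma, rho): downstream statistics are then deterministic
    # functions of (data, parameters)
    SX <- sinv$apply(X)
    coef <- solve(crossprod(X, SX), crossprod(SX, x))
  }
  list(coef = unname(drop(coef)), est = est, sinv = sinv, iter = iter,
       converged = converged, dvar = dvar)
}

# Generalized score statistic at the null fit (beta = 0), with optional
# leverage-based small-sample adjustment of the middle matrix.
gee_score_stat <- function(x, y, Z, blocks, wc, small_sample = TRUE,
                           L = NULL, control = gee_control(),
                           visit_var = FALSE) {
  nullfit <- gls_fit(Z, x, blocks, wc, control, visit_var)
  D <- cbind(Z, y)
  q2 <- ncol(D)
  if (is.null(L)) L <- matrix(c(rep(0, q2 - 1L), 1), nrow = 1L)
  S <- x - Z %*% nullfit$coef
  SinvD <- nullfit$sinv$apply(D)
  SinvS <- nullfit$sinv$apply(S)
  U <- crossprod(D, SinvS)
  H <- crossprod(D, SinvD)
  B <- matrix(0, q2, q2)
  if (small_sample) {
    Hinv <- solve(H)
    K <- (diag(q2) - Hinv %*% t(L) %*% solve(L %*% Hinv %*% t(L), L)) %*% Hinv
    for (i in seq_len(blocks$N)) {
      ii <- blocks$idx[[i]]
      Di <- D[ii, , drop = FALSE]
      ai <- SinvD[ii, , drop = FALSE]
      Pii <- Di %*% K %*% t(ai)
      g <- crossprod(ai, solve(diag(length(ii)) - Pii, S[ii]))
      B <- B + tcrossprod(g)
    }
  } else {
    for (i in seq_len(blocks$N)) {
      ii <- blocks$idx[[i]]
      g <- crossprod(SinvD[ii, , drop = FALSE], S[ii])
      B <- B + tcrossprod(g)
    }
  }
  Cm <- solve(H, t(L))
  mid <- crossprod(Cm, B %*% Cm)
  lu <- crossprod(Cm, U)
  if (nrow(L) == 1L && mid[1L] <= 0) {
    stop("degenerate variance in score statistic", call. = FALSE)
  }
  stat <- drop(crossprod(lu, solve(mid, lu)))
  list(statistic = stat, df = nrow(L),
       p.value = pchisq(stat, df = nrow(L), lower.tail = FALSE),
       alpha = nullfit$coef, U = U, H = H, B = B,
       sigma = nullfit$est$sigma, rho = nullfit$est$rho, R = nullfit$est$R,
       n_iter = nullfit$iter, converged = nullfit$converged)
}

# Robust Wald statistic from the joint (alpha, beta) GLS fit: sandwich
# covariance of the joint coefficients with per-subject inverse-leverage
# inflation of the residuals (Mancl-DeRouen), taking the beta entry.
gee_wald_stat <- function(x, y, Z, blocks, wc, small_sample = TRUE,
                          control = gee_control(), visit_var = FALSE) {
  if (var(y) == 0) stop("phenotype has no variance", call. = FALSE)
  Df <- cbind(Z, y)
  fit <- gls_fit(Df, x, blocks, wc, control, visit_var)
  q <- ncol(Z)
  alpha <- fit$coef[seq_len(q)]
  beta <- fit$coef[q + 1L]
  SinvD <- fit$sinv$apply(Df)
  H <- crossprod(Df, SinvD)
  Hinv <- solve(H)
  e <- x - Df %*% fit$coef
  B <- matrix(0, q + 1L, q + 1L)
  for (i in seq_len(blocks$N)) {
    ii <- blocks$idx[[i]]
    ai <- SinvD[ii, , drop = FALSE]
    if (small_sample) {
      Pii <- Df[ii, , drop = FALSE] %*% Hinv %*% t(ai)
      g <- tryCatch(crossprod(ai, solve(diag(length(ii)) - Pii, e[ii])),
                    error = function(err) {
                      stop("degenerate leverage in the small-sample ",
                           "adjustment (a subject block has leverage one)",
                           call. = FALSE)
                    })
    } else {
      g <- crossprod(ai, e[ii])
    }
    B <- B + tcrossprod(g)
  }
  Vmat <- unname(Hinv %*% B %*% Hinv)
  V <- Vmat[q + 1L, q + 1L]
  if (V <= 0) stop("degenerate variance in Wald statistic", call. = FALSE)
  stat <- beta^2 / V
  list(statistic = stat, df = 1L,
       p.value = pchisq(stat, df = 1L, lower.tail = FALSE),
       alpha = alpha, beta = beta, V = V, B_adj = B, H = H,
       sigma = fit$est$sigma, rho = fit$est$rho, R = fit$est$R,
       n_iter = fit$iter, converged = fit$converged)
}

#' Low-level GEE node test
#'
#' Fits the marginal model \eqn{E(x \mid Z, y) = Z\alpha + y\beta} under a
#' working correlation structure and tests \eqn{H_0: \beta = 0} with the
#' generalized score statistic (evaluated at the null fit) and/or the robust
#' Wald statistic, both with an optional small-sample adjustment that inflates
#' each subject's residual by its inverse leverage before forming the
#' sandwich middle matrix. This is the engine behind [test_genus()]; rows are
#' reordered internally so that subject blocks are contiguous and
#' visit-ordered.
#'
#' @param x Numeric response (a node covariate), one value per sample.
#' @param y Phenotype per sample (0/1 case status or a general exposure).
#' @param id Subject identifier per sample.
#' @param visit Optional integer visit index per sample (1-based); defaults to
#'   the within-subject row order. AR1 correlation decays with the absolute
#'   visit difference.
#' @param Z Covariate design matrix including the intercept; defaults to an
#'   intercept-only column.
#' @param wc Working correlation: `"identity"`, `"cs"` (compound symmetry /
#'   exchangeable), `"ar1"`, or `"un"` (unstructured; balanced data only).
#' @param statistic `"score"`, `"wald"`, or `"both"`.
#' @param small_sample Apply the small-sample leverage adjustment
#'   (default `TRUE`).
#' @param L Optional contrast matrix (rows = constraints) on
#'   \eqn{(\alpha, \beta)} for the score test; defaults to testing the last
#'   coefficient, \eqn{\beta}.
#' @param visit_var Estimate a per-visit variance diagonal (balanced designs
#'   only) instead of the default homoscedastic `D = I`.
#' @param control See [gee_control()].
#' @return An object of class `gee_fit`: a list with the statistics, p-values,
#'   parameter estimates and the intermediate matrices of the score test.
#' @examples
#' set.seed(1)
#' d <- data.frame(id = rep(1:10, each = 3), y = rep(rbinom(10, 1, .5), each = 3))
#' d$x <- rnorm(30) + 0.5 * d$y
#' f <- gee_node_test(d$x, d$y, d$id, wc = "cs")
#' f$p_score
#' @export
gee_node_test <- function(x, y, id, visit = NULL, Z = NULL,
                          wc = c("identity", "cs", "ar1", "un"),
                          statistic = c("both", "score", "wald"),
                          small_sample = TRUE, L = NULL, visit_var = FALSE,
                          control = gee_control()) {
  wc <- match.arg(wc)
  statistic <- match.arg(statistic)
  n <- length(x)
  stopifnot(length(y) == n, length(id) == n)
  if (!is.null(visit)) stopifnot(length(visit) == n)
  ord <- order(match(id, unique(id)),
               if (is.null(visit)) seq_len(n) else visit)
  x <- as.numeric(x)[ord]
  y <- as.numeric(y)[ord]
  if (is.null(Z)) Z <- matrix(1, n, 1L) else {
    Z <- as.matrix(Z)[ord, , drop = FALSE]
  }
  if (qr(Z)$rank < ncol(Z)) stop("Z is rank deficient", call. = FALSE)
  blocks <- make_blocks(id[ord], if (is.null(visit)) NULL else visit[ord])

  out <- list(wc = wc, small_sample = small_sample, n = n,
              n_subjects = blocks$N, statistic = statistic)
  if (statistic %in% c("both", "score")) {
    sc <- gee_score_stat(x, y, Z, blocks, wc, small_sample, L, control,
                         visit_var)
    out$score <- sc
    out$T_score <- sc$statistic
    out$p_score <- sc$p.value
  }
  if (statistic %in% c("both", "wald")) {
    wd <- gee_wald_stat(x, y, Z, blocks, wc, small_sample, control, visit_var)
    out$wald <- wd
    out$T_wald <- wd$statistic
    out$p_wald <- wd$p.value
    out$beta_hat <- wd$beta
    out$V_hat <- wd$V
  }
  structure(out, class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("<gee_fit> wc =", x$wc,
      if (x$small_sample) "(small-sample adjusted)" else "", "\n")
  if (!is.null(x$T_score)) {
    cat(sprintf("  score: T = %.4f, p = %.4g\n", x$T_score, x$p_score))
  }
  if (!is.null(x$T_wald)) {
    cat(sprintf("  wald : T = %.4f, p = %.4g (beta = %.4f)\n",
                x$T_wald, x$p_wald, x$beta_hat))
  }
  invisible(x)
}

#' @rdname gee_node_test
#' @param data A data frame with one row per sample.
#' @param response,phenotype,subject Column names in `data` for the node
#'   covariate, the phenotype and the subject id.
#' @param covariates Character vector of covariate column names (an intercept
#'   is always included).
#' @param ... Passed on to [gee_node_test()].
#' @export
gee_test <- function(data, response, phenotype, subject, visit = NULL,
                     covariates = NULL, ...) {
  stopifnot(is.data.frame(data))
  Z <- cbind(`(Intercept)` = rep(1, nrow(data)))
  if (length(covariates)) {
    Z <- cbind(Z, as.matrix(data[covariates]))
  }
  gee_node_test(data[[response]], data[[phenotype]], data[[subject]],
                visit = if (is.null(visit)) NULL else data[[visit]],
                Z = Z, ...)
}

#' @method tidy gee_fit
#' @export
tidy.gee_fit <- function(x, ...) {
  rows <- list()
  if (!is.null(x$T_score)) {
    rows <- c(rows, list(tibble::tibble(
      term = "phenotype", test = "score", estimate = NA_real_,
      statistic = x$T_score, p.value = x$p_score)))
  }
  if (!is.null(x$T_wald)) {
    rows <- c(rows, list(tibble::tibble(
      term = "phenotype", test = "wald", estimate = x$beta_hat,
      statistic = x$T_wald, p.value = x$p_wald)))
  }
  dplyr::bind_rows(rows)
}

#' @method glance gee_fit
#' @export
glance.gee_fit <- function(x, ...) {
  src <- x$wald %||% x$score
  tibble::tibble(n = x$n, n_subjects = x$n_subjects, wc = x$wc,
                 sigma = src$sigma,
                 rho = if (x$wc %in% c("cs", "ar1")) src$rho else NA_real_,
                 small_sample = x$small_sample,
                 n_iter = src$n_iter, converged = src$converged)
}
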