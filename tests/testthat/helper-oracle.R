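# Independent direct transcription of the marginal-model test statistics,
# written with dense matrices and explicit per-subject sums. Takes the
# working-covariance parameters (sigma, rho or R) as given and rebuilds every
# quantity from the printed formulas; used to cross-check the package engine.

oracle_corr <- function(wc, visit, rho, R) {
  J <- length(visit)
  if (wc == "identity") return(diag(J))
  if (wc == "cs") {
    M <- matrix(rho, J, J); diag(M) <- 1
    return(M)
  }
  if (wc == "ar1") return(rho ^ abs(outer(visit, visit, "-")))
  R
}

# x, y: vectors; Z: matrix; id: subject ids (rows contiguous, visit-ordered);
# params: list(sigma, rho, R) to plug into Sigma_i = sigma * R_i.
oracle_gee <- function(x, y, Z, id, visit = NULL, wc = "identity",
                       params, small_sample = TRUE) {
  n <- length(x)
  idx <- split(seq_len(n), factor(id, levels = unique(id)))
  if (is.null(visit)) visit <- unlist(lapply(idx, seq_along))
  vis <- split(visit, factor(id, levels = unique(id)))
  N <- length(idx)

  Sig <- lapply(seq_len(N), function(i) {
    params$sigma * oracle_corr(wc, vis[[i]], params$rho, params$R)
  })
  Sig_full <- matrix(0, n, n)
  for (i in seq_len(N)) Sig_full[idx[[i]], idx[[i]]] <- Sig[[i]]
  Sinv_full <- solve(Sig_full)

  # null GLS for alpha at beta = 0
  alpha <- solve(t(Z) %*% Sinv_full %*% Z, t(Z) %*% Sinv_full %*% x)
  D <- cbind(Z, y)
  q2 <- ncol(D)
  L <- matrix(c(rep(0, q2 - 1), 1), nrow = 1)
  S <- x - Z %*% alpha

  U <- t(D) %*% Sinv_full %*% S
  H <- matrix(0, q2, q2)
  for (i in seq_len(N)) {
    Di <- D[idx[[i]], , drop = FALSE]
    H <- H + t(Di) %*% solve(Sig[[i]]) %*% Di
  }
  Hinv <- solve(H)

  B <- matrix(0, q2, q2)
  for (i in seq_len(N)) {
    ii <- idx[[i]]
    Di <- D[ii, , drop = FALSE]
    Si <- S[ii]
    Sinv_i <- solve(Sig[[i]])
    if (small_sample) {
      Ptii <- Di %*% (diag(q2) -
                        Hinv %*% t(L) %*% solve(L %*% Hinv %*% t(L)) %*% L) %*%
        Hinv %*% t(Di) %*% Sinv_i
      Ii <- diag(length(ii))
      B <- B + t(Di) %*% Sinv_i %*% solve(Ii - Ptii) %*% Si %*% t(Si) %*%
        solve(Ii - t(Ptii)) %*% Sinv_i %*% Di
    } else {
      Ui <- t(Di) %*% Sinv_i %*% Si
      B <- B + Ui %*% t(Ui)
    }
  }
  T_score <- drop(t(U) %*% Hinv %*% t(L) %*%
                    solve(L %*% Hinv %*% B %*% Hinv %*% t(L)) %*%
                    L %*% Hinv %*% U)

  # Wald path: joint GLS; beta also solves the marginal estimating equation
  # (y' Sigma^-1 y)^-1 y' Sigma^-1 (x - Z alpha_full). Robust covariance is
  # the sandwich on the joint design with inverse-leverage-inflated residuals.
  coef_full <- solve(t(D) %*% Sinv_full %*% D, t(D) %*% Sinv_full %*% x)
  alpha_f <- coef_full[seq_len(q2 - 1)]
  W <- drop(t(y) %*% Sinv_full %*% y)
  beta <- drop(solve(W, t(y) %*% Sinv_full %*% (x - Z %*% alpha_f)))
  stopifnot(abs(beta - coef_full[q2]) < 1e-8) # the two derivations coincide
  efull <- x - D %*% coef_full
  Hf_inv <- solve(t(D) %*% Sinv_full %*% D)
  B_wald <- matrix(0, q2, q2)
  for (i in seq_len(N)) {
    ii <- idx[[i]]
    Di <- D[ii, , drop = FALSE]
    Sinv_i <- solve(Sig[[i]])
    if (small_sample) {
      Pii <- Di %*% Hf_inv %*% t(Di) %*% Sinv_i
      Ii <- diag(length(ii))
      Cov <- solve(Ii - Pii) %*% efull[ii] %*% t(efull[ii]) %*%
        solve(Ii - t(Pii))
      B_wald <- B_wald + t(Di) %*% Sinv_i %*% Cov %*% Sinv_i %*% Di
    } else {
      Ui <- t(Di) %*% Sinv_i %*% efull[ii]
      B_wald <- B_wald + Ui %*% t(Ui)
    }
  }
  V <- (Hf_inv %*% B_wald %*% Hf_inv)[q2, q2]
  list(alpha = drop(alpha), U = U, H = H, B = B, T_score = T_score,
       p_score = pchisq(T_score, 1, lower.tail = FALSE),
       beta = beta, V = V, B_wald = B_wald, T_wald = beta^2 / V,
       p_wald = pchisq(beta^2 / V, 1, lower.tail = FALSE))
}

# Random small GEE instance generator for oracle-equivalence checks.
random_gee_instance <- function(p_extra = 0) {
  N <- sample(6:20, 1)
  sizes <- sample(1:4, N, replace = TRUE)
  id <- rep(seq_len(N), sizes)
  n <- length(id)
  visit <- unlist(lapply(sizes, seq_len))
  Z <- matrix(1, n, 1)
  if (p_extra > 0) Z <- cbind(Z, matrix(rnorm(n * p_extra), n))
  ys <- rbinom(N, 1, 0.5)
  # at least two case and two control subjects (the leverage correction is
  # degenerate when a single subject carries all the phenotype information)
  while (sum(ys) < 2 || sum(1 - ys) < 2) ys <- rbinom(N, 1, 0.5)
  y <- rep(ys, sizes)
  x <- drop(Z %*% rnorm(ncol(Z))) + 0.3 * y +
    rep(rnorm(N, 0, 0.7), sizes) + rnorm(n)
  list(x = x, y = y, Z = Z, id = id, visit = visit, N = N)
}
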