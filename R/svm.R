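# RBF-kernel C-SVM trained by sequential minimal optimization (SMO), with
# Platt-scaled pairwise probabilities coupled into a 3-way posterior.
# Implemented in-package because no SVM library is available in the target
# environment; the algorithm is the standard one (Platt 1998 SMO with the
# |E_i - E_j| second-choice heuristic, fully deterministic), checked in the
# tests on separable and degenerate geometries.

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

# binary SMO on a precomputed kernel; y in {-1, +1}
smo_binary <- function(K, y, C = 1, tol = 1e-3, max_passes = 200) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  for (sweep_i in seq_len(max_passes)) {
    changed <- 0
    for (i in seq_len(n)) {
      Ei <- drop(K[i, ] %*% (alpha * y)) + b - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        E <- drop(K %*% (alpha * y)) + b - y
        j <- which.max(abs(E - Ei))
        if (j == i) j <- if (i == n) 1L else i + 1L
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        alpha[i] <- ai; alpha[j] <- aj
        b <- if (ai > 0 && ai < C) b1
             else if (aj > 0 && aj < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1
      }
    }
    # a full sweep with no update means the KKT conditions hold within tol
    if (changed == 0) break
  }
  list(alpha = alpha, b = b)
}

# Platt sigmoid P(y=1|f) = 1/(1+exp(A f + B)), Newton with backtracking
# (Lin, Lin & Weng 2007), on the training decision values
platt_fit <- function(f, y) {
  t <- ifelse(y > 0, (sum(y > 0) + 1) / (sum(y > 0) + 2),
              1 / (sum(y <= 0) + 2))
  A <- 0; B <- log((sum(y <= 0) + 1) / (sum(y > 0) + 1))
  obj <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  fval <- obj(A, B)
  for (it in 1:100) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    d1 <- t - p
    d2 <- p * (1 - p)
    g <- c(sum(f * d1), sum(d1))
    if (max(abs(g)) < 1e-5) break
    H <- matrix(c(sum(f^2 * d2) + 1e-12, sum(f * d2),
                  sum(f * d2), sum(d2) + 1e-12), 2)
    step <- -solve(H, g)   # Newton descent direction
    stepsize <- 1
    repeat {
      An <- A + stepsize * step[1]; Bn <- B + stepsize * step[2]
      fn <- obj(An, Bn)
      if (fn < fval + 1e-4 * stepsize * sum(g * step)) {
        A <- An; B <- Bn; fval <- fn; break
      }
      stepsize <- stepsize / 2
      if (stepsize < 1e-10) break
    }
    if (stepsize < 1e-10) break
  }
  c(A = A, B = B)
}

platt_prob <- function(ab, f) {
  z <- ab["A"] * f + ab["B"]
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

svm_train_multiclass <- function(X, y, cost = 1, gamma = 1 / ncol(X)) {
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  fits <- lapply(pairs, function(pr) {
    sel <- y %in% pr
    Xi <- X[sel, , drop = FALSE]
    yi <- ifelse(y[sel] == pr[1], 1, -1)
    K <- rbf_kernel(Xi, Xi, gamma)
    sm <- smo_binary(K, yi, C = cost)
    f <- drop(K %*% (sm$alpha * yi)) + sm$b
    list(pair = pr, X = Xi, y = yi, alpha = sm$alpha, b = sm$b,
         platt = platt_fit(f, yi))
  })
  list(fits = fits, gamma = gamma, cost = cost)
}

# pairwise coupling of r_ij into a 3-way posterior
# (Wu, Lin & Weng 2004, method 2)
couple_pairwise <- function(R) {
  k <- nrow(R)
  Q <- matrix(0, k, k)
  for (i in 1:k) {
    for (j in 1:k) {
      if (i == j) Q[i, i] <- sum(R[-i, i]^2)
      else Q[i, j] <- -R[j, i] * R[i, j]
    }
  }
  p <- rep(1 / k, k)
  for (it in 1:200) {
    pQp <- drop(p %*% Q %*% p)
    p_old <- p
    for (i in 1:k) {
      p[i] <- (-sum(Q[i, -i] * p[-i]) + pQp) / Q[i, i]
      p <- p / sum(p)
      pQp <- drop(p %*% Q %*% p)
    }
    if (max(abs(p - p_old)) < 1e-10) break
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

svm_predict_multiclass <- function(model, X) {
  n <- nrow(X)
  scores <- matrix(0, n, 3)
  for (m in seq_len(n)) {
    R <- matrix(0, 3, 3)
    for (fit in model$fits) {
      K <- rbf_kernel(matrix(X[m, ], 1), fit$X, model$gamma)
      f <- drop(K %*% (fit$alpha * fit$y)) + fit$b
      pij <- platt_prob(fit$platt, f)
      pij <- min(max(pij, 1e-7), 1 - 1e-7)
      R[fit$pair[1], fit$pair[2]] <- pij
      R[fit$pair[2], fit$pair[1]] <- 1 - pij
    }
    scores[m, ] <- couple_pairwise(R)
  }
  list(labels = max.col(scores, ties.method = "first"), scores = scores)
}
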