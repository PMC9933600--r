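# Independent oracles used to cross-check the package implementation.
# These deliberately avoid the package's own NIPALS/LOO code paths.

# SIMPLS for a single response (de Jong 1993).  Returns a p x ncomp
# matrix whose column a holds the regression coefficients of the
# a-component model (inputs pre-centered/scaled).
simpls1_coef <- function(X, y, ncomp) {
  X <- as.matrix(X)
  p <- ncol(X)
  R <- matrix(0, p, ncomp)
  V <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  s <- drop(crossprod(X, y))
  for (a in seq_len(ncomp)) {
    r <- s
    t <- drop(X %*% r)
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) {                      # rank exhausted
      ncomp <- a - 1
      R <- R[, seq_len(ncomp), drop = FALSE]
      q <- q[seq_len(ncomp)]
      break
    }
    t <- t / nt
    r <- r / nt
    pa <- drop(crossprod(X, t))
    q[a] <- sum(y * t)
    v <- pa
    if (a > 1) {
      v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        drop(crossprod(V[, 1:(a - 1), drop = FALSE], pa))
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v * sum(v * s)
    R[, a] <- r
    V[, a] <- v
  }
  B <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp))
    B[, a] <- R[, 1:a, drop = FALSE] %*% q[1:a]
  B
}

# Ordinary least squares predictions (no intercept; inputs pre-centered).
ols_pred <- function(Xtrain, y, Xnew) {
  b <- solve(crossprod(Xtrain), crossprod(Xtrain, y))
  drop(Xnew %*% b)
}

# Brute-force leave-one-out on a raw descriptor matrix: each fold refits
# population-SD scaling from scratch, drops columns that lost all
# variance, fits PLS via the SIMPLS oracle, and predicts the held-out row
# at every component count up to ncomp.  Returns the RMSECV per
# component count.
brute_loo_rmsecv <- function(X, y, ncomp) {
  n <- nrow(X)
  press <- matrix(0, n, ncomp)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    M <- X[idx, , drop = FALSE]
    ctr <- colMeans(M)
    scl <- sqrt(colMeans(sweep(M, 2, ctr)^2))
    keep <- scl > 0
    Ms <- scale(M[, keep, drop = FALSE], ctr[keep], scl[keep])
    ym <- mean(y[idx])
    a_max <- min(ncomp, sum(keep))
    if (a_max < 1) {                       # fold lost every column
      press[i, ] <- (y[i] - ym)^2
      next
    }
    B <- simpls1_coef(Ms, y[idx] - ym, a_max)
    a_eff <- ncol(B)
    if (a_eff < 1) {
      press[i, ] <- (y[i] - ym)^2
      next
    }
    xi <- (X[i, keep] - ctr[keep]) / scl[keep]
    pr <- drop(crossprod(B, xi)) + ym
    pr <- pr[pmin(seq_len(ncomp), a_eff)]
    press[i, ] <- (y[i] - pr)^2
  }
  sqrt(colMeans(press))
}

# Exhaustive search over all descriptor subsets of size 1..size_max,
# scoring each subset by the best leave-one-out RMSECV over the candidate
# component counts (the same objective the GA minimizes).
exhaustive_best_subset <- function(table, size_max = 3,
                                   lv_candidates = 1:3) {
  tr <- which(table$split == "T")
  if (!length(tr)) tr <- seq_along(table$ids)
  X <- table$X[tr, , drop = FALSE]
  y <- table$zeta[tr]
  pool <- colnames(X)
  best <- list(fitness = Inf)
  n_eval <- 0L
  for (k in seq_len(size_max)) {
    combos <- utils::combn(length(pool), k)
    for (ci in seq_len(ncol(combos))) {
      sel <- combos[, ci]
      cand <- lv_candidates[lv_candidates <= k]
      rmse <- brute_loo_rmsecv(X[, sel, drop = FALSE], y, max(cand))
      fit <- min(rmse[cand])
      n_eval <- n_eval + 1L
      if (fit < best$fitness)
        best <- list(fitness = fit, descriptors = pool[sel])
    }
  }
  best$n_evaluations <- n_eval
  best
}

# Small random modeling table used across property tests.
random_table <- function(n = 12, p = 5, seed = 1, noise_sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("d", seq_len(p))))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = noise_sd)
  schema <- data.frame(name = colnames(X), block = "core",
                       kind = "continuous")
  pnp_table(X, y, schema, split = rep("T", n))
}

# Synthetic pool with three planted informative descriptors, used for the
# GA-vs-exhaustive and support-recovery checks.  Noise SD is about a tenth
# of the planted signal SD.
planted_pool_spec <- function(seed) {
  synthetic_spec(n_samples = 60, n_core = 10, n_coating = 10,
                 n_corona = 10,
                 coefficients = c(core_01 = 25, coat_01 = -10,
                                  cor_01 = 20),
                 noise_sd = 2.2, offset = -150, seed = seed)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
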