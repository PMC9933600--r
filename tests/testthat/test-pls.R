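scaled_xy <- function(tab) {
  sc <- autoscale_fit(tab)
  tr <- if (any(tab$split == "T")) which(tab$split == "T")
        else seq_along(tab$ids)
  list(X = autoscale_apply(sc, tab)[tr, , drop = FALSE],
       y = tab$zeta[tr] - mean(tab$zeta[tr]))
}

test_that("NIPALS agrees with an independent SIMPLS oracle on random matrices", {
  for (seed in 1:5) {
    tab <- random_table(n = 15, p = 6, seed = seed)
    d <- scaled_xy(tab)
    for (a in 1:3) {
      dec <- nipals_pls1(d$X, d$y, a)
      b_oracle <- simpls1_coef(d$X, d$y, a)[, a]
      expect_equal(drop(d$X %*% dec$coef[, a]), drop(d$X %*% b_oracle),
                   tolerance = 1e-6)
    }
  }
})

test_that("full-rank PLS reproduces ordinary least squares", {
  for (seed in c(2, 9)) {
    tab <- random_table(n = 14, p = 4, seed = seed)
    d <- scaled_xy(tab)
    dec <- nipals_pls1(d$X, d$y, 4)
    expect_equal(drop(d$X %*% dec$coef[, 4]),
                 ols_pred(d$X, d$y, d$X), tolerance = 1e-8)
    # and through the user-facing fit on fresh rows
    fit <- qspr_pls(tab, ncomp = 4)
    expect_equal(unname(fitted(fit)),
                 ols_pred(d$X, d$y, d$X) + mean(tab$zeta),
                 tolerance = 1e-8)
  }
})

test_that("scores are orthogonal and weights unit norm for every fit", {
  for (seed in 1:4) {
    tab <- random_table(n = 12, p = 5, seed = seed)
    d <- scaled_xy(tab)
    dec <- nipals_pls1(d$X, d$y, 3)
    G <- crossprod(dec$scores)
    offdiag <- G - diag(diag(G))
    expect_lt(max(abs(offdiag)), 1e-8 * max(diag(G)))
    expect_equal(unname(colSums(dec$weights^2)), rep(1, 3))
  }
})

test_that("adding a latent vector never increases the training residual sum of squares", {
  tab <- random_table(n = 16, p = 6, seed = 3)
  d <- scaled_xy(tab)
  dec <- nipals_pls1(d$X, d$y, 5)
  rss <- vapply(1:5, function(a)
    sum((d$y - drop(d$X %*% dec$coef[, a]))^2), numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("permuting descriptor columns permutes coefficients identically", {
  tab <- random_table(n = 12, p = 5, seed = 6)
  fit <- qspr_pls(tab, ncomp = 2)
  perm <- c(4, 1, 5, 3, 2)
  tab2 <- subset_descriptors(tab, tab$schema$name[perm])
  fit2 <- qspr_pls(tab2, ncomp = 2)
  expect_equal(fit2$coef_std, fit$coef_std[perm])
})

test_that("a single informative descriptor is fully captured by the first component", {
  set.seed(8)
  n <- 30
  # nearly orthogonal columns: noise descriptors carry almost no signal
  X <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  X <- X + 0.02 * matrix(rnorm(n * 3), n, 3)
  colnames(X) <- c("x1", "x2", "x3")
  sch <- data.frame(name = colnames(X), block = "core",
                    kind = "continuous")
  tab <- pnp_table(X, zeta = 3 * X[, "x1"] + rnorm(n, sd = 1e-4),
                   schema = sch, split = rep("T", n))
  fit <- qspr_pls(tab, ncomp = 2)
  expect_gt(fit$yvar_pct[1], 99.5)
  # single-descriptor model on y = 3 * x_scaled recovers the slope
  tab1 <- subset_descriptors(tab, "x1")
  sc <- autoscale_fit(tab1)
  tab1$zeta <- 3 * autoscale_apply(sc, tab1)[, 1]
  fit1 <- qspr_pls(tab1, ncomp = 1)
  expect_equal(unname(fit1$coef_std), 3, tolerance = 1e-10)
})

test_that("cumulative endpoint variance equals 100 R2 of the training predictions", {
  for (seed in c(1, 7)) {
    tab <- random_table(n = 15, p = 6, seed = seed)
    fit <- qspr_pls(tab, ncomp = 3)
    y <- tab$zeta
    r2 <- 1 - sum((y - predict(fit))^2) / sum((y - mean(y))^2)
    expect_equal(sum(fit$yvar_pct), 100 * r2, tolerance = 1e-8)
  }
})

test_that("explained X-variance percentages are well formed", {
  tab <- pnp20()
  fit <- qspr_pls(tab, ncomp = 3)
  ev <- explained_variance(fit)
  expect_true(all(ev$x_pct >= 0 & ev$x_pct <= 100))
  expect_lte(max(ev$x_cum_pct), 100 + 1e-6)
})

test_that("requesting more components than the rank errors", {
  set.seed(2)
  X <- cbind(a = rnorm(8))
  X <- cbind(X, b = 2 * X[, "a"])   # rank 1
  sch <- data.frame(name = colnames(X), block = "core",
                    kind = "continuous")
  tab <- pnp_table(X, zeta = rnorm(8), schema = sch, split = rep("T", 8))
  expect_error(qspr_pls(tab, ncomp = 2), "rank")
  expect_error(nipals_pls1(scale(X), rep(0, 8), 1), "no variance")
})

test_that("raw-space coefficients and intercept reproduce scaled-space predictions", {
  tab <- pnp20()
  fit <- qspr_pls(tab, ncomp = 2)
  b <- coef(fit, "raw")
  manual <- drop(tab$X %*% b[-1]) + b[["(Intercept)"]]
  expect_equal(unname(manual), unname(predict(fit)), tolerance = 1e-10)
})
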