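test_that("perfect and mean-only predictions bracket the R2 scale", {
  set.seed(5)
  n <- 10
  X <- cbind(x1 = rnorm(n))
  sch <- data.frame(name = "x1", block = "core", kind = "continuous")
  tab <- pnp_table(X, zeta = 5 * X[, 1] + 2, schema = sch,
                   split = rep("T", n))
  fit <- qspr_pls(tab, ncomp = 1)
  st <- fit_statistics(fit)
  expect_equal(st$R2, 1, tolerance = 1e-10)
  expect_equal(st$RMSEC, 0, tolerance = 1e-6)
  # uninformative descriptor: predictions collapse to the mean, R2 = 0
  tab0 <- tab
  tab0$zeta <- c(rep(1, 5), rep(-1, 5))
  tab0$X[, 1] <- rep(c(1, 2), 5)
  fit0 <- qspr_pls(tab0, ncomp = 1)
  expect_lt(abs(fit_statistics(fit0)$R2), 0.35)
  expect_equal(mean(residuals(fit0)), 0, tolerance = 1e-10)
})

test_that("LOO equals a brute-force fold-by-fold oracle", {
  for (seed in c(3, 11)) {
    tab <- random_table(n = 12, p = 5, seed = seed)
    cv <- loo_cv(tab, ncomp = 2)
    oracle <- brute_loo_rmsecv(tab$X, tab$zeta, 2)[2]
    expect_equal(cv$RMSECV, oracle, tolerance = 1e-8)
  }
  # on the benchmark table, including the zero-variance fold drops
  tab <- pnp20()
  tr <- which(tab$split == "T")
  cv <- loo_cv(tab, ncomp = 2)
  oracle <- brute_loo_rmsecv(tab$X[tr, ], tab$zeta[tr], 2)[2]
  expect_equal(cv$RMSECV, oracle, tolerance = 1e-8)
})

test_that("LOO on an exactly linear 1-descriptor toy is error free", {
  sch <- data.frame(name = "x1", block = "core", kind = "continuous")
  tab <- pnp_table(cbind(x1 = c(1, 2, 4)), zeta = c(2, 4, 8),
                   schema = sch, split = rep("T", 3))
  cv <- loo_cv(tab, ncomp = 1)
  expect_equal(cv$RMSECV, 0, tolerance = 1e-8)
})

test_that("LOO records zero-variance drops for the singleton corona bits", {
  cv <- loo_cv(pnp20(), ncomp = 2)
  log5 <- cv$fold_log$dropped[cv$fold_log$structure_id == "5"]
  log7 <- cv$fold_log$dropped[cv$fold_log$structure_id == "7"]
  expect_match(log5, "kininogen-1")
  expect_match(log7, "CC1rs")
  # the fold that cannot see the CC1rs effect misses structure 7 by ~80 mV
  res7 <- cv$predictions$residual[cv$predictions$structure_id == "7"]
  expect_gt(abs(res7), 60)
  expect_true(all(cv$fold_log$dropped[!cv$fold_log$structure_id %in%
                                        c("5", "7")] == ""))
})

test_that("Q2F1 / RMSEP consistency identity holds for arbitrary fits", {
  for (seed in c(2, 8)) {
    set.seed(seed)
    tab <- random_table(n = 18, p = 4, seed = seed)
    tab$split <- rep(c("T", "T", "V"), 6)
    fit <- qspr_pls(tab, ncomp = 2)
    ext <- external_validate(fit)
    nv <- sum(tab$split == "V")
    ss_v <- sum((tab$zeta[tab$split == "V"] - fit$y_mean)^2)
    expect_equal(ext$Q2_ext, 1 - nv * ext$RMSEP^2 / ss_v,
                 tolerance = 1e-10)
  }
})

test_that("benchmark external validation is consistent with hand-computed endpoint sums", {
  # printed endpoints, transcribed directly
  y_train <- c(-70, -60, -30, -30, -20, -15, -10, -5, 5, 5, 10, 15, 45, 50)
  y_valid <- c(-50, -20, -10, -4, 10, 20)
  ybar <- sum(y_train) / 14
  ss_v <- sum((y_valid - ybar)^2)
  fit <- qspr_pls(pnp20(), ncomp = 2)
  ext <- external_validate(fit)
  expect_equal(ext$Q2_ext, 1 - 6 * ext$RMSEP^2 / ss_v, tolerance = 1e-10)
  expect_equal(fit$y_mean, ybar)
})

test_that("validation statistics are invariant to row order", {
  tab <- pnp20()
  perm <- c(20:11, 1:10)
  tab2 <- tab
  tab2$ids <- tab$ids[perm]
  tab2$X <- tab$X[perm, ]
  tab2$zeta <- tab$zeta[perm]
  tab2$split <- tab$split[perm]
  tab2$reference_pred <- tab$reference_pred[perm]
  r1 <- validate_model(qspr_pls(tab, ncomp = 2))
  r2 <- validate_model(qspr_pls(tab2, ncomp = 2))
  for (f in c("R2", "RMSEC", "Q2_cv", "RMSECV", "Q2_ext", "RMSEP"))
    expect_equal(r2[[f]], r1[[f]], tolerance = 1e-10)
})

test_that("LOO with a duplicated sample approaches the calibration statistic", {
  base <- random_table(n = 10, p = 3, seed = 13, noise_sd = 0.5)
  rmsecvs <- sapply(c(1, 6), function(k) {
    X <- rbind(base$X, base$X[rep(1, k - 1), , drop = FALSE])
    y <- c(base$zeta, rep(base$zeta[1], k - 1))
    sch <- base$schema
    tab <- pnp_table(X, y, sch, split = rep("T", nrow(X)))
    abs(loo_cv(tab, ncomp = 2)$RMSECV -
          fit_statistics(qspr_pls(tab, ncomp = 2))$RMSEC)
  })
  expect_lt(rmsecvs[2], rmsecvs[1])
})

test_that("validation report serializes to CSV and JSON", {
  rep <- validate_model(qspr_pls(pnp20(), ncomp = 2))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep, csv, js)
  d <- read.csv(csv)
  expect_equal(nrow(d), 20)
  j <- jsonlite::read_json(js)
  expect_equal(j$RMSECV, rep$RMSECV, tolerance = 1e-12)
})
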