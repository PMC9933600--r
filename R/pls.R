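#' NIPALS PLS1 decomposition of a scaled descriptor matrix
#'
#' Computes a partial least-squares regression with a single response by
#' the NIPALS algorithm with deflation of both `X` and `y` after each
#' component.  For one response the weight vector of each component is
#' `X'y` normalized, so the algorithm is deterministic and needs no
#' iteration or random start.  Inputs are expected already column-scaled
#' (`X`) and mean-centered (`y`); see [qspr_pls()] for the full pipeline.
#'
#' Per-component explained variance of `X` is measured against the
#' Frobenius norm of the input matrix,
#' `100 * ||t_a p_a'||_F^2 / ||X||_F^2`, and of `y` as the drop in residual
#' sum of squares at each component relative to the total sum of squares.
#'
#' @param X numeric matrix (n x p), column-scaled training descriptors.
#' @param y numeric vector of length n, centered response.
#' @param ncomp number of latent vectors A (1 <= A <= rank of `X`).
#' @return a list with components `weights` (p x A, unit-norm columns),
#'   `scores` (n x A, mutually orthogonal), `x_loadings`, `y_loadings`,
#'   `coef` (p x A matrix; column a holds the coefficients of the a-component
#'   model), `xvar_pct`, `yvar_pct` and `ncomp`.
#' @export
nipals_pls1 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(n >= 2, length(y) == n, ncomp >= 1)
  ssy <- sum(y^2)
  if (ssy <= 0) stop("response has no variance")
  ssx <- sum(X^2)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- xvar <- yvar <- numeric(ncomp)
  Xa <- X
  ya <- y
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * sqrt(ssy))
      stop("ncomp = ", ncomp, " exceeds the rank of the descriptor matrix")
    w <- w / nw
    t <- drop(Xa %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24)
      stop("ncomp = ", ncomp, " exceeds the rank of the descriptor matrix")
    pa <- drop(crossprod(Xa, t)) / tt
    qa <- sum(ya * t) / tt
    xvar[a] <- 100 * tt * sum(pa^2) / ssx
    rss0 <- sum(ya^2)
    ya <- ya - t * qa
    yvar[a] <- 100 * (rss0 - sum(ya^2)) / ssy
    Xa <- Xa - tcrossprod(t, pa)
    W[, a] <- w
    P[, a] <- pa
    Tm[, a] <- t
    q[a] <- qa
  }
  coef <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  for (a in seq_len(ncomp)) {
    coef[, a] <- W[, 1:a, drop = FALSE] %*%
      solve(crossprod(P[, 1:a, drop = FALSE], W[, 1:a, drop = FALSE]),
            q[1:a])
  }
  rownames(W) <- rownames(P) <- colnames(X)
  list(weights = W, scores = Tm, x_loadings = P, y_loadings = q,
       coef = coef, xvar_pct = xvar, yvar_pct = yvar, ncomp = ncomp)
}

#' Fit a nano-QSPR PLS model of zeta potential
#'
#' The main fitting function of the package.  Training rows (split label
#' `"T"`, or all rows if no split is assigned) are autoscaled column-wise
#' with [autoscale_fit()]; the endpoint is mean-centered (not
#' variance-scaled), so coefficients in scaled space read as mV per
#' descriptor standard deviation and all RMSE statistics stay in mV.  The
#' scaled system is decomposed by [nipals_pls1()].
#'
#' @param table a [pnp_table()].
#' @param descriptors optional character vector restricting the model to a
#'   descriptor subset (default: all columns).
#' @param ncomp number of latent vectors (default 2).
#' @param sd_denom autoscaling denominator, see [autoscale_fit()].
#' @return an object of class `qspr_pls` with, among others, per-component
#'   weights/scores/loadings, standardized (scaled-space) coefficients,
#'   raw-space coefficients and intercept, per-component explained variance
#'   of X and y, and the scaling parameters used.  Methods:
#'   [predict.qspr_pls()], [coef.qspr_pls()], `print`, `summary`,
#'   `fitted`, `residuals`, [plot.qspr_pls()].
#' @export
#' @examples
#' fit <- qspr_pls(pnp20(), ncomp = 2)
#' fit
#' coef(fit)
qspr_pls <- function(table, descriptors = NULL, ncomp = 2,
                     sd_denom = c("n", "n-1")) {
  sd_denom <- match.arg(sd_denom)
  stopifnot(inherits(table, "pnp_table"))
  if (!is.null(descriptors)) table <- subset_descriptors(table, descriptors)
  tr <- if (any(table$split == "T")) train_rows(table)
        else seq_along(table$ids)
  if (length(tr) < 2) stop("need at least 2 training samples")
  scaler <- autoscale_fit(table, rows = tr, sd_denom = sd_denom)
  if (any(scaler$dropped))
    message("dropping zero-variance descriptor(s): ",
            paste(scaler$names[scaler$dropped], collapse = ", "))
  Xs <- autoscale_apply(scaler, table)
  y_mean <- mean(table$zeta[tr])
  dec <- nipals_pls1(Xs[tr, , drop = FALSE], table$zeta[tr] - y_mean, ncomp)
  b_std <- dec$coef[, ncomp]
  keep <- !scaler$dropped
  b_raw <- b_std / scaler$scale[keep]
  intercept <- y_mean - sum(b_raw * scaler$center[keep])
  fit <- structure(list(
    descriptors = scaler$names[keep],
    ncomp = ncomp,
    scaler = scaler,
    y_mean = y_mean,
    weights = dec$weights,
    scores = dec$scores,
    x_loadings = dec$x_loadings,
    y_loadings = dec$y_loadings,
    coef_std = stats::setNames(b_std, scaler$names[keep]),
    coef_raw = stats::setNames(b_raw, scaler$names[keep]),
    intercept = intercept,
    xvar_pct = dec$xvar_pct,
    yvar_pct = dec$yvar_pct,
    table = table,
    train_rows = tr,
    call = match.call()
  ), class = "qspr_pls")
  fit
}

#' Predict zeta potential from a fitted nano-QSPR model
#'
#' New rows are scaled with the training autoscaling parameters, the
#' scaled-space coefficient vector is applied, and the training endpoint
#' mean is added back, so predictions are in mV.
#'
#' @param object a [qspr_pls()] fit.
#' @param newdata a [pnp_table()], matrix or data frame with the model's
#'   descriptor columns; defaults to the full table the model was built
#'   from (training and validation rows).
#' @param ... unused.
#' @return numeric vector of predicted zeta potentials (mV).
#' @export
predict.qspr_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$table
  Xs <- autoscale_apply(object$scaler, newdata)
  pred <- drop(Xs %*% object$coef_std) + object$y_mean
  if (inherits(newdata, "pnp_table")) names(pred) <- newdata$ids
  pred
}

#' @export
fitted.qspr_pls <- function(object, ...) {
  predict(object)[object$train_rows]
}

#' @export
residuals.qspr_pls <- function(object, ...) {
  object$table$zeta[object$train_rows] - fitted(object)
}

#' Model coefficients in scaled or raw descriptor units
#'
#' @param object a [qspr_pls()] fit.
#' @param type `"standardized"` (mV per descriptor SD, the scaled-space
#'   coefficients; default) or `"raw"` (mV per original descriptor unit,
#'   including an `(Intercept)` term).
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.qspr_pls <- function(object, type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  if (type == "standardized") object$coef_std
  else c("(Intercept)" = object$intercept, object$coef_raw)
}

#' Standardized (scaled-space) model coefficients
#'
#' Coefficients of the model expressed on autoscaled descriptors with a
#' centered endpoint: mV of zeta potential per standard deviation of each
#' descriptor.  Positive values increase the predicted zeta potential.
#'
#' @param model a [qspr_pls()] fit.
#' @return named numeric vector.
#' @export
standardized_coefficients <- function(model) {
  stopifnot(inherits(model, "qspr_pls"))
  model$coef_std
}

#' Per-component explained variance of the descriptor and endpoint blocks
#'
#' @param model a [qspr_pls()] fit.
#' @return data frame with one row per latent vector: percentage of
#'   descriptor-matrix (Frobenius) variance and of centered endpoint
#'   variance captured, plus cumulative columns.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "qspr_pls"))
  data.frame(component = seq_len(model$ncomp),
             x_pct = model$xvar_pct,
             y_pct = model$yvar_pct,
             x_cum_pct = cumsum(model$xvar_pct),
             y_cum_pct = cumsum(model$yvar_pct))
}

#' @export
print.qspr_pls <- function(x, digits = 3, ...) {
  cat("nano-QSPR PLS model: zeta potential (mV) ~ ",
      length(x$descriptors), " descriptors, ", x$ncomp,
      " latent vectors\n", sep = "")
  cat("training samples:", length(x$train_rows), "\n")
  if (!is.null(x$table)) {
    st <- fit_statistics(x)
    cat("R2 =", format(st$R2, digits = digits),
        "  RMSEC =", format(st$RMSEC, digits = digits), "mV\n")
  }
  cat("standardized coefficients (mV per SD):\n")
  print(round(x$coef_std, digits))
  invisible(x)
}

#' @export
summary.qspr_pls <- function(object, ...) {
  out <- list(fit = object,
              statistics = fit_statistics(object),
              variance = explained_variance(object),
              coef_std = object$coef_std,
              coef_raw = coef(object, "raw"))
  class(out) <- "summary.qspr_pls"
  out
}

#' @export
print.summary.qspr_pls <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nexplained variance (%):\n")
  print(round(x$variance, 1), row.names = FALSE)
  cat("\nraw-space equation (mV per descriptor unit):\n")
  print(round(x$coef_raw, digits))
  invisible(x)
}

#' Diagnostic plots for a fitted nano-QSPR model
#'
#' `which = "predictions"` draws observed versus predicted zeta potential
#' for training and validation samples; `which = "williams"` draws the
#' Williams plot (standardized residual against leverage) via
#' [williams_data()].
#'
#' @param x a [qspr_pls()] fit.
#' @param which `"predictions"` or `"williams"`.
#' @param ... passed to the underlying plot.
#' @export
plot.qspr_pls <- function(x, which = c("predictions", "williams"), ...) {
  which <- match.arg(which)
  if (which == "williams") return(plot(williams_data(x), ...))
  obs <- x$table$zeta
  pred <- predict(x)
  is_v <- x$table$split == "V"
  rng <- range(obs, pred)
  graphics::plot(obs, pred, pch = ifelse(is_v, 17, 16),
                 col = ifelse(is_v, "firebrick", "steelblue"),
                 xlim = rng, ylim = rng,
                 xlab = "observed zeta potential (mV)",
                 ylab = "predicted zeta potential (mV)", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", pch = c(16, 17),
                   col = c("steelblue", "firebrick"),
                   legend = c("training", "validation"), bty = "n")
  invisible(x)
}
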