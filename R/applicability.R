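#' Leverage of samples relative to the training descriptor space
#'
#' Leverage measures the distance of a sample from the centroid of the
#' training data in the space the model actually regresses on.  Two
#' conventions are provided:
#'
#' * `"score"` (default): the hat diagonal in the latent-vector space,
#'   `h_i = t_i' (T'T)^-1 t_i`, where `T` are the training scores and `t_i`
#'   the sample's projected scores.  This is the leverage a PLS model uses
#'   for its own predictions; over the training rows the leverages sum to
#'   the number of components.
#' * `"descriptor"`: the hat diagonal on the autoscaled descriptors,
#'   `h_i = x_i' (X'X)^-1 x_i`; training leverages sum to the number of
#'   retained descriptors, and the value is invariant to any invertible
#'   linear reparameterization of the descriptor columns.
#'
#' @param model a [qspr_pls()] fit.
#' @param newdata rows to evaluate (default: the model's full table).
#' @param space `"score"` or `"descriptor"`.
#' @return numeric vector of leverages.
#' @export
leverage <- function(model, newdata = NULL,
                     space = c("score", "descriptor")) {
  space <- match.arg(space)
  stopifnot(inherits(model, "qspr_pls"))
  if (is.null(newdata)) newdata <- model$table
  Xs <- autoscale_apply(model$scaler, newdata)
  if (space == "descriptor") {
    Xtr <- autoscale_apply(model$scaler,
                           model$table)[model$train_rows, , drop = FALSE]
    G <- crossprod(Xtr)
    Gi <- tryCatch(solve(G), error = function(e) {
      warning("X'X is singular; using the pseudo-inverse")
      s <- svd(G)
      pos <- s$d > max(s$d) * 1e-10
      s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    })
    h <- rowSums((Xs %*% Gi) * Xs)
  } else {
    R <- model$weights %*% solve(crossprod(model$x_loadings, model$weights))
    Tnew <- Xs %*% R
    Gi <- solve(crossprod(model$scores))
    h <- rowSums((Tnew %*% Gi) * Tnew)
  }
  if (inherits(newdata, "pnp_table")) names(h) <- newdata$ids
  h
}

#' Critical leverage threshold h* = 3 p / n
#'
#' @param p number of model variables.  Under the default convention
#'   (`"p"`) pass the descriptor count; `"p+1"` adds one for the intercept
#'   term before multiplying.
#' @param n number of training samples.
#' @param convention `"p"` (default) or `"p+1"`.
#' @return the scalar threshold `3 * p / n` (or `3 * (p + 1) / n`).
#' @export
#' @examples
#' critical_leverage(5, 14)          # 1.0714
#' critical_leverage(5, 14, "p+1")   # 1.2857
critical_leverage <- function(p, n, convention = c("p", "p+1")) {
  convention <- match.arg(convention)
  stopifnot(p >= 1, n >= 1)
  if (convention == "p+1") p <- p + 1
  3 * p / n
}

#' Williams-plot data: applicability domain of a nano-QSPR model
#'
#' Assembles per-sample leverage and standardized residuals together with
#' the critical leverage `h*` and in/out-of-domain flags.  The
#' standardized residual divides each raw residual by the RMSE of the
#' sample's own partition (RMSEC for training rows, RMSEP for validation
#' rows) or by the pooled RMSE over all rows; a sample is an outlier when
#' its absolute standardized residual exceeds 3, and flagged high-leverage
#' when `h > h*`.
#'
#' @param model a [qspr_pls()] fit.
#' @param table rows to assess (default: the model's full table).
#' @param space leverage convention, see [leverage()].
#' @param convention `h*` convention, see [critical_leverage()].
#' @param residual_scale `"partition"` (default) or `"pooled"`.
#' @return a data frame of class `qspr_ad` with columns `structure_id`,
#'   `split`, `leverage`, `std_residual`, `h_star`, `high_leverage`,
#'   `outlier`, `in_domain`.
#' @export
#' @examples
#' ad <- williams_data(qspr_pls(pnp20(), ncomp = 2))
#' subset(ad, !in_domain)
williams_data <- function(model, table = NULL,
                          space = c("score", "descriptor"),
                          convention = c("p", "p+1"),
                          residual_scale = c("partition", "pooled")) {
  residual_scale <- match.arg(residual_scale)
  stopifnot(inherits(model, "qspr_pls"))
  if (is.null(table)) table <- model$table
  h <- leverage(model, table, space = space)
  pred <- predict(model, table)
  res <- table$zeta - pred
  rmsec <- fit_statistics(model)$RMSEC
  va <- validation_rows(model$table)
  rmsep <- if (length(va)) external_validate(model)$RMSEP else rmsec
  s <- if (residual_scale == "pooled") {
    rep(sqrt(mean((model$table$zeta - predict(model))^2)), length(res))
  } else {
    ifelse(table$split == "V", rmsep, rmsec)
  }
  h_star <- critical_leverage(length(model$descriptors),
                              length(model$train_rows),
                              convention = convention)
  out <- data.frame(structure_id = table$ids,
                    split = table$split,
                    leverage = unname(h),
                    std_residual = res / s,
                    h_star = h_star)
  out$high_leverage <- out$leverage > h_star
  out$outlier <- abs(out$std_residual) > 3
  out$in_domain <- !out$high_leverage & !out$outlier
  class(out) <- c("qspr_ad", "data.frame")
  out
}

#' @export
print.qspr_ad <- function(x, digits = 3, ...) {
  cat("applicability domain (Williams plot data), h* =",
      format(x$h_star[1], digits = digits), "\n")
  cat(sum(!x$in_domain), "of", nrow(x), "samples outside the domain\n")
  print(data.frame(structure_id = x$structure_id, split = x$split,
                   leverage = round(x$leverage, digits),
                   std_residual = round(x$std_residual, digits),
                   in_domain = x$in_domain), row.names = FALSE)
  invisible(x)
}

#' Draw a Williams plot
#'
#' @param x a [williams_data()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.qspr_ad <- function(x, ...) {
  is_v <- x$split == "V"
  graphics::plot(x$leverage, x$std_residual,
                 pch = ifelse(is_v, 17, 16),
                 col = ifelse(is_v, "firebrick", "steelblue"),
                 xlim = c(0, max(x$leverage, x$h_star) * 1.05),
                 ylim = range(-3.5, 3.5, x$std_residual),
                 xlab = "leverage h", ylab = "standardized residual", ...)
  graphics::abline(h = c(-3, 3), lty = 2)
  graphics::abline(v = x$h_star[1], lty = 2)
  graphics::legend("topright", pch = c(16, 17),
                   col = c("steelblue", "firebrick"),
                   legend = c("training", "validation"), bty = "n")
  invisible(x)
}
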