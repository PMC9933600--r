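#' Fit autoscaling parameters on the training rows
#'
#' Autoscaling (column-wise standardization) is fitted on the training rows
#' only and then applied to every partition, so validation samples are
#' expressed in training-set units.  Columns with zero variance on the
#' fitting rows are flagged and silently dropped when the scaler is
#' applied: a constant column carries no information for the model, and
#' inside leave-one-out folds a fingerprint bit present in exactly one
#' training sample becomes constant when that sample is held out.
#'
#' The default standard deviation uses the population (n) denominator,
#' which is the convention under which the package's standardized
#' coefficients are expressed; the sample (n-1) denominator is available
#' via `sd_denom = "n-1"`.
#'
#' @param x a [pnp_table()] or a numeric matrix.
#' @param rows integer row indices to fit on; defaults to the training rows
#'   of a `pnp_table` (or all rows of a matrix).
#' @param sd_denom `"n"` (population, default) or `"n-1"` (sample).
#' @return an object of class `autoscaler` with fields `center`, `scale`,
#'   `dropped` (logical flags for zero-variance columns) and `sd_denom`.
#' @seealso [autoscale_apply()], [autoscale_invert()]
#' @export
autoscale_fit <- function(x, rows = NULL, sd_denom = c("n", "n-1")) {
  sd_denom <- match.arg(sd_denom)
  X <- if (inherits(x, "pnp_table")) x$X else as.matrix(x)
  if (is.null(rows)) {
    rows <- if (inherits(x, "pnp_table") && any(x$split == "T"))
      train_rows(x) else seq_len(nrow(X))
  }
  if (length(rows) < 2) stop("need at least 2 rows to fit the autoscaler")
  M <- X[rows, , drop = FALSE]
  ctr <- colMeans(M)
  ss <- colSums(sweep(M, 2, ctr)^2)
  denom <- if (sd_denom == "n") length(rows) else length(rows) - 1
  scl <- sqrt(ss / denom)
  structure(list(center = ctr, scale = scl, dropped = scl <= 0,
                 names = colnames(X), sd_denom = sd_denom,
                 n_fit = length(rows)),
            class = "autoscaler")
}

#' Apply (or invert) fitted autoscaling parameters
#'
#' `autoscale_apply()` transforms retained columns to
#' `(x - center) / scale` using the training parameters and removes the
#' flagged zero-variance columns; `autoscale_invert()` maps a scaled matrix
#' of retained columns back to original units.
#'
#' @param params an [autoscale_fit()] result.
#' @param x a [pnp_table()], matrix or data frame with the fitted columns.
#' @return a numeric matrix of the retained, scaled columns.
#' @export
autoscale_apply <- function(params, x) {
  stopifnot(inherits(params, "autoscaler"))
  X <- if (inherits(x, "pnp_table")) x$X else as.matrix(x)
  miss <- setdiff(params$names, colnames(X))
  if (length(miss))
    stop("column(s) missing from table: ", paste(miss, collapse = ", "))
  X <- X[, params$names, drop = FALSE]
  keep <- !params$dropped
  scale(X[, keep, drop = FALSE],
        center = params$center[keep], scale = params$scale[keep])[, ,
                                                                  drop = FALSE]
}

#' @param scaled a matrix produced by `autoscale_apply()`.
#' @rdname autoscale_apply
#' @export
autoscale_invert <- function(params, scaled) {
  stopifnot(inherits(params, "autoscaler"))
  keep <- !params$dropped
  sweep(sweep(as.matrix(scaled), 2, params$scale[keep], `*`),
        2, params$center[keep], `+`)
}

#' @export
print.autoscaler <- function(x, ...) {
  cat("autoscaler over", x$n_fit, "rows (sd denominator:", x$sd_denom,
      ")\n")
  if (any(x$dropped))
    cat("zero-variance columns dropped:",
        paste(x$names[x$dropped], collapse = ", "), "\n")
  invisible(x)
}
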