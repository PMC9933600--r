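#' Goodness-of-fit statistics of a fitted model
#'
#' @param model a [qspr_pls()] fit.
#' @return list with `R2 = 1 - SS_res/SS_tot` over the training rows and
#'   `RMSEC = sqrt(mean(residual^2))` in mV.
#' @export
fit_statistics <- function(model) {
  stopifnot(inherits(model, "qspr_pls"))
  y <- model$table$zeta[model$train_rows]
  res <- y - fitted(model)
  list(R2 = 1 - sum(res^2) / sum((y - model$y_mean)^2),
       RMSEC = sqrt(mean(res^2)))
}

# Leave-one-out engine on raw matrices.  For each held-out training row the
# autoscaler is refitted on the remaining rows (columns that become
# constant in the fold are dropped), the fold is decomposed by NIPALS up to
# ncomp components (capped at the usable fold rank), and the held-out row
# is predicted at every component count at once.  Returns an n x ncomp
# prediction matrix plus a per-fold log of dropped columns and the
# component cap actually used.
loo_engine <- function(X, y, ncomp, sd_denom = "n") {
  n <- nrow(X)
  pred <- matrix(NA_real_, n, ncomp)
  drops <- vector("list", n)
  ncomp_used <- integer(n)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    M <- X[idx, , drop = FALSE]
    ctr <- colMeans(M)
    ss <- colSums(sweep(M, 2, ctr)^2)
    denom <- if (sd_denom == "n") length(idx) else length(idx) - 1
    scl <- sqrt(ss / denom)
    keep <- scl > 0
    drops[[i]] <- colnames(X)[!keep]
    a_max <- min(ncomp, sum(keep))
    Xf <- scale(M[, keep, drop = FALSE], ctr[keep], scl[keep])
    ym <- mean(y[idx])
    dec <- NULL
    while (a_max >= 1) {
      dec <- tryCatch(nipals_pls1(Xf, y[idx] - ym, a_max),
                      error = function(e) NULL)
      if (!is.null(dec)) break
      a_max <- a_max - 1
    }
    if (is.null(dec)) {
      pred[i, ] <- ym          # degenerate fold: mean-only prediction
      ncomp_used[i] <- 0L
      next
    }
    ncomp_used[i] <- a_max
    xi <- (X[i, keep] - ctr[keep]) / scl[keep]
    pa <- drop(crossprod(dec$coef, xi)) + ym
    pred[i, ] <- pa[pmin(seq_len(ncomp), a_max)]
  }
  list(pred = pred, drops = drops, ncomp_used = ncomp_used)
}

#' Leave-one-out cross-validation of a descriptor subset
#'
#' For every training sample in turn, the autoscaler and the PLS model are
#' refitted from scratch on the remaining training samples and the held-out
#' sample is predicted.  Descriptors with zero variance inside a fold (for
#' example a corona fingerprint bit carried by the held-out sample alone)
#' are dropped for that fold, and if the usable rank of a fold falls below
#' `ncomp` the component count is reduced for that fold.  Both events are
#' recorded in the returned fold log: on sparse fingerprints this honest
#' refitting is exactly what makes RMSECV much larger than the calibration
#' or external prediction error.
#'
#' @param table a [pnp_table()].
#' @param descriptors optional descriptor subset (default: all).
#' @param ncomp number of latent vectors.
#' @param sd_denom autoscaling denominator, see [autoscale_fit()].
#' @param reference mean used in the Q2 denominator: the full-training
#'   endpoint mean (`"training"`, default) or each fold's own mean
#'   (`"fold"`).
#' @return list of class `qspr_loo`: `Q2_cv`, `RMSECV` (mV), a per-sample
#'   data frame `predictions`, and `fold_log` describing dropped columns
#'   and per-fold component counts.
#' @export
loo_cv <- function(table, descriptors = NULL, ncomp = 2,
                   sd_denom = c("n", "n-1"),
                   reference = c("training", "fold")) {
  sd_denom <- match.arg(sd_denom)
  reference <- match.arg(reference)
  stopifnot(inherits(table, "pnp_table"))
  if (!is.null(descriptors)) table <- subset_descriptors(table, descriptors)
  tr <- if (any(table$split == "T")) train_rows(table)
        else seq_along(table$ids)
  if (length(tr) < 3) stop("need at least 3 training samples for LOO")
  X <- table$X[tr, , drop = FALSE]
  y <- table$zeta[tr]
  eng <- loo_engine(X, y, ncomp, sd_denom)
  pred <- eng$pred[, ncomp]
  press <- sum((y - pred)^2)
  ref_ss <- if (reference == "training") {
    sum((y - mean(y))^2)
  } else {
    n <- length(y)
    sum((y - (n * mean(y) - y) / (n - 1))^2)
  }
  folds <- data.frame(structure_id = table$ids[tr],
                      ncomp_used = eng$ncomp_used,
                      dropped = vapply(eng$drops, function(d)
                        paste(d, collapse = ";"), character(1)))
  structure(list(
    Q2_cv = 1 - press / ref_ss,
    RMSECV = sqrt(press / length(y)),
    predictions = data.frame(structure_id = table$ids[tr], observed = y,
                             predicted = pred, residual = y - pred),
    fold_log = folds,
    ncomp = ncomp
  ), class = "qspr_loo")
}

#' @export
print.qspr_loo <- function(x, digits = 4, ...) {
  cat("leave-one-out cross-validation (", nrow(x$predictions),
      " folds, ", x$ncomp, " LV)\n", sep = "")
  cat("Q2_cv =", format(x$Q2_cv, digits = digits),
      "  RMSECV =", format(x$RMSECV, digits = digits), "mV\n")
  dropped <- x$fold_log[x$fold_log$dropped != "", ]
  if (nrow(dropped)) {
    cat("folds with zero-variance descriptor drops:\n")
    for (i in seq_len(nrow(dropped)))
      cat("  holding out ", dropped$structure_id[i], ": dropped ",
          dropped$dropped[i], "\n", sep = "")
  }
  invisible(x)
}

#' External validation of a fitted model
#'
#' Computes `RMSEP` and the external validation coefficient
#' `Q2_ext = 1 - sum((y - yhat)^2) / sum((y - mean(y_train))^2)` over the
#' validation rows.  The reference mean is the training endpoint mean
#' (the Q2-F1 convention), which ties `Q2_ext` and `RMSEP` together through
#' `Q2_ext = 1 - n_V * RMSEP^2 / sum_V (y - mean(y_train))^2`.
#'
#' @param model a [qspr_pls()] fit.
#' @param table table holding the validation rows (split `"V"`); defaults
#'   to the table the model was fitted from.
#' @return list with `Q2_ext`, `RMSEP` (mV) and a per-sample data frame.
#' @export
external_validate <- function(model, table = NULL) {
  stopifnot(inherits(model, "qspr_pls"))
  if (is.null(table)) table <- model$table
  va <- validation_rows(table)
  if (!length(va)) stop("table has no validation rows")
  y <- table$zeta[va]
  pred <- predict(model, table)[va]
  sse <- sum((y - pred)^2)
  list(Q2_ext = 1 - sse / sum((y - model$y_mean)^2),
       RMSEP = sqrt(sse / length(y)),
       predictions = data.frame(structure_id = table$ids[va], observed = y,
                                predicted = pred, residual = y - pred))
}

#' Full validation battery for a nano-QSPR model
#'
#' Bundles goodness of fit (R2, RMSEC), leave-one-out cross-validation
#' (Q2_cv, RMSECV) with per-fold rescaling, and external validation
#' (Q2_ext, RMSEP) into a single report with per-sample predictions for
#' all three exercises.
#'
#' @param model a [qspr_pls()] fit.
#' @param sd_denom,reference passed to [loo_cv()].
#' @return object of class `qspr_validation`; see [as.data.frame.qspr_validation()]
#'   and [write_validation_report()] for export.
#' @export
#' @examples
#' rep <- validate_model(qspr_pls(pnp20(), ncomp = 2))
#' rep
validate_model <- function(model, sd_denom = NULL, reference = "training") {
  stopifnot(inherits(model, "qspr_pls"))
  if (is.null(sd_denom)) sd_denom <- model$scaler$sd_denom
  fitst <- fit_statistics(model)
  loo <- loo_cv(model$table, descriptors = model$scaler$names,
                ncomp = model$ncomp, sd_denom = sd_denom,
                reference = reference)
  ext <- if (length(validation_rows(model$table)))
    external_validate(model) else NULL
  tr <- model$train_rows
  per_sample <- data.frame(
    structure_id = model$table$ids,
    split = model$table$split,
    observed = model$table$zeta,
    predicted = predict(model),
    row.names = NULL)
  per_sample$residual <- per_sample$observed - per_sample$predicted
  per_sample$loo_predicted <- NA_real_
  per_sample$loo_predicted[tr] <- loo$predictions$predicted
  structure(list(
    R2 = fitst$R2, RMSEC = fitst$RMSEC,
    Q2_cv = loo$Q2_cv, RMSECV = loo$RMSECV,
    Q2_ext = if (is.null(ext)) NA_real_ else ext$Q2_ext,
    RMSEP = if (is.null(ext)) NA_real_ else ext$RMSEP,
    per_sample = per_sample,
    fold_log = loo$fold_log,
    ncomp = model$ncomp
  ), class = "qspr_validation")
}

#' @export
print.qspr_validation <- function(x, digits = 4, ...) {
  cat("nano-QSPR validation report (", x$ncomp, " LV)\n", sep = "")
  cat("  calibration:        R2 =", format(x$R2, digits = digits),
      "  RMSEC =", format(x$RMSEC, digits = digits), "mV\n")
  cat("  leave-one-out:    Q2_cv =", format(x$Q2_cv, digits = digits),
      "  RMSECV =", format(x$RMSECV, digits = digits), "mV\n")
  if (!is.na(x$Q2_ext))
    cat("  external:        Q2_ext =", format(x$Q2_ext, digits = digits),
        "  RMSEP =", format(x$RMSEP, digits = digits), "mV\n")
  dropped <- x$fold_log[x$fold_log$dropped != "", ]
  if (nrow(dropped)) {
    cat("note: RMSECV includes folds in which descriptors lost all",
        "variance and were dropped\n")
    cat("      (a fingerprint bit carried by a single training sample",
        "cannot be learned\n       when that sample is held out):\n")
    for (i in seq_len(nrow(dropped)))
      cat("      holding out ", dropped$structure_id[i], " dropped: ",
          dropped$dropped[i], "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.qspr_validation <- function(x, ...) x$per_sample

#' Write a validation report to CSV (per sample) and JSON (summary)
#'
#' @param report a [validate_model()] result.
#' @param csv_path path for the per-sample CSV, or `NULL` to skip.
#' @param json_path path for the JSON summary, or `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_validation_report <- function(report, csv_path = NULL,
                                    json_path = NULL) {
  stopifnot(inherits(report, "qspr_validation"))
  if (!is.null(csv_path))
    utils::write.csv(report$per_sample, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(R2 = report$R2, RMSEC = report$RMSEC, Q2_cv = report$Q2_cv,
           RMSECV = report$RMSECV, Q2_ext = report$Q2_ext,
           RMSEP = report$RMSEP, ncomp = report$ncomp,
           fold_log = report$fold_log),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
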