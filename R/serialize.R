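#' Serialize a fitted model to JSON / restore it
#'
#' Writes the complete fitted state — scaling parameters, per-component
#' weights, scores and loadings, coefficients in scaled and raw space,
#' explained variance and metadata — as a plain-text JSON document with
#' full (17 significant digit) precision, so that a restored model
#' reproduces predictions exactly.  The training table itself is not
#' embedded; a restored model predicts from matrices or tables supplied
#' by the caller.
#'
#' @param model a [qspr_pls()] fit.
#' @param path JSON file path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `qspr_pls` object (without the original
#'   training table attached).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "qspr_pls"))
  payload <- list(
    package = "nanoqspr",
    class = "qspr_pls",
    descriptors = model$descriptors,
    ncomp = model$ncomp,
    scaler = list(center = as.list(model$scaler$center),
                  scale = as.list(model$scaler$scale),
                  dropped = model$scaler$dropped,
                  names = model$scaler$names,
                  sd_denom = model$scaler$sd_denom,
                  n_fit = model$scaler$n_fit),
    y_mean = model$y_mean,
    weights = model$weights,
    scores = model$scores,
    x_loadings = model$x_loadings,
    y_loadings = model$y_loadings,
    coef_std = as.list(model$coef_std),
    coef_raw = as.list(model$coef_raw),
    intercept = model$intercept,
    xvar_pct = model$xvar_pct,
    yvar_pct = model$yvar_pct,
    n_train = length(model$train_rows)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$class, "qspr_pls"))
    stop("not a serialized qspr_pls model: ", path)
  sc <- structure(list(center = unlist(p$scaler$center),
                       scale = unlist(p$scaler$scale),
                       dropped = p$scaler$dropped,
                       names = p$scaler$names,
                       sd_denom = p$scaler$sd_denom,
                       n_fit = p$scaler$n_fit),
                  class = "autoscaler")
  as_mat <- function(m, rn) {
    m <- as.matrix(m)
    rownames(m) <- rn
    m
  }
  structure(list(
    descriptors = p$descriptors,
    ncomp = p$ncomp,
    scaler = sc,
    y_mean = p$y_mean,
    weights = as_mat(p$weights, p$descriptors),
    scores = as.matrix(p$scores),
    x_loadings = as_mat(p$x_loadings, p$descriptors),
    y_loadings = p$y_loadings,
    coef_std = unlist(p$coef_std),
    coef_raw = unlist(p$coef_raw),
    intercept = p$intercept,
    xvar_pct = p$xvar_pct,
    yvar_pct = p$yvar_pct,
    table = NULL,
    train_rows = seq_len(p$n_train),
    call = NULL
  ), class = "qspr_pls")
}
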