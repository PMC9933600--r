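#' Compare nested descriptor domains: core, core+coating, core+coating+corona
#'
#' Fits a PLS model on each of the three nested descriptor pools and
#' reports its calibration error (RMSEC) and leave-one-out error (RMSECV),
#' quantifying how much the coating and protein-corona blocks add beyond
#' the bare core description.  Descriptors for each pool are either used
#' in full (default) or selected by a GA run restricted to the pool.
#'
#' @param table a [pnp_table()] with block-tagged descriptors.
#' @param ncomp requested latent-vector count; capped at the usable rank
#'   of each pool.
#' @param ga optional [ga_control()]; when given, [ga_select()] picks the
#'   descriptors (and component count) within each pool.
#' @param sd_denom see [autoscale_fit()].
#' @return a data frame of class `qspr_domains` with one row per non-empty
#'   domain: `domain`, `n_descriptors`, `descriptors`, `ncomp`, `RMSEC`,
#'   `RMSECV`.
#' @export
#' @examples
#' compare_domains(pnp20(), ncomp = 2)
compare_domains <- function(table, ncomp = 2, ga = NULL,
                            sd_denom = c("n", "n-1")) {
  sd_denom <- match.arg(sd_denom)
  stopifnot(inherits(table, "pnp_table"))
  pools <- list(
    core = c("core"),
    `core+coating` = c("core", "coating"),
    `core+coating+corona` = c("core", "coating", "corona")
  )
  rows <- list()
  for (nm in names(pools)) {
    pool <- table$schema$name[table$schema$block %in% pools[[nm]]]
    if (!any(table$schema$block %in% utils::tail(pools[[nm]], 1))) {
      warning("domain '", nm, "' skipped: no '",
              utils::tail(pools[[nm]], 1), "' descriptors in the table")
      next
    }
    if (!length(pool)) next
    if (!is.null(ga)) {
      ga_pool <- ga
      ga_pool$size_min <- min(ga$size_min, length(pool))
      if (!is.null(ga$size_max))
        ga_pool$size_max <- min(ga$size_max, length(pool))
      res <- ga_select(table, pool = pool, control = ga_pool)
      sel <- res$descriptors
      a <- res$ncomp
    } else {
      sel <- pool
      sub <- subset_descriptors(table, sel)
      tr <- if (any(sub$split == "T")) train_rows(sub)
            else seq_along(sub$ids)
      scaler <- autoscale_fit(sub, rows = tr, sd_denom = sd_denom)
      a <- max(1L, min(ncomp, sum(!scaler$dropped), length(tr) - 1L))
    }
    fit <- suppressMessages(qspr_pls(table, sel, a, sd_denom = sd_denom))
    st <- fit_statistics(fit)
    cv <- loo_cv(table, sel, a, sd_denom = sd_denom)
    rows[[nm]] <- data.frame(domain = nm, n_descriptors = length(sel),
                             descriptors = paste(sel, collapse = ";"),
                             ncomp = a, RMSEC = st$RMSEC,
                             RMSECV = cv$RMSECV)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qspr_domains", "data.frame")
  out
}

#' @export
print.qspr_domains <- function(x, digits = 3, ...) {
  cat("descriptor-domain comparison (RMSE in mV):\n")
  d <- data.frame(domain = x$domain, n = x$n_descriptors, ncomp = x$ncomp,
                  RMSEC = round(x$RMSEC, digits),
                  RMSECV = round(x$RMSECV, digits))
  print(d, row.names = FALSE)
  invisible(x)
}
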