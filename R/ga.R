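#' Genetic-algorithm settings for descriptor selection
#'
#' The search runs a standard generational GA over bit-vector chromosomes
#' (one bit per descriptor in the pool): tournament selection, uniform
#' crossover, independent per-bit mutation, elitism, and a repair step that
#' randomly flips bits until the subset size lies inside
#' `[size_min, size_max]`.  For every chromosome the component count is
#' chosen as the best-scoring member of `lv_candidates` (capped at the
#' subset size), so descriptor subset and model dimensionality are searched
#' jointly.
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param p_crossover probability of uniform crossover per mating pair.
#' @param p_mutation per-bit mutation probability; default `2 / pool size`
#'   (set at run time when `NULL`).
#' @param elitism number of best chromosomes copied unchanged.
#' @param tournament tournament size for selection.
#' @param size_min,size_max allowed subset sizes (`size_max = NULL` means
#'   the pool size).
#' @param lv_candidates candidate latent-vector counts.
#' @param fitness `"rmsecv"` (leave-one-out RMSE, minimized; default) or
#'   `"r2"` (training R2, maximized).
#' @param seed integer RNG seed; the run is fully reproducible given the
#'   seed.
#' @return a list of class `ga_control`.
#' @export
ga_control <- function(pop_size = 50, generations = 100,
                       p_crossover = 0.8, p_mutation = NULL, elitism = 2,
                       tournament = 3, size_min = 1, size_max = NULL,
                       lv_candidates = 1:3,
                       fitness = c("rmsecv", "r2"), seed = 1) {
  fitness <- match.arg(fitness)
  stopifnot(p_crossover >= 0, p_crossover <= 1,
            is.null(p_mutation) || (p_mutation >= 0 && p_mutation <= 1),
            size_min >= 1, elitism >= 0, pop_size >= 2)
  structure(list(pop_size = pop_size, generations = generations,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 elitism = elitism, tournament = tournament,
                 size_min = size_min, size_max = size_max,
                 lv_candidates = sort(unique(as.integer(lv_candidates))),
                 fitness = fitness, seed = as.integer(seed)),
            class = "ga_control")
}

#' Cross-validated fitness of one descriptor subset
#'
#' Delegates to [loo_cv()] on the table restricted to the given subset:
#' the fitness of a chromosome is exactly the statistic the validation
#' module reports for that subset.
#'
#' @param table a [pnp_table()].
#' @param descriptors non-empty character vector of descriptor names.
#' @param ncomp latent-vector count (must not exceed the subset size).
#' @param fitness `"rmsecv"` or `"r2"`.
#' @param sd_denom see [autoscale_fit()].
#' @return scalar fitness value (mV for `"rmsecv"`).
#' @export
evaluate_chromosome <- function(table, descriptors, ncomp = 2,
                                fitness = c("rmsecv", "r2"),
                                sd_denom = "n") {
  fitness <- match.arg(fitness)
  stopifnot(length(descriptors) >= 1, ncomp <= length(descriptors))
  if (fitness == "rmsecv") {
    loo_cv(table, descriptors, ncomp, sd_denom = sd_denom)$RMSECV
  } else {
    fit_statistics(qspr_pls(table, descriptors, ncomp,
                            sd_denom = sd_denom))$R2
  }
}

# Fitness of a bit chromosome with joint choice of the component count.
# Uses the multi-component LOO engine so all lv candidates are scored from
# one pass over the folds.  Returns the signed objective (lower = better),
# the reported fitness value, and the chosen ncomp.
score_chromosome <- function(bits, X, y, names, ctl, sd_denom) {
  sel <- which(bits)
  cand <- ctl$lv_candidates[ctl$lv_candidates <= length(sel)]
  if (!length(cand)) cand <- 1L
  if (ctl$fitness == "rmsecv") {
    eng <- loo_engine(X[, sel, drop = FALSE], y, max(cand), sd_denom)
    rmse <- sqrt(colMeans((y - eng$pred)^2))[cand]
    best <- which.min(rmse)
    list(objective = rmse[best], value = rmse[best], ncomp = cand[best])
  } else {
    ym <- mean(y)
    M <- X[, sel, drop = FALSE]
    ctr <- colMeans(M)
    denom <- if (sd_denom == "n") nrow(M) else nrow(M) - 1
    scl <- sqrt(colSums(sweep(M, 2, ctr)^2) / denom)
    keep <- scl > 0
    if (!any(keep)) return(list(objective = 0, value = 0, ncomp = 1L))
    Ms <- scale(M[, keep, drop = FALSE], ctr[keep], scl[keep])
    cand <- cand[cand <= sum(keep)]
    if (!length(cand)) cand <- 1L
    dec <- nipals_pls1(Ms, y - ym, max(cand))
    r2 <- cumsum(dec$yvar_pct)[cand] / 100
    best <- which.max(r2)
    list(objective = -r2[best], value = r2[best], ncomp = cand[best])
  }
}

repair_bits <- function(bits, size_min, size_max) {
  k <- sum(bits)
  if (k < size_min) {
    off <- which(!bits)
    bits[off[sample.int(length(off), size_min - k)]] <- TRUE
  } else if (k > size_max) {
    on <- which(bits)
    bits[on[sample.int(length(on), k - size_max)]] <- FALSE
  }
  bits
}

#' Genetic-algorithm descriptor selection for PLS models
#'
#' Searches the descriptor pool for the subset (and latent-vector count)
#' minimizing the leave-one-out RMSECV (or maximizing training R2) of the
#' PLS model, using the GA described in [ga_control()].  The best fitness
#' reported is recomputed from scratch for the winning subset, so it never
#' relies on cached values.
#'
#' @param table a [pnp_table()].
#' @param pool character vector of candidate descriptor names (default:
#'   all descriptors in the table).
#' @param control a [ga_control()].
#' @return object of class `qspr_ga`: `descriptors` (best subset),
#'   `ncomp`, `fitness` (fresh re-evaluation), `trajectory` (best fitness
#'   per generation), `n_evaluations` and the `control` used.
#' @export
#' @examples
#' ctl <- ga_control(pop_size = 20, generations = 10, seed = 7,
#'                   size_max = 3)
#' ga <- ga_select(pnp20(), control = ctl)
#' ga$descriptors
ga_select <- function(table, pool = NULL, control = ga_control()) {
  stopifnot(inherits(table, "pnp_table"), inherits(control, "ga_control"))
  if (is.null(pool)) pool <- table$schema$name
  if (!length(pool)) stop("empty descriptor pool")
  sub <- subset_descriptors(table, pool)
  tr <- if (any(sub$split == "T")) train_rows(sub) else seq_along(sub$ids)
  X <- sub$X[tr, , drop = FALSE]
  y <- sub$zeta[tr]
  npool <- length(pool)
  ctl <- control
  if (is.null(ctl$size_max)) ctl$size_max <- npool
  if (is.null(ctl$p_mutation)) ctl$p_mutation <- min(1, 2 / npool)
  stopifnot(ctl$size_min <= ctl$size_max, ctl$size_max <= npool)
  sd_denom <- "n"

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(ctl$seed)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  score <- function(bits) {
    key <- paste(which(bits), collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    out <- score_chromosome(bits, X, y, pool, ctl, sd_denom)
    n_eval <<- n_eval + 1L
    cache[[key]] <- out
    out
  }

  pop <- lapply(seq_len(ctl$pop_size), function(i) {
    k <- sample(ctl$size_min:ctl$size_max, 1)
    bits <- rep(FALSE, npool)
    bits[sample.int(npool, k)] <- TRUE
    bits
  })
  scores <- lapply(pop, score)
  obj <- vapply(scores, `[[`, numeric(1), "objective")
  traj <- numeric(ctl$generations)
  for (g in seq_len(ctl$generations)) {
    ord <- order(obj)
    newpop <- pop[ord[seq_len(min(ctl$elitism, ctl$pop_size))]]
    while (length(newpop) < ctl$pop_size) {
      pick <- function() {
        cand <- sample.int(ctl$pop_size, ctl$tournament, replace = TRUE)
        pop[[cand[which.min(obj[cand])]]]
      }
      p1 <- pick(); p2 <- pick()
      if (stats::runif(1) < ctl$p_crossover) {
        mask <- stats::runif(npool) < 0.5
        c1 <- ifelse(mask, p1, p2)
        c2 <- ifelse(mask, p2, p1)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (length(newpop) >= ctl$pop_size) break
        flip <- stats::runif(npool) < ctl$p_mutation
        child <- xor(child, flip)
        child <- repair_bits(child, ctl$size_min, ctl$size_max)
        newpop[[length(newpop) + 1]] <- child
      }
    }
    pop <- newpop
    scores <- lapply(pop, score)
    obj <- vapply(scores, `[[`, numeric(1), "objective")
    traj[g] <- scores[[which.min(obj)]]$value
  }
  best_i <- which.min(obj)
  best_bits <- pop[[best_i]]
  best_names <- pool[best_bits]
  best_ncomp <- scores[[best_i]]$ncomp
  # fresh re-evaluation through the public validation path (no caching)
  best_fitness <- evaluate_chromosome(sub, best_names, best_ncomp,
                                      fitness = ctl$fitness,
                                      sd_denom = sd_denom)
  structure(list(descriptors = best_names, ncomp = best_ncomp,
                 fitness = best_fitness, trajectory = traj,
                 n_evaluations = n_eval, control = ctl),
            class = "qspr_ga")
}

#' @export
print.qspr_ga <- function(x, digits = 4, ...) {
  cat("GA descriptor selection (", x$control$generations,
      " generations, ", x$n_evaluations, " unique evaluations)\n",
      sep = "")
  cat("best subset (", length(x$descriptors), " descriptors, ",
      x$ncomp, " LV): ", paste(x$descriptors, collapse = ", "),
      "\n", sep = "")
  cat("fitness (", x$control$fitness, "): ",
      format(x$fitness, digits = digits), "\n", sep = "")
  invisible(x)
}

#' Write a GA result to JSON (and its trajectory to CSV)
#'
#' @param result a [ga_select()] result.
#' @param json_path output JSON path.
#' @param trajectory_csv optional CSV path for the per-generation best
#'   fitness.
#' @return `result`, invisibly.
#' @export
write_ga_result <- function(result, json_path, trajectory_csv = NULL) {
  stopifnot(inherits(result, "qspr_ga"))
  jsonlite::write_json(
    list(descriptors = result$descriptors, ncomp = result$ncomp,
         fitness = result$fitness, n_evaluations = result$n_evaluations,
         control = unclass(result$control)),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(trajectory_csv))
    utils::write.csv(data.frame(generation = seq_along(result$trajectory),
                                best_fitness = result$trajectory),
                     trajectory_csv, row.names = FALSE)
  invisible(result)
}
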