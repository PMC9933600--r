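#' Specification for a synthetic nanoparticle descriptor table
#'
#' Describes a descriptor pool with the statistical structure the modeling
#' pipeline assumes: a block of correlated continuous core descriptors on
#' molecular-weight-like scales, a block of small non-negative integer
#' coating counts, and a block of independent Bernoulli protein-corona
#' fingerprint bits.  The endpoint is a planted sparse linear combination
#' of named descriptors plus Gaussian noise, so selection and regression
#' methods can be checked against a known ground truth.
#'
#' @param n_samples number of nanoparticles.
#' @param n_core,n_coating,n_corona block sizes (defaults 33 / 34 / 80,
#'   the pool sizes of the benchmark study design).
#' @param prevalence Bernoulli success probability of each corona bit,
#'   in (0, 1).
#' @param coefficients named numeric vector: planted raw-space effect
#'   (mV per descriptor unit) of each named descriptor; all other
#'   descriptors have zero effect.
#' @param noise_sd Gaussian endpoint noise, mV.
#' @param offset endpoint intercept, mV.
#' @param core_mean,core_sd,core_cor location, scale and pairwise
#'   correlation (via a shared factor) of the core block.
#' @param coating_lambda Poisson mean of the coating counts.
#' @param corona_correlated when `TRUE`, corona bits co-occur through a
#'   shared latent adsorption factor instead of being independent.
#' @param seed integer RNG seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, n_core = 33, n_coating = 34,
                           n_corona = 80, prevalence = 0.3,
                           coefficients = numeric(0), noise_sd = 5,
                           offset = 0, core_mean = 6.2, core_sd = 0.7,
                           core_cor = 0.3, coating_lambda = 1,
                           corona_correlated = FALSE, seed = 1) {
  stopifnot(n_samples >= 1, prevalence > 0, prevalence < 1, noise_sd >= 0,
            core_cor >= 0, core_cor < 1)
  structure(list(n_samples = n_samples, n_core = n_core,
                 n_coating = n_coating, n_corona = n_corona,
                 prevalence = prevalence,
                 coefficients = coefficients, noise_sd = noise_sd,
                 offset = offset, core_mean = core_mean, core_sd = core_sd,
                 core_cor = core_cor, coating_lambda = coating_lambda,
                 corona_correlated = corona_correlated,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

synthetic_names <- function(spec) {
  c(sprintf("core_%02d", seq_len(spec$n_core)),
    sprintf("coat_%02d", seq_len(spec$n_coating)),
    sprintf("cor_%02d", seq_len(spec$n_corona)))
}

#' Generate a synthetic descriptor table from a specification
#'
#' Draws the descriptor blocks described by [synthetic_spec()], computes
#' the endpoint as `offset + sum(planted coefficient * descriptor) +
#' N(0, noise_sd)`, and assigns train/validation labels with
#' [split_every_third()].  The same seed always yields an identical table.
#'
#' @param spec a [synthetic_spec()].
#' @return a [pnp_table()].
#' @export
#' @examples
#' spec <- fixture_like_spec(seed = 42)
#' tab <- generate_pnp_table(spec)
#' range(tab$zeta)
generate_pnp_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nms <- synthetic_names(spec)
  unknown <- setdiff(names(spec$coefficients), nms)
  if (length(unknown))
    stop("planted coefficient names descriptor(s) outside the pool: ",
         paste(unknown, collapse = ", "))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_samples
  shared <- stats::rnorm(n)
  core <- sapply(seq_len(spec$n_core), function(j)
    spec$core_mean + spec$core_sd *
      (sqrt(spec$core_cor) * shared +
         sqrt(1 - spec$core_cor) * stats::rnorm(n)))
  coating <- sapply(seq_len(spec$n_coating), function(j)
    stats::rpois(n, spec$coating_lambda))
  if (spec$corona_correlated) {
    adsorb <- stats::rnorm(n)   # latent adsorption propensity
    corona <- sapply(seq_len(spec$n_corona), function(j) {
      thr <- stats::qnorm(spec$prevalence)
      as.numeric(sqrt(0.5) * adsorb + sqrt(0.5) * stats::rnorm(n) < thr)
    })
  } else {
    corona <- sapply(seq_len(spec$n_corona), function(j)
      stats::rbinom(n, 1, spec$prevalence))
  }
  X <- cbind(core, coating, corona)
  colnames(X) <- nms
  beta <- stats::setNames(rep(0, length(nms)), nms)
  beta[names(spec$coefficients)] <- spec$coefficients
  zeta <- spec$offset + drop(X %*% beta) +
    stats::rnorm(n, sd = spec$noise_sd)
  schema <- data.frame(
    name = nms,
    block = rep(c("core", "coating", "corona"),
                c(spec$n_core, spec$n_coating, spec$n_corona)),
    kind = rep(c("continuous", "count", "binary"),
               c(spec$n_core, spec$n_coating, spec$n_corona)))
  tab <- pnp_table(X, zeta, schema)
  if (n >= 3) tab <- split_every_third(tab)
  tab
}

#' A synthetic specification mimicking the benchmark study setting
#'
#' Returns a [synthetic_spec()] for 20 samples whose planted
#' structure-property relationship mirrors the benchmark model: one core
#' descriptor with a positive effect, one coating count with a negative
#' effect, two corona bits with positive effects and one with a negative
#' effect, and an endpoint centered so that zeta potentials span roughly
#' -70 to +50 mV.
#'
#' @param seed integer RNG seed.
#' @return a [synthetic_spec()].
#' @export
fixture_like_spec <- function(seed = 1) {
  # raw-space effects on the scale of the benchmark model's own equation
  coefs <- c(core_01 = 20, coat_01 = -19,
             cor_01 = 45, cor_02 = 36, cor_03 = -21)
  spec <- synthetic_spec(n_samples = 20, coefficients = coefs,
                         noise_sd = 5, seed = seed)
  # center the expected endpoint at about -10 mV (benchmark training mean)
  expected <- coefs[["core_01"]] * spec$core_mean +
    coefs[["coat_01"]] * spec$coating_lambda +
    (coefs[["cor_01"]] + coefs[["cor_02"]] + coefs[["cor_03"]]) *
      spec$prevalence
  spec$offset <- -10 - expected
  spec
}
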