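## Isotropic linear elasticity of the keratinous setal shaft.

#' Lamé parameters from engineering constants
#'
#' `lambda = E*nu / ((1+nu)(1-2nu))`, `mu = E / (2(1+nu))`.
#'
#' @param E Young's modulus, GPa (> 0).
#' @param nu Poisson's ratio, in `[0, 0.5)`; the incompressible limit is
#'   rejected.
#' @return named list with `lambda` and `mu` in GPa.
#' @export
lame_from_E_nu <- function(E, nu) {
  stopifnot(E > 0)
  if (nu < 0 || nu >= 0.5)
    stop("nu must lie in [0, 0.5); nu >= 0.5 is the incompressible limit",
         call. = FALSE)
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

#' Engineering constants from Lamé parameters
#'
#' Algebraic inverse of [lame_from_E_nu()].
#'
#' @param lambda,mu Lamé parameters, GPa (`mu > 0`, `lambda >= 0`).
#' @return named list with `E` (GPa) and `nu`.
#' @export
E_nu_from_lame <- function(lambda, mu) {
  stopifnot(mu > 0, lambda >= 0)
  list(E = mu * (3 * lambda + 2 * mu) / (lambda + mu),
       nu = lambda / (2 * (lambda + mu)))
}

#' Elastic parameters of the setal shaft
#'
#' Validates and completes an isotropic linear-elastic parameter set.
#' Defaults are the keratin values used throughout the model:
#' `E = 4.518 GPa`, `nu = 0.401`.
#'
#' @param E Young's modulus, GPa.
#' @param nu Poisson's ratio, strictly in (0, 0.5) so the Lamé parameters
#'   stay finite.
#' @return object of class `elastic_params`: list with `E`, `nu`, `lambda`,
#'   `mu` (GPa).
#' @export
elastic_params <- function(E = 4.518, nu = 0.401) {
  stopifnot(E > 0, nu > 0, nu < 0.5)
  lm <- lame_from_E_nu(E, nu)
  structure(list(E = E, nu = nu, lambda = lm$lambda, mu = lm$mu),
            class = "elastic_params")
}

#' @export
print.elastic_params <- function(x, ...) {
  cat(sprintf("<elastic_params> E = %.4g GPa, nu = %.4g (lambda = %.4g, mu = %.4g GPa)\n",
              x$E, x$nu, x$lambda, x$mu))
  invisible(x)
}

#' Sample material parameters for one run
#'
#' Draws Young's modulus and Poisson's ratio once from independent normal
#' distributions; draws violating the admissibility constraints (`E > 0`,
#' `0 < nu < 0.5`) are rejected and redrawn, which with the default spreads
#' is astronomically rare.
#'
#' @param E_mean,E_sd mean and standard deviation of E, GPa.
#' @param nu_mean,nu_sd mean and standard deviation of nu.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return an [elastic_params()] object.
#' @export
sample_material <- function(E_mean = 4.518, E_sd = 0.036,
                            nu_mean = 0.401, nu_sd = 0.002, seed = 1L) {
  stopifnot(E_sd >= 0, nu_sd >= 0)
  rng <- .seeded_rng(seed)
  on.exit(rng$restore())
  E <- rnorm(1, E_mean, E_sd)
  nu <- rnorm(1, nu_mean, nu_sd)
  tries <- 0L
  while ((E <= 0 || nu <= 0 || nu >= 0.5) && tries < 1000L) {
    E <- rnorm(1, E_mean, E_sd)
    nu <- rnorm(1, nu_mean, nu_sd)
    tries <- tries + 1L
  }
  if (E <= 0 || nu <= 0 || nu >= 0.5)
    stop("could not draw admissible material parameters", call. = FALSE)
  elastic_params(E = E, nu = nu)
}

#' Cauchy stress from infinitesimal strain
#'
#' `sigma = lambda * tr(eps) * I + 2 * mu * eps` for an isotropic
#' linear-elastic material.
#'
#' @param eps 3x3 symmetric strain tensor (dimensionless).
#' @param params an [elastic_params()] object.
#' @return 3x3 stress tensor, GPa.
#' @export
isotropic_stress <- function(eps, params) {
  stopifnot(is.matrix(eps), all(dim(eps) == c(3, 3)))
  params$lambda * sum(diag(eps)) * diag(3) + 2 * params$mu * eps
}

## run a block of code under a local, seeded R RNG without disturbing the
## caller's RNG state
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}
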