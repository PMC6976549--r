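#' Rate models for diversification processes
#'
#' A rate model bundles the per-species speciation rate \eqn{\lambda_n(t)} and
#' extinction rate \eqn{\mu_n(t)} as functions of the standing diversity
#' \eqn{n} (number of species) and time \eqn{t}.  Three families are provided:
#' constant rates, purely time-dependent (diversity-independent) rates, and
#' linear diversity-dependent speciation with constant extinction.  Rates are
#' per lineage per unit time and are clamped at zero, so downstream consumers
#' never see a negative transition rate.
#'
#' Time runs from the past towards the present throughout the package: the
#' crown age `t_c` is smaller than the present time `t_p`.
#'
#' @param lambda,mu Nonnegative constant per-species speciation and
#'   extinction rates.
#' @name rate_model
NULL

new_rate_model <- function(speciation, extinction, diversity_independent,
                           time_independent, type, params) {
  structure(
    list(
      speciation = speciation,
      extinction = extinction,
      diversity_independent = diversity_independent,
      time_independent = time_independent,
      type = type,
      params = params
    ),
    class = "rate_model"
  )
}

check_nonnegative_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < 0) {
    stop(sprintf("`%s` must be nonnegative (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

#' @describeIn rate_model Constant per-species speciation and extinction
#'   rates \eqn{\lambda}, \eqn{\mu}.
#' @return A `rate_model` object: a list with vectorised functions
#'   `speciation(n, t)` and `extinction(n, t)` (vectorised over `n`, scalar
#'   `t`), and flags `diversity_independent` and `time_independent`.
#' @examples
#' m <- constant_rates(0.8, 0.1)
#' speciation_rate(m, 5, 3.2) # 0.8
#' @export
constant_rates <- function(lambda, mu) {
  check_nonnegative_scalar(lambda, "lambda")
  check_nonnegative_scalar(mu, "mu")
  force(lambda); force(mu)
  new_rate_model(
    speciation = function(n, t) rep_len(lambda, length(n)),
    extinction = function(n, t) rep_len(mu, length(n)),
    diversity_independent = TRUE,
    time_independent = TRUE,
    type = "constant",
    params = list(lambda = lambda, mu = mu)
  )
}

#' @describeIn rate_model Linear diversity-dependent speciation
#'   \eqn{\lambda_n = \max(0, \lambda_0 (1 - n/K))} with constant extinction
#'   \eqn{\mu}; `K` is the carrying capacity at which speciation vanishes.
#' @param lambda0 Nonnegative speciation rate at vanishing diversity.
#' @param carrying_capacity Positive diversity at which speciation reaches zero.
#' @export
linear_dd_rates <- function(lambda0, carrying_capacity, mu) {
  check_nonnegative_scalar(lambda0, "lambda0")
  check_nonnegative_scalar(mu, "mu")
  if (!is.numeric(carrying_capacity) || length(carrying_capacity) != 1L ||
      !is.finite(carrying_capacity) || carrying_capacity <= 0) {
    stop("`carrying_capacity` must be a single positive number", call. = FALSE)
  }
  force(lambda0); force(carrying_capacity); force(mu)
  new_rate_model(
    speciation = function(n, t) pmax(0, lambda0 * (1 - n / carrying_capacity)),
    extinction = function(n, t) rep_len(mu, length(n)),
    diversity_independent = FALSE,
    time_independent = TRUE,
    type = "linear_dd",
    params = list(lambda0 = lambda0, carrying_capacity = carrying_capacity,
                  mu = mu)
  )
}

#' @describeIn rate_model Diversity-independent but time-dependent rates.
#'   `lambda_fn` and `mu_fn` map a scalar time to a nonnegative rate; a
#'   negative value at evaluation time raises an error at the point of use.
#' @param lambda_fn,mu_fn Functions of a single time argument returning a
#'   nonnegative rate.
#' @export
time_dependent_rates <- function(lambda_fn, mu_fn) {
  stopifnot(is.function(lambda_fn), is.function(mu_fn))
  force(lambda_fn); force(mu_fn)
  eval_checked <- function(fn, what) {
    function(n, t) {
      v <- fn(t)
      if (!all(is.finite(v)) || any(v < 0)) {
        stop(sprintf("%s rate function returned a negative or non-finite value at t = %g",
                     what, t), call. = FALSE)
      }
      rep_len(v, length(n))
    }
  }
  new_rate_model(
    speciation = eval_checked(lambda_fn, "speciation"),
    extinction = eval_checked(mu_fn, "extinction"),
    diversity_independent = TRUE,
    time_independent = FALSE,
    type = "time_dependent",
    params = list(lambda_fn = lambda_fn, mu_fn = mu_fn)
  )
}

#' Evaluate a rate model
#'
#' @param model A [rate_model] object.
#' @param n Diversity (number of species); may be a vector of positive
#'   integers.
#' @param t Scalar time.
#' @return Nonnegative per-species rate(s), one per element of `n`.
#' @export
speciation_rate <- function(model, n, t) {
  stopifnot(inherits(model, "rate_model"))
  model$speciation(n, t)
}

#' @rdname speciation_rate
#' @export
extinction_rate <- function(model, n, t) {
  stopifnot(inherits(model, "rate_model"))
  model$extinction(n, t)
}

#' Build a rate model from a tagged configuration list
#'
#' Accepts the tagged record used in JSON run configurations:
#' `type = "constant"` (fields `lambda`, `mu`), `type = "linear_dd"`
#' (fields `lambda0`, `carrying_capacity`, `mu`), or
#' `type = "exponential_time"` (fields `lambda0`, `lambda_decay`, `mu0`,
#' `mu_decay`, giving \eqn{\lambda(t) = \lambda_0 e^{-d_\lambda t}} and
#' likewise for \eqn{\mu}).  An unknown type is an error.
#'
#' @param config A named list.
#' @return A [rate_model].
#' @export
rate_model_from_config <- function(config) {
  if (is.null(config$type)) {
    stop("rate-model config must have a `type` field", call. = FALSE)
  }
  switch(
    as.character(config$type),
    constant = constant_rates(config$lambda, config$mu),
    linear_dd = linear_dd_rates(config$lambda0, config$carrying_capacity,
                                config$mu),
    exponential_time = {
      l0 <- config$lambda0; ld <- config$lambda_decay
      m0 <- config$mu0; md <- config$mu_decay
      check_nonnegative_scalar(l0, "lambda0")
      check_nonnegative_scalar(m0, "mu0")
      time_dependent_rates(
        function(t) l0 * exp(-ld * t),
        function(t) m0 * exp(-md * t)
      )
    },
    stop(sprintf("unknown rate-model type '%s'", config$type), call. = FALSE)
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model: %s%s%s>\n", x$type,
              if (x$diversity_independent) ", diversity-independent" else ", diversity-dependent",
              if (x$time_independent) ", time-independent" else ", time-dependent"))
  invisible(x)
}
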