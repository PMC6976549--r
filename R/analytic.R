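#' Likelihood result container
#'
#' All likelihood routines return this decomposition in log space:
#' `log_likelihood = log_numerator - log_combinatorial - log_conditioning`.
#' For the analytic diversity-independent formulas the conditioning is built
#' into the numerator (the crown-survival factor cancels), so
#' `log_conditioning` is 0 there; for the Q-framework it holds the log of the
#' crown-survival probability \eqn{P_c}.
#'
#' @param log_numerator,log_combinatorial,log_conditioning Log-space parts.
#' @param diagnostics Named list of numerical diagnostics (truncation used,
#'   tail masses, solver tolerances, probe history).
#' @return A `likelihood_result` object.
#' @keywords internal
new_likelihood_result <- function(log_numerator, log_combinatorial = 0,
                                  log_conditioning = 0,
                                  diagnostics = list()) {
  structure(
    list(
      log_likelihood = log_numerator - log_combinatorial - log_conditioning,
      log_numerator = log_numerator,
      log_combinatorial = log_combinatorial,
      log_conditioning = log_conditioning,
      diagnostics = diagnostics
    ),
    class = "likelihood_result"
  )
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("<likelihood_result: log L = %.10g>\n", x$log_likelihood))
  cat(sprintf("  numerator %.10g | combinatorial %.6g | conditioning %.10g\n",
              x$log_numerator, x$log_combinatorial, x$log_conditioning))
  invisible(x)
}

#' @export
logLik.likelihood_result <- function(object, ...) {
  structure(object$log_likelihood, class = "logLik")
}

#' Weighted sum over compositions of the missing-species count
#'
#' Computes \deqn{\sum_{\mathbf m \mid m_p} \prod_{j} (m_j + 1)\,\eta_j^{m_j},}
#' the sum over all ways to distribute `m_p` missing species over the
#' branches obtained by breaking the tree, each branch `j` carrying
#' geometric weight `etas[j]`.  Evaluated as the coefficient of
#' \eqn{z^{m_p}} in \eqn{\prod_j (1 - \eta_j z)^{-2}} by truncated series
#' convolution (each factor contributes coefficients \eqn{(m+1)\eta_j^m}),
#' which is polynomial-time; explicit enumeration is kept only as a test
#' oracle.
#'
#' @param etas Vector of geometric weights in `[0, 1)`, one per branch slot.
#' @param m_p Nonnegative integer number of missing species.
#' @return Positive scalar; 1 when `m_p = 0`.
#' @examples
#' composition_sum(c(0.5, 0.5), 2) # 2.5
#' @export
composition_sum <- function(etas, m_p) {
  stopifnot(is.numeric(etas), length(etas) >= 1,
            all(etas >= 0), all(etas < 1))
  if (!is.numeric(m_p) || length(m_p) != 1L || m_p < 0 || m_p != round(m_p)) {
    stop("`m_p` must be a single nonnegative integer", call. = FALSE)
  }
  if (m_p == 0) return(1)
  ms <- 0:m_p
  acc <- (ms + 1) * etas[1]^ms
  for (eta in etas[-1]) {
    fac <- (ms + 1) * eta^ms
    acc <- series_product(acc, fac, m_p)
  }
  acc[m_p + 1L]
}

# Truncated product of two coefficient vectors (degree 0..D each).
series_product <- function(a, b, D) {
  out <- numeric(D + 1L)
  for (i in 0:D) {
    out[i + 1L] <- sum(a[seq_len(i + 1L)] * b[(i + 1L):1L])
  }
  out
}

# Kendall pairs at the node times t_0 = t_1 = t_c, t_2, ..., t_{k_p - 1},
# all measured to t_p.  Returns list(xi = ..., eta = ...), each of length k_p.
node_kendall_pairs <- function(model, bt, f_p = NULL, tol = 1e-12) {
  times <- c(bt$t_c, bt$t_c, bt$internal)
  pairs <- lapply(times, function(tt) {
    if (is.null(f_p)) {
      kendall_xi_eta(model, tt, bt$t_p, tol)
    } else {
      kendall_xi_eta_rho(model, f_p, tt, bt$t_p, tol)
    }
  })
  list(
    xi = vapply(pairs, `[[`, numeric(1), "xi"),
    eta = vapply(pairs, `[[`, numeric(1), "eta")
  )
}

#' Analytic likelihood: diversity-independent rates, n-sampling
#'
#' The closed-form likelihood of the branching times of a reconstructed tree
#' with `k_p` tips and a known number `m_p` of unsampled extant species,
#' under diversity-independent (possibly time-dependent) rates, conditional
#' on both crown lineages surviving to the present:
#' \deqn{L = \frac{(k_p - 1)!}{\binom{k_p + m_p}{m_p}}
#'   (1 - \eta(t_c, t_p))^2
#'   \prod_{i=2}^{k_p-1} \lambda(t_i) (1 - \xi(t_i, t_p)) (1 - \eta(t_i, t_p))
#'   \sum_{\mathbf m \mid m_p} \prod_{j=0}^{k_p-1} (m_j + 1) \eta(t_j, t_p)^{m_j}.}
#' At `m_p = 0` this is the classic breaking-the-tree likelihood.  All
#' products accumulate in log space.
#'
#' @param model A diversity-independent [rate_model].
#' @param bt A [branching_times] object.
#' @param m_p Number of unsampled extant species (nonnegative integer).
#' @param tol Quadrature tolerance for the Kendall integrals.
#' @return A `likelihood_result` (`log_conditioning = 0`: the conditioning
#'   is already embedded).
#' @export
loglik_div_indep_n <- function(model, bt, m_p = 0, tol = 1e-12) {
  check_di_model(model)
  stopifnot(inherits(bt, "branching_times"))
  scheme <- n_sampling(m_p)
  m_p <- scheme$m_p
  k_p <- bt$k_p
  np <- node_kendall_pairs(model, bt, f_p = NULL, tol = tol)
  lam_i <- if (k_p > 2) {
    vapply(bt$internal, function(ti) model$speciation(1L, ti), numeric(1))
  } else numeric(0)
  internal_idx <- seq_len(k_p)[-(1:2)] # slots 3..k_p hold t_2..t_{k_p-1}
  log_num <- lfactorial(k_p - 1) +
    2 * log1p(-np$eta[1]) +
    sum(log(lam_i)) +
    sum(log1p(-np$xi[internal_idx])) +
    sum(log1p(-np$eta[internal_idx])) +
    log(composition_sum(np$eta, m_p))
  new_likelihood_result(
    log_numerator = log_num,
    log_combinatorial = lchoose(k_p + m_p, m_p),
    log_conditioning = 0,
    diagnostics = list(method = "analytic_n", quadrature_tol = tol)
  )
}

#' Analytic likelihood: diversity-independent rates, rho-sampling
#'
#' As [loglik_div_indep_n()] but for the sampling scheme in which each extant
#' species is included independently with probability `f_p`:
#' \deqn{L = (k_p - 1)!\,(1 - \tilde\eta(t_c, t_p))^2
#'  \prod_{i=2}^{k_p-1} \lambda(t_i)(1 - \tilde\xi(t_i, t_p))(1 - \tilde\eta(t_i, t_p)),}
#' with the sampling-adjusted Kendall pair of [kendall_xi_eta_rho()].  At
#' `f_p = 1` this equals [loglik_div_indep_n()] with `m_p = 0` (shared code
#' path for the Kendall pair).
#'
#' @inheritParams loglik_div_indep_n
#' @param f_p Sampling probability in `(0, 1]`.
#' @export
loglik_div_indep_rho <- function(model, bt, f_p, tol = 1e-12) {
  check_di_model(model)
  stopifnot(inherits(bt, "branching_times"))
  scheme <- rho_sampling(f_p)
  k_p <- bt$k_p
  np <- node_kendall_pairs(model, bt, f_p = scheme$f_p, tol = tol)
  lam_i <- if (k_p > 2) {
    vapply(bt$internal, function(ti) model$speciation(1L, ti), numeric(1))
  } else numeric(0)
  internal_idx <- seq_len(k_p)[-(1:2)]
  log_num <- lfactorial(k_p - 1) +
    2 * log1p(-np$eta[1]) +
    sum(log(lam_i)) +
    sum(log1p(-np$xi[internal_idx])) +
    sum(log1p(-np$eta[internal_idx]))
  new_likelihood_result(
    log_numerator = log_num,
    log_combinatorial = 0,
    log_conditioning = 0,
    diagnostics = list(method = "analytic_rho", f_p = scheme$f_p,
                       quadrature_tol = tol)
  )
}

#' Analytic likelihood: diversity-dependent speciation without extinction
#'
#' The closed-form likelihood for the pure-birth diversity-dependent model
#' (all extant species sampled):
#' \deqn{L = (k_p - 1)! \prod_{i=2}^{k_p-1} \lambda_i(t_i)
#'   \prod_{j=2}^{k_p} \exp\Big(-j \int_{t_{j-1}}^{t_j} \lambda_j(s)\,ds\Big),}
#' with \eqn{t_1 = t_c} and \eqn{t_{k_p} = t_p}.  Between consecutive
#' branching times there are exactly `j` species, each avoiding speciation at
#' rate \eqn{\lambda_j(s)}.  For time-constant rates the integrals reduce to
#' \eqn{\lambda_j (t_j - t_{j-1})}, special-cased for exactness; otherwise
#' adaptive quadrature is used.  Conditioning has no effect without
#' extinction.
#'
#' @param model A [rate_model] with extinction identically zero; speciation
#'   may depend on diversity and time.
#' @param bt A [branching_times] object.
#' @param tol Quadrature tolerance for time-dependent speciation integrals.
#' @return A `likelihood_result`.
#' @examples
#' bt <- branching_times(0, 1, 2)
#' loglik_pure_birth_dd(constant_rates(1, 0), bt) # log(2) - 5
#' @export
loglik_pure_birth_dd <- function(model, bt, tol = 1e-12) {
  stopifnot(inherits(model, "rate_model"), inherits(bt, "branching_times"))
  probe_t <- seq(bt$t_c, bt$t_p, length.out = 7)
  for (tt in probe_t) {
    if (any(model$extinction(1:(bt$k_p + 5L), tt) != 0)) {
      stop("pure-birth likelihood requires extinction identically zero",
           call. = FALSE)
    }
  }
  k_p <- bt$k_p
  times <- node_times(bt) # (t_0, t_1, ..., t_{k_p})
  lam_nodes <- if (k_p > 2) {
    vapply(2:(k_p - 1), function(i) {
      model$speciation(i, times[i + 1L])
    }, numeric(1))
  } else numeric(0)
  exponents <- vapply(2:k_p, function(j) {
    a <- times[j]       # t_{j-1}
    b <- times[j + 1L]  # t_j
    if (model$time_independent) {
      model$speciation(j, a) * (b - a)
    } else {
      f <- function(s) vapply(s, function(si) model$speciation(j, si), numeric(1))
      stats::integrate(f, a, b, rel.tol = tol, abs.tol = tol,
                       subdivisions = 2000L)$value
    }
  }, numeric(1))
  log_num <- lfactorial(k_p - 1) + sum(log(lam_nodes)) -
    sum((2:k_p) * exponents)
  new_likelihood_result(
    log_numerator = log_num,
    diagnostics = list(method = "analytic_pure_birth_dd",
                       quadrature_tol = tol)
  )
}
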