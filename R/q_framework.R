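#' Truncated Q-vector
#'
#' The working state of the numerical likelihood framework: the vector
#' \eqn{(Q_0^k, \dots, Q_M^k)} at time `t`, where \eqn{Q_m^k(t)} is
#' proportional to the probability that the diversification process is
#' consistent with the phylogeny up to time `t` and carries `k` observed
#' lineages (ancestral to sampled tips) plus `m` missing species.  Values are
#' stored rescaled: the true quantities are `values * exp(log_scale)`,
#' guarding against underflow as the process ages.
#'
#' @param k Observed-lineage count (at least 2).
#' @param values Nonnegative numeric vector `Q_0 ... Q_M`.
#' @param t Time stamp of the vector.
#' @param log_scale Accumulated log rescaling factor.
#' @return A `q_vector` object with fields `k`, `values`, `M`, `t`,
#'   `log_scale`.
#' @export
q_vector <- function(k, values, t, log_scale = 0) {
  stopifnot(k >= 2, k == round(k), is.numeric(values), length(values) >= 1,
            all(is.finite(values)), all(values >= 0),
            is.numeric(t), length(t) == 1L)
  structure(
    list(k = as.integer(k), values = as.numeric(values),
         M = length(values) - 1L, t = t, log_scale = log_scale),
    class = "q_vector"
  )
}

#' @export
print.q_vector <- function(x, ...) {
  cat(sprintf("<q_vector: k = %d, M = %d, t = %g, log_scale = %.6g>\n",
              x$k, x$M, x$t, x$log_scale))
  invisible(x)
}

stop_truncation <- function(msg) {
  stop(structure(class = c("divlik_truncation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Right-hand side of the Q-vector ODE system
#'
#' The branch dynamics of the framework: with `n = k + m` species in total,
#' \deqn{\dot Q_m = \mu_{k+m+1}(m+1) Q_{m+1}
#'   + \lambda_{k+m-1}(m - 1 + 2k) Q_{m-1}
#'   - (\lambda_{m+k} + \mu_{m+k})(m+k) Q_m,}
#' with \eqn{Q_{-1} = Q_{M+1} = 0}.  The generator is tridiagonal in `m`,
#' which the branch propagator exploits.
#'
#' @param q A [q_vector].
#' @param model A [rate_model].
#' @param t Time at which to evaluate the (possibly time-dependent) rates.
#' @return Numeric derivative vector of length `M + 1`.
#' @export
q_rhs <- function(q, model, t) {
  stopifnot(inherits(q, "q_vector"), inherits(model, "rate_model"))
  q_rhs_values(q$values, q$k, model, t)
}

q_rhs_values <- function(Q, k, model, t) {
  M <- length(Q) - 1L
  ms <- 0:M
  lam_n <- model$speciation(k + ms, t)
  mu_n <- model$extinction(k + ms, t)
  mu_up <- model$extinction(k + ms + 1L, t)
  lam_dn <- model$speciation(pmax(k + ms - 1L, 1L), t)
  q_up <- c(Q[-1L], 0)       # Q_{m+1}
  q_dn <- c(0, Q[-(M + 1L)]) # Q_{m-1}
  mu_up * (ms + 1) * q_up +
    lam_dn * (ms - 1 + 2 * k) * q_dn -
    (lam_n + mu_n) * (ms + k) * Q
}

#' Propagate a Q-vector along a branch
#'
#' Integrates the tridiagonal ODE system of [q_rhs()] from `q$t` to `t_end`
#' with a stiff-capable solver (lsoda, banded Jacobian).  The vector is
#' rescaled into `log_scale` so the stored maximum stays near 1.  After
#' propagation the truncation is checked: if the top entry `Q_M` exceeds
#' `tail_threshold` times the vector maximum, a truncation error is raised
#' advising a larger `M`.
#'
#' @param q A [q_vector] with `q$t <= t_end`.
#' @param model A [rate_model].
#' @param t_end End time of the branch.
#' @param tol Relative solver tolerance.
#' @param tail_threshold Maximum tolerated ratio `Q_M / max(Q)`.
#' @return A [q_vector] at `t_end` with the same `k`.
#' @export
propagate_branch <- function(q, model, t_end, tol = 1e-10,
                             tail_threshold = 1e-8) {
  stopifnot(inherits(q, "q_vector"), inherits(model, "rate_model"))
  if (t_end < q$t) stop("`t_end` must not precede `q$t`", call. = FALSE)
  if (t_end == q$t) return(q)
  vals <- q$values
  log_scale <- q$log_scale
  mx <- max(vals)
  if (mx > 0) { # keep the stored maximum at 1; true scale lives in log_scale
    vals <- vals / mx
    log_scale <- log_scale + log(mx)
  }
  k <- q$k
  rhs <- function(t, y, parms) list(q_rhs_values(y, k, model, t))
  sol <- deSolve::ode(y = vals, times = c(q$t, t_end), func = rhs,
                      parms = NULL, method = "lsoda", jactype = "bandint",
                      bandup = 1L, banddown = 1L,
                      rtol = tol, atol = tol * 1e-6, maxsteps = 100000L)
  out <- pmax(as.numeric(sol[nrow(sol), -1L]), 0)
  mx2 <- max(out)
  if (!is.finite(mx2) || mx2 <= 0) {
    stop("Q-vector propagation failed: vector vanished or became non-finite",
         call. = FALSE)
  }
  if (out[length(out)] / mx2 > tail_threshold) {
    stop_truncation(sprintf(
      "Q-vector truncation too small (Q_M / max = %.3g > %.3g); increase M",
      out[length(out)] / mx2, tail_threshold))
  }
  q_vector(k, out / mx2, t_end, log_scale + log(mx2))
}

#' Apply the node (speciation) operator to a Q-vector
#'
#' At a branching time \eqn{t_k} the vector is transformed by the diagonal
#' operator \eqn{Q_m \leftarrow k\,\lambda_{k+m}(t_k)\,Q_m} and the observed
#' lineage count increases to `k + 1`.  The factor `k` reflects that the
#' likelihood is of branching times, not of a topology (any of the `k`
#' branches may split); the time differential is omitted, making the result
#' a density in the branching time.
#'
#' @param q A [q_vector] with `q$t` equal to the branching time.
#' @param model A [rate_model].
#' @param t_k The branching time.
#' @return A [q_vector] with `k + 1` observed lineages.
#' @export
apply_node <- function(q, model, t_k) {
  stopifnot(inherits(q, "q_vector"), inherits(model, "rate_model"))
  if (abs(q$t - t_k) > 1e-12 * max(1, abs(t_k))) {
    stop("`q$t` must equal the branching time `t_k`", call. = FALSE)
  }
  ms <- 0:q$M
  lam <- model$speciation(q$k + ms, t_k)
  q_vector(q$k + 1L, q$k * lam * q$values, t_k, q$log_scale)
}

#' Q-vector at the present time
#'
#' Runs the full operator chain of the framework: starting from
#' \eqn{Q_m^{k=2}(t_c) = \delta_{m,0}} (no missing species at crown age),
#' alternately propagates along branches and applies the node operator at
#' each branching time, ending with the vector \eqn{Q^{k_p}(t_p)}.
#'
#' @param model A [rate_model].
#' @param bt A [branching_times] object.
#' @param M Truncation (largest missing-species count tracked).
#' @param tol Solver tolerance.
#' @param tail_threshold Passed to [propagate_branch()].
#' @return A [q_vector] with `k = k_p` at `t_p`.
#' @export
q_at_present <- function(model, bt, M, tol = 1e-10, tail_threshold = 1e-8) {
  stopifnot(inherits(model, "rate_model"), inherits(bt, "branching_times"),
            M >= 1)
  times <- node_times(bt) # times[j + 1] = t_j, t_0 = t_1 = t_c
  q <- q_vector(2L, c(1, rep(0, M)), bt$t_c)
  k_p <- bt$k_p
  for (k in 2:k_p) {
    q <- propagate_branch(q, model, times[k + 1L], tol, tail_threshold)
    if (k < k_p) q <- apply_node(q, model, times[k + 1L])
  }
  q
}

#' Crown-survival conditioning probability
#'
#' The probability \eqn{P_c(t_c, t_p)} that both crown lineages have extant
#' descendants at the present, computed inside the framework: propagate
#' \eqn{\delta_{m,0}} with `k = 2` over the full window (no node operators)
#' and apply the weights
#' \deqn{P_c = \sum_m \frac{6}{(m+2)(m+3)}\, Q_m^{k=2}(t_p).}
#' Sampling does not enter: conditioning requires survival only, so the same
#' \eqn{P_c} divides both sampling variants.  For diversity-independent
#' rates \eqn{P_c = (1 - \xi(t_c, t_p))^2}, which serves as a cross-check.
#'
#' @param model A [rate_model].
#' @param t_c,t_p Crown age and present time.
#' @param M Truncation; `NULL` selects it by doubling until the value is
#'   stable to a relative 1e-10.
#' @param tol Solver tolerance.
#' @return Probability in `(0, 1]`.
#' @export
conditioning_probability <- function(model, t_c, t_p, M = NULL,
                                     tol = 1e-10) {
  stopifnot(inherits(model, "rate_model"))
  pc_at <- function(M) {
    q <- q_vector(2L, c(1, rep(0, M)), t_c)
    q <- propagate_branch(q, model, t_p, tol)
    ms <- 0:q$M
    sum(6 / ((ms + 2) * (ms + 3)) * q$values) * exp(q$log_scale)
  }
  if (!is.null(M)) return(min(pc_at(M), 1))
  M <- 30L
  prev <- NULL
  repeat {
    val <- tryCatch(pc_at(M), divlik_truncation_error = function(e) NULL)
    if (!is.null(val) && !is.null(prev) &&
        abs(val - prev) <= 1e-10 * max(abs(val), 1e-300)) {
      return(min(val, 1))
    }
    prev <- val
    M <- M * 2L
    if (M > 1e4) {
      stop("conditioning probability did not converge by M = 10^4",
           call. = FALSE)
    }
  }
}

# Log-likelihood at a fixed truncation; errors (divlik_truncation_error) if
# M is too small.  Returns a likelihood_result.
loglik_q_fixed <- function(model, bt, scheme, M, tol = 1e-10,
                           tail_threshold = 1e-8) {
  q <- q_at_present(model, bt, M, tol, tail_threshold)
  p_c <- conditioning_probability(model, bt$t_c, bt$t_p, M = M, tol = tol)
  if (scheme$variant == "n_sampling") {
    m_p <- scheme$m_p
    if (M < m_p) stop_truncation("truncation M below m_p")
    num <- q$values[m_p + 1L]
    if (num <= 0) {
      stop(sprintf(paste0("degenerate likelihood: Q_{m_p = %d} = 0 after ",
                          "propagation (k_p = %d, M = %d)"),
                   m_p, bt$k_p, M), call. = FALSE)
    }
    new_likelihood_result(
      log_numerator = log(num) + q$log_scale,
      log_combinatorial = lchoose(bt$k_p + m_p, m_p),
      log_conditioning = log(p_c),
      diagnostics = list(method = "q_framework_n", M = M, tol = tol,
                         tail_ratio = q$values[M + 1L] / max(q$values),
                         P_c = p_c)
    )
  } else {
    f_p <- scheme$f_p
    ms <- 0:q$M
    terms <- (1 - f_p)^ms * q$values
    p_s_scaled <- sum(terms)
    if (p_s_scaled <= 0) {
      stop("degenerate likelihood: weighted Q-sum vanished", call. = FALSE)
    }
    if (terms[M + 1L] > tol * p_s_scaled && f_p < 1) {
      stop_truncation("rho-sampling tail of (1 - f_p)^m Q_m above tolerance; increase M")
    }
    # conditioning consistent with the mass-extinction reading of
    # rho-sampling: the crown vector is thinned by the sampling operator
    # before the survival weights are applied, so the likelihood is
    # conditioned on both crown lineages having *sampled* descendants
    # (for diversity-independent rates this is (1 - xi~)^2)
    q2 <- q_vector(2L, c(1, rep(0, M)), bt$t_c)
    q2 <- propagate_branch(q2, model, bt$t_p, tol)
    thinned <- sampling_operator_apply(q2$values, f_p, k = 2L)
    ms2 <- 0:q2$M
    p_c_rho <- min(sum(6 / ((ms2 + 2) * (ms2 + 3)) * thinned) *
                     exp(q2$log_scale), 1)
    new_likelihood_result(
      log_numerator = bt$k_p * log(f_p) + log(p_s_scaled) + q$log_scale,
      log_combinatorial = 0,
      log_conditioning = log(p_c_rho),
      diagnostics = list(method = "q_framework_rho", M = M, tol = tol,
                         tail_ratio = q$values[M + 1L] / max(q$values),
                         P_c_survival = p_c, P_c = p_c_rho)
    )
  }
}

#' Apply the rho-sampling (mass-extinction) operator to a Q-vector
#'
#' The sampling step at the present is a linear operator
#' \eqn{C(f_p)} with entries
#' \eqn{C_{m,n} = \binom{n}{m} f_p^{k+m} (1 - f_p)^{n-m}}:
#' each of the `k` observed lineages is sampled (factor \eqn{f_p^k}) and of
#' the `n` missing species, `m` survive the thinning as still-missing
#' species while `n - m` become unsampled.  Row `m = 0` yields the
#' likelihood numerator weights \eqn{f_p^k (1-f_p)^n}; the full matrix is
#' needed to thin the crown vector for conditioning.
#'
#' @param values Numeric Q-vector values `Q_0 ... Q_M`.
#' @param f_p Sampling probability in `(0, 1]`.
#' @param k Observed-lineage count the vector carries.
#' @return Numeric vector of the same length.
#' @export
sampling_operator_apply <- function(values, f_p, k) {
  M <- length(values) - 1L
  out <- numeric(M + 1L)
  if (f_p == 1) return(values * rep(1, M + 1L)) # thinning is the identity up to f^k = 1
  log1mf <- log(1 - f_p)
  logf <- log(f_p)
  for (m in 0:M) {
    nn <- m:M
    # all weights assembled in log space: lchoose alone overflows for large n
    w <- exp((k + m) * logf + lchoose(nn, m) + (nn - m) * log1mf)
    out[m + 1L] <- sum(w * values[nn + 1L])
  }
  out
}

#' Choose the Q-vector truncation
#'
#' The framework's operators are infinite-dimensional; in practice the
#' missing-species dimension is truncated at `M`.  Starting from
#' `max(3 k_p, m_p + 20, 30)`, `M` is doubled until a further doubling
#' changes the log-likelihood by less than 1e-9; the probe history is
#' recorded.
#'
#' @param model A [rate_model].
#' @param bt A [branching_times] object.
#' @param scheme A [n_sampling()] or [rho_sampling()] scheme.
#' @param tol Solver tolerance used for the probes.
#' @return Integer `M`, with attribute `history` (a data frame of probed
#'   `M` and log-likelihood values).
#' @export
choose_truncation <- function(model, bt, scheme, tol = 1e-10) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  m_p <- if (scheme$variant == "n_sampling") scheme$m_p else 0L
  M <- max(3L * bt$k_p, m_p + 20L, 30L)
  probe <- function(M) {
    tryCatch(
      loglik_q_fixed(model, bt, scheme, M, tol)$log_likelihood,
      divlik_truncation_error = function(e) NA_real_
    )
  }
  hist_M <- integer(0)
  hist_ll <- numeric(0)
  ll <- probe(M)
  hist_M <- c(hist_M, M); hist_ll <- c(hist_ll, ll)
  repeat {
    M2 <- 2L * M
    if (M2 > 1e4) {
      stop("Q-vector truncation did not converge by M = 10^4", call. = FALSE)
    }
    ll2 <- probe(M2)
    hist_M <- c(hist_M, M2); hist_ll <- c(hist_ll, ll2)
    if (!is.na(ll) && !is.na(ll2) && abs(ll2 - ll) < 1e-9) {
      return(structure(M, history = data.frame(M = hist_M,
                                               log_likelihood = hist_ll)))
    }
    M <- M2
    ll <- ll2
  }
}

#' Q-framework likelihood, n-sampling
#'
#' Assembles the framework likelihood
#' \deqn{L = \frac{Q_{m_p}^{k_p}(t_p)}{\binom{k_p + m_p}{m_p} P_c(t_c, t_p)}}
#' in log space from [q_at_present()], the binomial factor for the choice of
#' the `m_p` missing species, and [conditioning_probability()].  Valid for
#' arbitrary diversity-dependent, time-dependent rate models; for the
#' diversity-independent and pure-birth special cases it agrees with the
#' analytic formulas ([loglik_div_indep_n()], [loglik_pure_birth_dd()]).
#'
#' @param model A [rate_model].
#' @param bt A [branching_times] object.
#' @param m_p Number of unsampled extant species.
#' @param M Truncation; `NULL` (default) selects it via [choose_truncation()].
#' @param tol Solver tolerance.
#' @return A `likelihood_result`.
#' @export
loglik_q_n <- function(model, bt, m_p = 0, M = NULL, tol = 1e-10) {
  scheme <- n_sampling(m_p)
  loglik_q_scheme(model, bt, scheme, M, tol)
}

#' Q-framework likelihood, rho-sampling
#'
#' The sampling-probability variant: the numerator is the weighted sum
#' \deqn{P_s = \sum_m f_p^{k_p} (1 - f_p)^m\, Q_m^{k_p}(t_p)}
#' (the `m = 0` row of the mass-extinction operator applied to the Q-vector)
#' and the likelihood is \eqn{P_s / P_c}.  At `f_p = 1` only the `m = 0`
#' term survives and the result equals [loglik_q_n()] with `m_p = 0`.
#'
#' @inheritParams loglik_q_n
#' @param f_p Sampling probability in `(0, 1]`.
#' @export
loglik_q_rho <- function(model, bt, f_p, M = NULL, tol = 1e-10) {
  scheme <- rho_sampling(f_p)
  loglik_q_scheme(model, bt, scheme, M, tol)
}

loglik_q_scheme <- function(model, bt, scheme, M, tol) {
  stopifnot(inherits(model, "rate_model"), inherits(bt, "branching_times"))
  history <- NULL
  if (is.null(M)) {
    M <- choose_truncation(model, bt, scheme, tol)
    history <- attr(M, "history")
    M <- as.integer(M)
  }
  res <- loglik_q_fixed(model, bt, scheme, M, tol)
  if (!is.null(history)) res$diagnostics$truncation_history <- history
  res
}
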