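#' Kendall auxiliary functions for time-dependent birth-death processes
#'
#' For a diversity-independent birth-death process with rates
#' \eqn{\lambda(t)}, \eqn{\mu(t)}, the distribution of the number of
#' descendants of a single lineage between times `t` and `t_p` is a
#' zero-inflated geometric law governed by two numbers: the extinction
#' probability \eqn{\xi(t, t_p)} and the geometric decay parameter
#' \eqn{\eta(t, t_p)}.  Both are built from
#' \deqn{\alpha(t, s) = \exp\Big(\int_t^s (\mu(s') - \lambda(s'))\,ds'\Big)}
#' via
#' \deqn{\xi = 1 - \frac{1}{\alpha(t, t_p) + \int_t^{t_p} \lambda \alpha\,ds}
#'           = 1 - \frac{1}{1 + \int_t^{t_p} \mu \alpha\,ds},}
#' \deqn{\eta = 1 - \frac{\alpha(t, t_p)}{\alpha(t, t_p) + \int_t^{t_p} \lambda \alpha\,ds}.}
#' For time-dependent rates, the integrals are computed by solving the
#' equivalent initial-value problem (avoiding nested quadrature); both
#' printed integral variants are evaluated and must agree to within 100x the
#' solver tolerance.  For constant rates the closed forms
#' \eqn{\xi = \mu(1 - e^{-(\lambda-\mu)\Delta}) / (\lambda - \mu e^{-(\lambda-\mu)\Delta})}
#' and \eqn{\eta = \lambda(1 - e^{-(\lambda-\mu)\Delta}) / (\lambda - \mu e^{-(\lambda-\mu)\Delta})}
#' are used, switching to the critical limit
#' \eqn{\xi = \eta = \lambda\Delta/(1 + \lambda\Delta)} when
#' \eqn{|\lambda - \mu|\Delta < 10^{-8}}.
#'
#' @param model A diversity-independent [rate_model].
#' @param t Start time.
#' @param t_p End (present) time, `t >= t_p` is rejected except equality.
#' @param tol Absolute tolerance for the auxiliary integrals.
#' @return A `kendall_pair` object: list with `xi`, `eta`, `t`, `t_p`.
#' @examples
#' kendall_xi_eta(constant_rates(0.8, 0.4), 0, 1)
#' @export
kendall_xi_eta <- function(model, t, t_p, tol = 1e-12) {
  check_di_model(model)
  check_ordered(t, t_p)
  if (t == t_p) return(new_kendall_pair(0, 0, t, t_p))
  if (model$time_independent) {
    lambda <- model$speciation(1, t)
    mu <- model$extinction(1, t)
    xe <- xi_eta_constant(lambda, mu, t_p - t)
    return(new_kendall_pair(xe[1], xe[2], t, t_p))
  }
  ivp <- kendall_integrals(model, t, t_p, tol)
  pair_from_integrals(ivp, f_p = 1, tol, t, t_p)
}

#' Kendall pair under rho-sampling
#'
#' The sampling-adjusted variants \eqn{\tilde\xi, \tilde\eta} obtained when
#' each extant species at `t_p` is sampled independently with probability
#' `f_p` (equivalently, a mass extinction of intensity \eqn{-\ln f_p} just
#' before the present):
#' \deqn{\tilde\xi = 1 - \frac{f_p}{\alpha(t,t_p) + f_p \int_t^{t_p} \lambda\alpha\,ds}, \quad
#'       \tilde\eta = 1 - \frac{\alpha(t,t_p)}{\alpha(t,t_p) + f_p \int_t^{t_p} \lambda\alpha\,ds}.}
#' At `f_p = 1` these coincide with [kendall_xi_eta()].
#'
#' @inheritParams kendall_xi_eta
#' @param f_p Sampling probability in `(0, 1]`.
#' @return A `kendall_pair`.
#' @export
kendall_xi_eta_rho <- function(model, f_p, t, t_p, tol = 1e-12) {
  check_di_model(model)
  check_ordered(t, t_p)
  if (!is.numeric(f_p) || length(f_p) != 1L || !is.finite(f_p) ||
      f_p <= 0 || f_p > 1) {
    stop("`f_p` must be a single probability in (0, 1]", call. = FALSE)
  }
  if (t == t_p) return(new_kendall_pair(0, 0, t, t_p))
  if (model$time_independent) {
    lambda <- model$speciation(1, t)
    mu <- model$extinction(1, t)
    xe <- xi_eta_rho_constant(lambda, mu, f_p, t_p - t)
    return(new_kendall_pair(xe[1], xe[2], t, t_p))
  }
  ivp <- kendall_integrals(model, t, t_p, tol)
  pair_from_integrals(ivp, f_p = f_p, tol, t, t_p)
}

new_kendall_pair <- function(xi, eta, t, t_p) {
  structure(list(xi = xi, eta = eta, t = t, t_p = t_p),
            class = "kendall_pair")
}

#' @export
print.kendall_pair <- function(x, ...) {
  cat(sprintf("<kendall_pair over [%g, %g]: xi = %.10g, eta = %.10g>\n",
              x$t, x$t_p, x$xi, x$eta))
  invisible(x)
}

check_di_model <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  if (!model$diversity_independent) {
    stop("this operation requires a diversity-independent rate model",
         call. = FALSE)
  }
  invisible(model)
}

check_ordered <- function(t, s) {
  if (t > s) stop("start time must not exceed end time", call. = FALSE)
  invisible(NULL)
}

# Closed-form constant-rate Kendall pair; critical limit when lambda ~ mu.
xi_eta_constant <- function(lambda, mu, delta) {
  r <- lambda - mu
  if (abs(r) * delta < 1e-8) {
    v <- lambda * delta / (1 + lambda * delta)
    return(c(v, v))
  }
  e <- exp(-r * delta)
  den <- lambda - mu * e
  c(mu * (1 - e) / den, lambda * (1 - e) / den)
}

# Constant-rate rho-sampling pair (Stadler-style forms); critical limit
# xi = (1 - f + f*lambda*delta)/(1 + f*lambda*delta),
# eta = f*lambda*delta/(1 + f*lambda*delta).
xi_eta_rho_constant <- function(lambda, mu, f_p, delta) {
  r <- lambda - mu
  if (abs(r) * delta < 1e-8) {
    den <- 1 + f_p * lambda * delta
    return(c((1 - f_p + f_p * lambda * delta) / den,
             f_p * lambda * delta / den))
  }
  e <- exp(-r * delta)
  den <- f_p * lambda + ((1 - f_p) * lambda - mu) * e
  c((f_p * mu + ((1 - f_p) * lambda - mu) * e) / den,
    f_p * lambda * (1 - e) / den)
}

# Solve the IVP for alpha(t, s), int lambda*alpha and int mu*alpha over
# [t, t_p]; returns c(A, I_lambda, I_mu) at s = t_p.
kendall_integrals <- function(model, t, t_p, tol = 1e-12) {
  rhs <- function(s, y, parms) {
    lam <- model$speciation(1L, s)
    mu <- model$extinction(1L, s)
    list(c((mu - lam) * y[1], lam * y[1], mu * y[1]))
  }
  sol <- deSolve::ode(
    y = c(A = 1, Il = 0, Im = 0), times = c(t, t_p), func = rhs,
    parms = NULL, method = "lsoda", rtol = tol, atol = tol * 1e-2
  )
  sol[nrow(sol), c("A", "Il", "Im")]
}

pair_from_integrals <- function(ivp, f_p, tol, t, t_p) {
  A <- ivp[["A"]]; Il <- ivp[["Il"]]; Im <- ivp[["Im"]]
  den1 <- A + f_p * Il
  den2 <- f_p + (1 - f_p) * A + f_p * Im
  xi1 <- 1 - f_p / den1
  xi2 <- 1 - f_p / den2
  eta1 <- 1 - A / den1
  eta2 <- 1 - A / den2
  if (abs(xi1 - xi2) > 100 * max(tol, 1e-14) ||
      abs(eta1 - eta2) > 100 * max(tol, 1e-14)) {
    stop(sprintf(paste0("the two integral forms of xi/eta disagree beyond ",
                        "tolerance (|dxi| = %.3g, |deta| = %.3g); ",
                        "tighten the quadrature tolerance"),
                 abs(xi1 - xi2), abs(eta1 - eta2)), call. = FALSE)
  }
  new_kendall_pair((xi1 + xi2) / 2, (eta1 + eta2) / 2, t, t_p)
}

#' Integrating factor \eqn{\alpha(t, s)}
#'
#' \eqn{\alpha(t,s) = \exp(\int_t^s (\mu(s') - \lambda(s'))\,ds')}, in closed
#' form for constant rates and by adaptive quadrature otherwise.
#'
#' @inheritParams kendall_xi_eta
#' @param s End time, `s >= t`.
#' @return Positive scalar.
#' @export
bd_alpha <- function(model, t, s, tol = 1e-12) {
  check_di_model(model)
  check_ordered(t, s)
  if (t == s) return(1)
  if (model$time_independent) {
    lambda <- model$speciation(1, t)
    mu <- model$extinction(1, t)
    return(exp((mu - lambda) * (s - t)))
  }
  integrand <- function(u) {
    vapply(u, function(ui) {
      model$extinction(1L, ui) - model$speciation(1L, ui)
    }, numeric(1))
  }
  val <- stats::integrate(integrand, t, s, rel.tol = tol,
                          abs.tol = tol, subdivisions = 2000L)
  exp(val$value)
}

#' Descendant-count distribution of a single lineage
#'
#' The probability \eqn{P_n(s, t)} that a diversity-independent process
#' started from one species at time `s` has `n` species at time `t`:
#' \eqn{P_0 = \xi(s, t)} and \eqn{P_n = (1 - \xi)(1 - \eta)\eta^{n-1}} for
#' \eqn{n \ge 1}, a zero-inflated geometric law.
#'
#' @inheritParams kendall_xi_eta
#' @param s Start time.
#' @param N Truncation: probabilities are reported for `n = 0, ..., N`.
#' @return An `occupancy_distribution`: list with `probabilities`
#'   (`P_0 ... P_N`), `s`, `t`, `truncation` and the geometric `tail_mass`
#'   \eqn{(1-\xi)\eta^N} beyond the truncation.
#' @export
single_lineage_distribution <- function(model, s, t, N, tol = 1e-12) {
  stopifnot(N >= 1)
  pair <- kendall_xi_eta(model, s, t, tol)
  n <- seq_len(N)
  p <- c(pair$xi, (1 - pair$xi) * (1 - pair$eta) * pair$eta^(n - 1))
  structure(
    list(probabilities = p, s = s, t = t, truncation = as.integer(N),
         tail_mass = (1 - pair$xi) * pair$eta^N,
         xi = pair$xi, eta = pair$eta),
    class = "occupancy_distribution"
  )
}

#' @export
print.occupancy_distribution <- function(x, ...) {
  cat(sprintf("<occupancy_distribution over [%g, %g], N = %d, tail mass %.3g>\n",
              x$s, x$t, x$truncation, x$tail_mass))
  invisible(x)
}

#' Solve the birth-death master equation
#'
#' Integrates the forward Kolmogorov system
#' \deqn{\dot P_n = \mu_{n+1}(n+1) P_{n+1} + \lambda_{n-1}(n-1) P_{n-1}
#'       - (\lambda_n + \mu_n) n P_n}
#' truncated at `n = N` (no inflow from `N + 1`), for an arbitrary
#' (diversity-dependent, time-dependent) rate model.  The truncation is
#' reflecting-at-top: probability that would flow past `N` is lost, and the
#' loss is reported so an undersized truncation is a detectable failure.
#'
#' @param model A [rate_model].
#' @param initial Nonnegative vector of probabilities over `n = 0, ..., N`
#'   (shorter vectors are zero-padded); must sum to at most 1.
#' @param t0,t1 Integration window, `t0 <= t1`.
#' @param N Truncation (largest species count tracked).
#' @param tol Solver tolerance.
#' @return Numeric vector `P_0 ... P_N` at `t1`, with attributes
#'   `tail` (final `P_N`) and `leak` (probability lost past the truncation).
#' @export
solve_master_equation <- function(model, initial, t0, t1, N, tol = 1e-10) {
  stopifnot(inherits(model, "rate_model"), N >= 1)
  check_ordered(t0, t1)
  if (any(initial < 0)) stop("`initial` must be nonnegative", call. = FALSE)
  if (sum(initial) > 1 + 1e-12) stop("`initial` must sum to at most 1", call. = FALSE)
  p0 <- rep(0, N + 1L)
  p0[seq_along(initial)] <- initial
  if (length(initial) > N + 1L) stop("`initial` longer than truncation", call. = FALSE)
  if (t0 == t1) {
    return(structure(p0, tail = p0[N + 1L], leak = 0))
  }
  ns <- 0:N
  rhs <- function(t, p, parms) {
    lam <- model$speciation(pmax(ns, 1L), t)
    mu <- model$extinction(pmax(ns, 1L), t)
    lam[1] <- 0; mu[1] <- 0 # n = 0 is absorbing
    flux_up <- lam * ns * p          # n -> n+1
    flux_down <- mu * ns * p         # n -> n-1
    dp <- -(flux_up + flux_down)
    dp[-1] <- dp[-1] + flux_up[-(N + 1L)]
    dp[-(N + 1L)] <- dp[-(N + 1L)] + flux_down[-1]
    # top state: births at n = N leave the system (reflecting closure drops them)
    list(dp)
  }
  sol <- deSolve::ode(y = p0, times = c(t0, t1), func = rhs, parms = NULL,
                      method = "lsoda", jactype = "bandint", bandup = 1L,
                      banddown = 1L, rtol = tol, atol = tol * 1e-4)
  p1 <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
  leak <- sum(p0) - sum(p1)
  tail_mass <- p1[N + 1L]
  if (tail_mass > 10 * tol) {
    stop(sprintf(paste0("master-equation truncation too small: P_N = %.3g ",
                        "exceeds 10 * tol; increase N"), tail_mass),
         call. = FALSE)
  }
  structure(p1, tail = tail_mass, leak = leak)
}
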