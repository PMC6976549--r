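# Independent oracles used across the suite.  These deliberately avoid the
# package's production code paths (series convolution, ODE propagation):
# enumeration, closed forms and convolutions written out directly.

# All compositions of m into k nonnegative parts, one per row.
enumerate_compositions <- function(m, k) {
  if (k == 1L) return(matrix(m, nrow = 1L))
  out <- NULL
  for (first in 0:m) {
    rest <- enumerate_compositions(m - first, k - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# Brute-force composition sum: sum over compositions of prod (m_j + 1) eta_j^m_j.
brute_composition_sum <- function(etas, m_p) {
  if (m_p == 0) return(1)
  comps <- enumerate_compositions(m_p, length(etas))
  sum(apply(comps, 1L, function(m) prod((m + 1) * etas^m)))
}

# Printed constant-rate closed forms for the Kendall pair, written out
# independently of the package (including the critical limit).
oracle_xi_eta_const <- function(lambda, mu, delta) {
  r <- lambda - mu
  if (abs(r) * delta < 1e-10) {
    v <- lambda * delta / (1 + lambda * delta)
    return(c(xi = v, eta = v))
  }
  e <- exp(-r * delta)
  c(xi = mu * (1 - e) / (lambda - mu * e),
    eta = lambda * (1 - e) / (lambda - mu * e))
}

oracle_xi_eta_rho_const <- function(lambda, mu, f_p, delta) {
  r <- lambda - mu
  if (abs(r) * delta < 1e-10) {
    den <- 1 + f_p * lambda * delta
    return(c(xi = (1 - f_p + f_p * lambda * delta) / den,
             eta = f_p * lambda * delta / den))
  }
  e <- exp(-r * delta)
  den <- f_p * lambda + ((1 - f_p) * lambda - mu) * e
  c(xi = (f_p * mu + ((1 - f_p) * lambda - mu) * e) / den,
    eta = f_p * lambda * (1 - e) / den)
}

# Brute-force n-sampling likelihood with explicit composition enumeration
# (log scale), for constant rates only: xi/eta from the closed-form oracle.
brute_loglik_n_const <- function(lambda, mu, bt, m_p) {
  k_p <- bt$k_p
  slot_times <- c(bt$t_c, bt$t_c, bt$internal)
  xs <- t(vapply(slot_times, function(tt) {
    oracle_xi_eta_const(lambda, mu, bt$t_p - tt)
  }, c(xi = 0, eta = 0)))
  term <- lfactorial(k_p - 1) - lchoose(k_p + m_p, m_p) +
    2 * log(1 - xs[1, "eta"])
  if (k_p > 2) {
    for (i in 3:k_p) {
      term <- term + log(lambda) + log(1 - xs[i, "xi"]) +
        log(1 - xs[i, "eta"])
    }
  }
  unname(term + log(brute_composition_sum(xs[, "eta"], m_p)))
}

# Random strictly increasing branching times on (0, t_p).
random_branching_times <- function(k_p, t_p) {
  internal <- sort(stats::runif(k_p - 2, 0.05 * t_p, 0.95 * t_p))
  while (length(internal) > 1 && min(diff(internal)) < 1e-6) {
    internal <- sort(stats::runif(k_p - 2, 0.05 * t_p, 0.95 * t_p))
  }
  branching_times(0, internal, t_p)
}

# Lineage table built by hand (for deterministic reconstruction tests).
manual_lineage_table <- function(parent, birth, death, t_c, t_p) {
  out <- tibble::tibble(
    id = seq_along(parent), parent = as.integer(parent),
    birth = as.numeric(birth), death = as.numeric(death),
    sampled = rep(NA, length(parent))
  )
  attr(out, "t_c") <- t_c
  attr(out, "t_p") <- t_p
  class(out) <- c("lineage_table", class(out))
  out
}
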