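test_that("the Q-vector right-hand side equals an explicitly built tridiagonal generator", {
  build_generator <- function(model, k, M, t) {
    V <- matrix(0, M + 1, M + 1)
    for (m in 0:M) {
      n <- k + m
      V[m + 1, m + 1] <- -(speciation_rate(model, n, t) +
                             extinction_rate(model, n, t)) * n
      if (m < M) V[m + 1, m + 2] <- extinction_rate(model, n + 1, t) * (m + 1)
      if (m > 0) V[m + 1, m] <- speciation_rate(model, n - 1, t) * (m - 1 + 2 * k)
    }
    V
  }
  set.seed(3)
  for (model in list(constant_rates(0.8, 0.4), linear_dd_rates(1, 6, 0.2))) {
    for (k in c(2L, 4L)) {
      M <- 7L
      vals <- runif(M + 1)
      q <- q_vector(k, vals, t = 1.5)
      V <- build_generator(model, k, M, 1.5)
      expect_equal(q_rhs(q, model, 1.5), as.numeric(V %*% vals),
                   tolerance = 1e-14)
    }
  }
  qz <- q_vector(3L, rep(0, 6), t = 0)
  expect_equal(q_rhs(qz, constant_rates(1, 0.5), 0), rep(0, 6))
})

test_that("branch propagation: identity at zero length, pure-birth closed form", {
  m <- constant_rates(0.9, 0.2)
  q <- q_vector(2L, c(1, rep(0, 10)), t = 1)
  expect_identical(propagate_branch(q, m, 1), q)
  # pure birth: the m = 0 equation decouples (no extinction inflow), so
  # Q_0(t) = exp(-k lambda delta) exactly; upper components fill in with the
  # unsampled-survivor configurations and are checked against the k = 2
  # generating function below
  yule <- constant_rates(0.7, 0)
  for (k in c(2L, 5L)) {
    qk <- q_vector(k, c(1, rep(0, 250)), t = 0)
    out <- propagate_branch(qk, yule, 2)
    vals <- out$values * exp(out$log_scale)
    expect_equal(vals[1], exp(-k * 0.7 * 2), tolerance = 1e-9)
  }
  # k = 2 full vector: coefficients of H^2 = (1-eta)^2 (1-z eta)^{-4}
  # (xi = 0 under pure birth), i.e. (1-eta)^2 C(m+3,3) eta^m
  q2 <- propagate_branch(q_vector(2L, c(1, rep(0, 120)), t = 0), yule, 2)
  eta <- 1 - exp(-0.7 * 2)
  want <- (1 - eta)^2 * choose((0:12) + 3, 3) * eta^(0:12)
  expect_equal((q2$values * exp(q2$log_scale))[1:13], want, tolerance = 1e-8)
})

test_that("branch propagation matches generating-function coefficients for constant rates", {
  m <- constant_rates(0.8, 0.4)
  M <- 80L
  q <- propagate_branch(q_vector(2L, c(1, rep(0, M)), t = 0), m, 1)
  bt <- branching_times(0, numeric(0), 1)
  fs <- f_series(m, bt, 1, D = M)
  got <- q$values * exp(q$log_scale)
  expect_equal(got[1:20], fs$coefficients[1:20], tolerance = 1e-8)
})

test_that("the node operator multiplies by k * lambda_{k+m} and increments k", {
  m1 <- constant_rates(1, 0.3)
  q <- q_vector(2L, c(0.3, 0.1), t = 2)
  out <- apply_node(q, m1, 2)
  expect_equal(out$values, c(0.6, 0.2))
  expect_equal(out$k, 3L)
  dd <- linear_dd_rates(1, 10, 0.1)
  out2 <- apply_node(q_vector(2L, c(1, 1), t = 2), dd, 2)
  expect_equal(out2$values, c(2 * 0.8, 2 * 0.7))
  outz <- apply_node(q_vector(4L, c(0, 0, 0), t = 1), m1, 1)
  expect_equal(outz$values, c(0, 0, 0))
})

test_that("q_at_present: pure-birth product formula and single-branch reduction", {
  dd <- linear_dd_rates(1, 10, 0)
  bt <- branching_times(0, c(1.0, 1.8), 3)
  q <- q_at_present(dd, bt, M = 12)
  vals <- q$values * exp(q$log_scale)
  # product formula for the decoupled m = 0 component:
  # prod_i i*lambda_i(t_i) * prod_j exp(-j int lambda_j)
  lam <- function(n) max(0, 1 - n / 10)
  want <- 2 * lam(2) * 3 * lam(3) *
    exp(-2 * lam(2) * 1 - 3 * lam(3) * 0.8 - 4 * lam(4) * 1.2)
  expect_equal(vals[1], want, tolerance = 1e-9)
  # k_p = 2 reduces to one branch propagation
  m <- constant_rates(0.8, 0.3)
  bt2 <- branching_times(0, numeric(0), 2)
  q1 <- q_at_present(m, bt2, M = 200)
  q2 <- propagate_branch(q_vector(2L, c(1, rep(0, 200)), t = 0), m, 2)
  expect_equal(q1$values, q2$values, tolerance = 1e-12)
  expect_equal(q1$log_scale, q2$log_scale, tolerance = 1e-12)
})

test_that("conditioning probability: pure birth saturates at 1, DI closed form holds", {
  expect_equal(conditioning_probability(constant_rates(0.9, 0), 0, 3), 1,
               tolerance = 1e-8)
  m <- constant_rates(0.8, 0.4)
  pc <- conditioning_probability(m, 0, 5)
  xi <- kendall_xi_eta(m, 0, 5)$xi
  expect_equal(pc, (1 - xi)^2, tolerance = 1e-8 * (1 - xi)^2)
  expect_true(pc > 0 && pc <= 1)
})

test_that("Q-framework and analytic likelihoods agree on small configurations", {
  bt <- branching_times(0, c(2.5, 4.0), 5)
  m <- constant_rates(0.8, 0.3)
  for (m_p in 0:2) {
    expect_equal(loglik_q_n(m, bt, m_p)$log_likelihood,
                 loglik_div_indep_n(m, bt, m_p)$log_likelihood,
                 tolerance = 1e-6)
  }
  bt2 <- branching_times(0, numeric(0), 1)
  expect_equal(loglik_q_n(constant_rates(0.8, 0), bt2, 0)$log_likelihood,
               -1.6, tolerance = 1e-8)
  dd <- linear_dd_rates(1, 12, 0)
  expect_equal(loglik_q_n(dd, bt, 0)$log_likelihood,
               loglik_pure_birth_dd(dd, bt)$log_likelihood, tolerance = 1e-8)
})

test_that("rho-sampling route: exact f_p = 1 reduction and generating-function identity", {
  m <- constant_rates(0.8, 0.3)
  bt <- branching_times(0, c(1.0, 1.9), 2.5)
  expect_equal(loglik_q_rho(m, bt, 1)$log_likelihood,
               loglik_q_n(m, bt, 0)$log_likelihood, tolerance = 1e-12)
  r <- loglik_q_rho(m, bt, 0.5)
  expect_equal(r$log_likelihood,
               loglik_div_indep_rho(m, bt, 0.5)$log_likelihood,
               tolerance = 1e-6)
  # P_s = f^{k_p} F_{k_p}(1 - f, t_p)
  M <- r$diagnostics$M
  q <- q_at_present(m, bt, M)
  p_s <- sum(0.5^bt$k_p * 0.5^(0:M) * q$values) * exp(q$log_scale)
  fs <- f_series(m, bt, bt$t_p, D = M)
  p_s_gen <- 0.5^bt$k_p * sum(0.5^(0:M) * fs$coefficients)
  expect_equal(p_s, p_s_gen, tolerance = 1e-8 * p_s_gen)
})

test_that("truncation selection: floor rules and insensitivity beyond the chosen M", {
  yule <- constant_rates(0.8, 0)
  bt <- branching_times(0, c(1), 2)
  M <- choose_truncation(yule, bt, n_sampling(0))
  expect_gte(as.integer(M), 30L)
  expect_s3_class(attr(M, "history"), "data.frame")
  M50 <- choose_truncation(yule, bt, n_sampling(50))
  expect_gte(as.integer(M50), 70L)
  m <- constant_rates(0.8, 0.4)
  bt2 <- branching_times(0, c(1.2), 3)
  Mc <- as.integer(choose_truncation(m, bt2, n_sampling(1)))
  l1 <- loglik_q_n(m, bt2, 1, M = Mc)$log_likelihood
  l2 <- loglik_q_n(m, bt2, 1, M = 2L * Mc)$log_likelihood
  expect_lt(abs(l1 - l2), 1e-9)
})

test_that("an undersized Q-vector truncation is a loud, typed failure", {
  m <- constant_rates(0.9, 0.6)
  bt <- branching_times(0, numeric(0), 5)
  expect_error(q_at_present(m, bt, M = 10), class = "divlik_truncation_error")
})
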