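#' Truncated power series
#'
#' A plain coefficient vector \eqn{c_0, \dots, c_D} in a formal variable `z`,
#' used by the generating-function oracle for the diversity-independent
#' case.  Arithmetic is ordinary floating point; the oracle never touches
#' the ODE code path, which is what makes it an independent cross-check.
#'
#' @param coefficients Numeric vector `c_0 ... c_D`.
#' @return A `truncated_series` object.
#' @keywords internal
new_truncated_series <- function(coefficients) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1,
            all(is.finite(coefficients)))
  structure(list(coefficients = coefficients,
                 degree = length(coefficients) - 1L),
            class = "truncated_series")
}

#' @export
print.truncated_series <- function(x, ...) {
  cat(sprintf("<truncated_series: degree %d>\n", x$degree))
  invisible(x)
}

#' Series coefficients of the single-branch generating function H
#'
#' \eqn{H(z, s, t) = \partial_z G(z, s, t)
#'   = (1-\xi)(1-\eta) / (1 - z\eta)^2} where `G` is the generating function
#' of the single-lineage descendant distribution; its coefficients are
#' \eqn{c_m = (1-\xi)(1-\eta)(m+1)\eta^m}.
#'
#' @param model A diversity-independent [rate_model].
#' @param s,t Start and end times, `s <= t`.
#' @param D Series degree.
#' @param tol Quadrature tolerance for the Kendall pair.
#' @return A `truncated_series` of degree `D`.
#' @export
h_series <- function(model, s, t, D, tol = 1e-12) {
  check_di_model(model)
  stopifnot(D >= 0)
  pair <- kendall_xi_eta(model, s, t, tol)
  m <- 0:D
  new_truncated_series((1 - pair$xi) * (1 - pair$eta) * (m + 1) * pair$eta^m)
}

#' Series coefficients of the tree generating function F_k
#'
#' The generating function of the Q-vector for a diversity-independent
#' model, as a product over the branches obtained by breaking the tree:
#' \deqn{F_k(z, t) = H^2(z, t_c, t) \prod_{j=2}^{k-1} j \lambda(t_j) H(z, t_j, t),}
#' computed by truncated series multiplication to degree `D`.  Coefficient
#' `m` of \eqn{F_{k_p}(z, t_p)} is \eqn{Q_m^{k_p}(t_p)}.
#'
#' @param model A diversity-independent [rate_model].
#' @param bt A [branching_times] object.
#' @param t Evaluation time (typically `bt$t_p`); must not precede the last
#'   branching time used.
#' @param k Number of branches (defaults to `bt$k_p`, using all branching
#'   times).
#' @param D Series degree.
#' @param tol Quadrature tolerance.
#' @return A `truncated_series` of degree `D`.
#' @export
f_series <- function(model, bt, t, D, k = bt$k_p, tol = 1e-12) {
  check_di_model(model)
  stopifnot(inherits(bt, "branching_times"), k >= 2, k <= bt$k_p)
  times <- node_times(bt)
  h_c <- h_series(model, bt$t_c, t, D, tol)$coefficients
  acc <- series_product(h_c, h_c, D)
  if (k > 2) {
    for (j in 2:(k - 1)) {
      t_j <- times[j + 1L]
      if (t_j > t) stop("evaluation time precedes branching time t_j", call. = FALSE)
      h_j <- h_series(model, t_j, t, D, tol)$coefficients
      lam_j <- model$speciation(1L, t_j)
      acc <- j * lam_j * series_product(acc, h_j, D)
    }
  }
  new_truncated_series(acc)
}

#' Generating-function oracle for Q-vector entries
#'
#' Extracts \eqn{Q_{m_p}^{k_p}(t_p)} as coefficient `m_p` of the series
#' [f_series()] at the present time, entirely by closed-form Kendall pairs
#' and series arithmetic.  Equals both the ODE-propagated
#' [q_at_present()] entry and the closed form
#' \eqn{(k_p-1)!\,(1-\xi_c)^2(1-\eta_c)^2 \prod \lambda (1-\xi)(1-\eta)
#' \times} composition sum, giving a three-way consistency triangle.
#'
#' @param model A diversity-independent [rate_model].
#' @param bt A [branching_times] object.
#' @param m_p Coefficient index (missing-species count).
#' @param tol Quadrature tolerance.
#' @return Scalar value of \eqn{Q_{m_p}^{k_p}(t_p)}.
#' @export
q_oracle <- function(model, bt, m_p, tol = 1e-12) {
  stopifnot(m_p >= 0, m_p == round(m_p))
  f <- f_series(model, bt, bt$t_p, D = m_p, tol = tol)
  f$coefficients[m_p + 1L]
}
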