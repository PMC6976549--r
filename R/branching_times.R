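#' Branching times of a reconstructed phylogeny
#'
#' The data the likelihood is computed from: the crown age `t_c` at which the
#' process starts from two ancestor species, the ordered internal branching
#' times \eqn{t_2 < \dots < t_{k_p - 1}} at which the reconstructed tree goes
#' from \eqn{k} to \eqn{k+1} branches, and the present time `t_p`.  The tip
#' count is \eqn{k_p = } `length(internal) + 2`.  Likelihoods in this package
#' are densities over this vector of branching times, not over topologies:
#' for the models covered here all topologies sharing the same branching
#' times are equally probable.
#'
#' The conventions \eqn{t_0 = t_1 = t_c} and \eqn{t_{k_p} = t_p} are exposed
#' by [node_times()].
#'
#' @param t_c Crown age (start of the process).
#' @param internal Strictly increasing numeric vector of internal branching
#'   times, all in `(t_c, t_p)`; may be empty (a two-tip tree).
#' @param t_p Present time, `t_p > t_c`.
#' @return A `branching_times` object with fields `t_c`, `internal`, `t_p`
#'   and the derived tip count `k_p`.
#' @examples
#' bt <- branching_times(0, c(2.5, 4.0), 5)
#' bt$k_p # 4
#' @export
branching_times <- function(t_c, internal = numeric(0), t_p) {
  stopifnot(is.numeric(t_c), length(t_c) == 1L, is.finite(t_c),
            is.numeric(t_p), length(t_p) == 1L, is.finite(t_p),
            is.numeric(internal))
  internal <- as.numeric(internal)
  if (t_p <= t_c) stop("`t_p` must be strictly greater than `t_c`", call. = FALSE)
  if (length(internal)) {
    if (any(!is.finite(internal))) stop("branching times must be finite", call. = FALSE)
    if (is.unsorted(internal, strictly = TRUE)) {
      stop("internal branching times must be strictly increasing (ties rejected)",
           call. = FALSE)
    }
    if (internal[1] <= t_c || internal[length(internal)] >= t_p) {
      stop("internal branching times must lie strictly between `t_c` and `t_p`",
           call. = FALSE)
    }
  }
  structure(
    list(t_c = t_c, internal = internal, t_p = t_p,
         k_p = length(internal) + 2L),
    class = "branching_times"
  )
}

#' Node-time vector with the crown convention
#'
#' Returns \eqn{(t_0, t_1, t_2, \dots, t_{k_p - 1}, t_{k_p})} where
#' \eqn{t_0 = t_1 = t_c} and \eqn{t_{k_p} = t_p}; element `j + 1` of the
#' result is \eqn{t_j}.
#'
#' @param bt A [branching_times] object.
#' @return Numeric vector of length `bt$k_p + 1`.
#' @export
node_times <- function(bt) {
  stopifnot(inherits(bt, "branching_times"))
  c(bt$t_c, bt$t_c, bt$internal, bt$t_p)
}

#' @export
print.branching_times <- function(x, ...) {
  cat(sprintf("<branching_times: k_p = %d, crown age %g, present %g>\n",
              x$k_p, x$t_c, x$t_p))
  if (length(x$internal)) {
    cat(" internal:", paste(signif(x$internal, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Incomplete-sampling schemes
#'
#' Two models for extant species missing from the phylogeny: `n_sampling`
#' fixes the known number `m_p` of unsampled extant species; `rho_sampling`
#' samples each extant species independently with probability `f_p`.
#'
#' @param m_p Nonnegative integer count of unsampled extant species.
#' @param f_p Sampling probability in `(0, 1]`.
#' @return A `sampling_scheme` object with field `variant` and the scheme's
#'   parameter.
#' @export
n_sampling <- function(m_p) {
  if (!is.numeric(m_p) || length(m_p) != 1L || !is.finite(m_p) ||
      m_p < 0 || m_p != round(m_p)) {
    stop("`m_p` must be a single nonnegative integer", call. = FALSE)
  }
  structure(list(variant = "n_sampling", m_p = as.integer(m_p)),
            class = "sampling_scheme")
}

#' @rdname n_sampling
#' @export
rho_sampling <- function(f_p) {
  if (!is.numeric(f_p) || length(f_p) != 1L || !is.finite(f_p) ||
      f_p <= 0 || f_p > 1) {
    stop("`f_p` must be a single probability in (0, 1]", call. = FALSE)
  }
  structure(list(variant = "rho_sampling", f_p = f_p),
            class = "sampling_scheme")
}

#' @export
print.sampling_scheme <- function(x, ...) {
  if (x$variant == "n_sampling") {
    cat(sprintf("<sampling_scheme: n-sampling, m_p = %d>\n", x$m_p))
  } else {
    cat(sprintf("<sampling_scheme: rho-sampling, f_p = %g>\n", x$f_p))
  }
  invisible(x)
}
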