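#' Exact stochastic simulation of the diversification process
#'
#' Gillespie simulation of the (diversity-dependent, time-dependent)
#' birth-death process started from a crown of two species at `t_c`, run to
#' the present `t_p`.  With `n` species the total event rate is
#' \eqn{n(\lambda_n(t) + \mu_n(t))}; time-independent models use exact
#' exponential waiting times, time-dependent models use thinning (rejection)
#' against a per-interval envelope taken as 1.2 times the maximum of the
#' total rate over a bracketing grid, refreshed after every event.
#'
#' @param model A [rate_model].
#' @param t_c,t_p Crown age and present time.
#' @param seed Optional integer seed for reproducibility.
#' @return A `lineage_table`: a tibble with one row per lineage and columns
#'   `id`, `parent` (`NA` for the two crown lineages), `birth`, `death`
#'   (`NA` if extant at `t_p`) and `sampled` (`NA` until a sampling scheme
#'   is applied by [reconstruct_tree()]); attributes `t_c` and `t_p`.
#' @export
simulate_complete_tree <- function(model, t_c, t_p, seed = NULL) {
  stopifnot(inherits(model, "rate_model"), t_p > t_c)
  if (!is.null(seed)) set.seed(seed)
  core <- sim_core(model, t_c, t_p)
  out <- tibble::tibble(
    id = seq_along(core$parent),
    parent = core$parent,
    birth = core$birth,
    death = core$death,
    sampled = rep(NA, length(core$parent))
  )
  attr(out, "t_c") <- t_c
  attr(out, "t_p") <- t_p
  class(out) <- c("lineage_table", class(out))
  out
}

# Bare-vectors Gillespie core (kept lean: it is run 10^4+ times in the
# simulation-closure checks).
sim_core <- function(model, t_c, t_p) {
  cap <- 16L
  parent <- rep(NA_integer_, cap)
  birth <- rep(NA_real_, cap)
  death <- rep(NA_real_, cap)
  parent[1:2] <- NA_integer_
  birth[1:2] <- t_c
  n_lin <- 2L
  alive <- c(1L, 2L)
  n_alive <- 2L
  t <- t_c
  spec <- model$speciation
  ext <- model$extinction
  time_indep <- model$time_independent
  repeat {
    if (n_alive == 0L) break
    n <- n_alive
    if (time_indep) {
      lam <- spec(n, t)
      mu <- ext(n, t)
      total <- n * (lam + mu)
      if (total <= 0) break
      t_ev <- t + stats::rexp(1L, total)
      if (t_ev > t_p) break
    } else {
      grid <- seq(t, t_p, length.out = 33L)
      env_rate <- 1.2 * max(vapply(grid, function(u) {
        n * (spec(n, u) + ext(n, u))
      }, numeric(1)))
      if (!is.finite(env_rate)) {
        stop("unbounded total event rate over the simulation window",
             call. = FALSE)
      }
      if (env_rate <= 0) break
      t_ev <- t
      accepted <- FALSE
      repeat {
        t_ev <- t_ev + stats::rexp(1L, env_rate)
        if (t_ev > t_p) break
        rate <- n * (spec(n, t_ev) + ext(n, t_ev))
        if (rate > env_rate) {
          stop("thinning envelope violated: rate exceeds bracketing-grid bound",
               call. = FALSE)
        }
        if (stats::runif(1L) < rate / env_rate) { accepted <- TRUE; break }
      }
      if (!accepted) break
      lam <- spec(n, t_ev)
      mu <- ext(n, t_ev)
    }
    t <- t_ev
    idx <- alive[sample.int(n_alive, 1L)]
    if (stats::runif(1L) < lam / (lam + mu)) {
      # speciation: new lineage branches off idx
      n_lin <- n_lin + 1L
      if (n_lin > cap) {
        cap <- cap * 2L
        length(parent) <- cap
        length(birth) <- cap
        length(death) <- cap
      }
      parent[n_lin] <- idx
      birth[n_lin] <- t
      n_alive <- n_alive + 1L
      alive[n_alive] <- n_lin
    } else {
      death[idx] <- t
      pos <- match(idx, alive[seq_len(n_alive)])
      alive[pos] <- alive[n_alive]
      n_alive <- n_alive - 1L
    }
  }
  list(parent = parent[seq_len(n_lin)], birth = birth[seq_len(n_lin)],
       death = death[seq_len(n_lin)])
}

# For each lineage: does it have a descendant (including itself) with
# flag == TRUE?  Children are born after their parents, so a single reverse
# sweep over birth order suffices.
descendant_flag <- function(parent, birth, flag) {
  out <- flag
  for (i in order(birth, decreasing = TRUE)) {
    if (out[i] && !is.na(parent[i])) out[parent[i]] <- TRUE
  }
  out
}

#' Prune a simulated tree to its sampled, reconstructed form
#'
#' Applies a sampling scheme at the present (n-sampling drops a uniformly
#' chosen subset of the stated size; rho-sampling thins each extant species
#' independently with probability `f_p`), prunes all lineages without
#' sampled descendants, and returns the branching times of the reconstructed
#' tree.  Replicates where fewer than two species are sampled, or where a
#' crown lineage has no sampled descendant, are flagged rather than silently
#' resampled, as is an n-sampling request exceeding the extant count.
#'
#' @param table A `lineage_table` from [simulate_complete_tree()].
#' @param scheme A [n_sampling()] or [rho_sampling()] scheme.
#' @param seed Optional integer seed for the sampling draw.
#' @return A list with `status` (`"ok"`, `"extinct"`, or `"infeasible"`);
#'   on success also `bt` (a [branching_times]), `k_p`, `m_p_realized`
#'   (unsampled extant species) and `table` (the lineage table with the
#'   `sampled` column filled in); otherwise `reason`.
#' @export
reconstruct_tree <- function(table, scheme, seed = NULL) {
  stopifnot(inherits(table, "lineage_table"), inherits(scheme, "sampling_scheme"))
  if (!is.null(seed)) set.seed(seed)
  t_c <- attr(table, "t_c")
  t_p <- attr(table, "t_p")
  parent <- table$parent
  birth <- table$birth
  death <- table$death
  extant <- is.na(death)
  n_extant <- sum(extant)
  sampled <- extant
  if (scheme$variant == "n_sampling") {
    if (scheme$m_p >= n_extant) {
      return(list(status = "infeasible",
                  reason = sprintf("m_p = %d >= extant count %d",
                                   scheme$m_p, n_extant)))
    }
    if (scheme$m_p > 0) {
      drop <- sample(which(extant), scheme$m_p)
      sampled[drop] <- FALSE
    }
  } else {
    keep <- stats::runif(n_extant) < scheme$f_p
    sampled[which(extant)] <- keep
  }
  k_p <- sum(sampled)
  if (k_p < 2L) {
    return(list(status = "extinct", reason = "fewer than 2 sampled tips"))
  }
  sdesc <- descendant_flag(parent, birth, sampled)
  roots <- which(is.na(parent))
  if (!all(sdesc[roots])) {
    return(list(status = "extinct",
                reason = "a crown lineage has no sampled descendant"))
  }
  # a speciation event (child c born at b from parent p) is a node of the
  # reconstructed tree iff both the child clade and the parent's
  # continuation after b retain sampled descendants
  node_times <- numeric(0)
  for (c_idx in which(!is.na(parent) & sdesc)) {
    b <- birth[c_idx]
    p <- parent[c_idx]
    after <- sampled[p] ||
      any(sdesc & !is.na(parent) & parent == p & birth > b)
    if (after) node_times <- c(node_times, b)
  }
  table$sampled <- sampled
  list(
    status = "ok",
    bt = branching_times(t_c, sort(node_times), t_p),
    k_p = k_p,
    m_p_realized = n_extant - k_p,
    table = table
  )
}

#' Monte-Carlo crown survival fraction
#'
#' Fraction of simulated replicates in which both crown lineages have at
#' least one extant descendant at the present (sampling is ignored: the
#' conditioning used throughout the package requires survival only).  This
#' is the stochastic counterpart of [conditioning_probability()].
#'
#' @param model A [rate_model].
#' @param t_c,t_p Crown age and present time.
#' @param replicates Number of independent replicates (at least 100).
#' @param seed Root seed; replicate `r` uses a substream derived from it by
#'   counter, so any replicate is reproducible in isolation.
#' @return A list with `fraction`, its Monte-Carlo `se`, and `replicates`.
#' @export
survival_fraction <- function(model, t_c, t_p, replicates = 1000L,
                              seed = 1L) {
  stopifnot(replicates >= 100)
  hits <- 0L
  for (r in seq_len(replicates)) {
    set.seed(substream_seed(seed, r))
    core <- sim_core(model, t_c, t_p)
    extant <- is.na(core$death)
    if (!any(extant)) next
    edesc <- descendant_flag(core$parent, core$birth, extant)
    roots <- which(is.na(core$parent))
    if (all(edesc[roots])) hits <- hits + 1L
  }
  p <- hits / replicates
  list(fraction = p, se = sqrt(p * (1 - p) / replicates),
       replicates = replicates)
}

substream_seed <- function(seed, r) {
  (as.numeric(seed) * 48271 + as.numeric(r)) %% 2147483647
}

#' Serialize a lineage table as Newick
#'
#' `mode = "complete"` writes the full tree, including extinct lineages
#' (tips of extinct lineages end at their extinction time, so the tree is
#' not ultrametric).  `mode = "reconstructed"` prunes to sampled tips and is
#' ultrametric: every tip sits at depth `t_p - t_c`.  Tip labels are
#' `t<id>`.
#'
#' @param table A `lineage_table`; for reconstructed mode the `sampled`
#'   column must be filled (e.g. by [reconstruct_tree()]); if it is all
#'   `NA`, every extant species is treated as sampled.
#' @param mode `"complete"` or `"reconstructed"`.
#' @return A single Newick string (with trailing `;`).
#' @export
write_newick <- function(table, mode = c("reconstructed", "complete")) {
  stopifnot(inherits(table, "lineage_table"))
  mode <- match.arg(mode)
  t_c <- attr(table, "t_c")
  t_p <- attr(table, "t_p")
  parent <- table$parent
  birth <- table$birth
  death <- table$death
  extant <- is.na(death)
  end_time <- ifelse(extant, t_p, death)
  if (mode == "reconstructed") {
    sampled <- table$sampled
    if (all(is.na(sampled))) sampled <- extant
    sampled[is.na(sampled)] <- FALSE
    keep <- descendant_flag(parent, birth, sampled)
    tip_flag <- sampled
  } else {
    keep <- rep(TRUE, length(parent))
    tip_flag <- rep(TRUE, length(parent))
  }
  roots <- which(is.na(parent))
  if (!all(keep[roots])) {
    stop("cannot write reconstructed tree: a crown lineage has no sampled descendant",
         call. = FALSE)
  }
  kids_of <- function(p, from) {
    idx <- which(!is.na(parent) & parent == p & birth > from & keep)
    idx[order(birth[idx])]
  }
  rec <- function(l, from) {
    kids <- kids_of(l, from)
    if (!length(kids)) {
      return(list(str = paste0("t", l), time = end_time[l]))
    }
    c1 <- kids[1]
    u1 <- birth[c1]
    rest_has <- length(kids) > 1L || tip_flag[l]
    if (!rest_has) {
      return(rec(c1, u1)) # branch passes through an unobserved split
    }
    left <- rec(l, u1)
    right <- rec(c1, u1)
    list(str = sprintf("(%s:%.12g,%s:%.12g)",
                       left$str, left$time - u1,
                       right$str, right$time - u1),
         time = u1)
  }
  a <- rec(roots[1], t_c)
  b <- rec(roots[2], t_c)
  sprintf("(%s:%.12g,%s:%.12g);", a$str, a$time - t_c, b$str, b$time - t_c)
}
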