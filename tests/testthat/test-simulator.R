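# k(t) for a lineage table: number of lineages alive at t that are ancestral
# to at least one sampled tip, computed recursively (independent of the
# package's reverse-sweep implementation).
ltt_counts <- function(tab, t) {
  parent <- tab$parent; birth <- tab$birth; death <- tab$death
  sampled <- tab$sampled
  sampled[is.na(sampled)] <- FALSE
  leads_to_sample <- function(l, from) {
    if (sampled[l]) return(TRUE)
    kids <- which(!is.na(parent) & parent == l & birth > from)
    for (k in kids) if (leads_to_sample(k, birth[k])) return(TRUE)
    FALSE
  }
  alive <- which(birth <= t & (is.na(death) | death > t))
  k <- sum(vapply(alive, function(l) leads_to_sample(l, t), logical(1)))
  c(n = length(alive), k = k)
}

test_that("simulation is reproducible under a seed and grows from the crown pair", {
  m <- constant_rates(0.8, 0.4)
  a <- simulate_complete_tree(m, 0, 4, seed = 11)
  b <- simulate_complete_tree(m, 0, 4, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(sum(is.na(a$parent)), 2L)
  expect_equal(a$birth[1:2], c(0, 0))
  expect_true(all(a$birth[-(1:2)] > 0))
  ok <- !is.na(a$death)
  expect_true(all(a$death[ok] > a$birth[ok]))
  expect_true(all(a$birth <= 4) && all(a$death[ok] <= 4))
})

test_that("a pure-birth simulation never drops below the two crown lineages", {
  yule <- constant_rates(0.9, 0)
  for (s in 1:5) {
    tab <- simulate_complete_tree(yule, 0, 2, seed = s)
    expect_gte(sum(is.na(tab$death)), 2L)
  }
})

test_that("observed and missing lineages partition the total: k(t) + m(t) = n(t)", {
  m <- constant_rates(0.9, 0.45)
  tab <- simulate_complete_tree(m, 0, 4, seed = 25)
  rec <- reconstruct_tree(tab, rho_sampling(0.7), seed = 5)
  expect_equal(rec$status, "ok") # this seed yields a surviving, sampled tree
  tab2 <- rec$table
  for (t in c(0.5, 1.5, 2.5, 3.5)) {
    cnt <- ltt_counts(tab2, t)
    expect_gte(cnt[["k"]], 0)
    expect_lte(cnt[["k"]], cnt[["n"]])
  }
  # at the present, k equals the number of sampled tips
  cnt_p <- ltt_counts(tab2, 4 - 1e-9)
  expect_equal(cnt_p[["k"]], rec$k_p)
})

test_that("reconstruction recovers the complete tree when nothing is pruned", {
  yule <- constant_rates(1.1, 0)
  tab <- simulate_complete_tree(yule, 0, 1.5, seed = 2)
  rec <- reconstruct_tree(tab, n_sampling(0))
  expect_equal(rec$status, "ok")
  expect_equal(rec$k_p, sum(is.na(tab$death)))
  expect_equal(rec$m_p_realized, 0L)
  expect_equal(rec$bt$internal, sort(tab$birth[-(1:2)]), tolerance = 1e-12)
  # rho-sampling with f_p = 1 is the same reconstruction
  rec2 <- reconstruct_tree(tab, rho_sampling(1))
  expect_equal(rec2$bt$internal, rec$bt$internal)
})

test_that("extinct and infeasible replicates are flagged, not resampled", {
  # hand-built table: crown pair, one extinct child; only lineage 1 survives
  tab <- manual_lineage_table(
    parent = c(NA, NA, 1),
    birth = c(0, 0, 1),
    death = c(NA, 2.5, 2),
    t_c = 0, t_p = 3
  )
  rec <- reconstruct_tree(tab, n_sampling(0))
  expect_equal(rec$status, "extinct")
  expect_match(rec$reason, "sampled")
  # two survivors but m_p exhausts them
  tab2 <- manual_lineage_table(
    parent = c(NA, NA), birth = c(0, 0), death = c(NA, NA),
    t_c = 0, t_p = 3
  )
  expect_equal(reconstruct_tree(tab2, n_sampling(2))$status, "infeasible")
  expect_equal(reconstruct_tree(tab2, n_sampling(1))$status, "extinct")
})

test_that("unsampled-but-surviving side branches are pruned from the branching times", {
  # crown pair; lineage 3 splits from 1 at t = 1 and survives but is unsampled
  tab <- manual_lineage_table(
    parent = c(NA, NA, 1),
    birth = c(0, 0, 1),
    death = c(NA, NA, NA),
    t_c = 0, t_p = 3
  )
  tab$sampled <- c(TRUE, TRUE, FALSE)
  # force the n-sampling draw to drop lineage 3: m_p = 1 and check both cases
  set.seed(1)
  statuses <- replicate(40, {
    r <- reconstruct_tree(tab, n_sampling(1))
    if (r$status != "ok") return("dead")
    paste(r$k_p, length(r$bt$internal))
  })
  # whenever reconstruction succeeds with k_p = 2, the t = 1 split is gone
  expect_true(all(statuses %in% c("dead", "2 0")))
})

test_that("Newick output: minimal tree, ultrametric reconstructed mode, round trip", {
  tab <- manual_lineage_table(
    parent = c(NA, NA), birth = c(0, 0), death = c(NA, NA),
    t_c = 0, t_p = 2.5
  )
  expect_equal(write_newick(tab, "reconstructed"), "(t1:2.5,t2:2.5);")
  m <- constant_rates(0.9, 0.4)
  tab2 <- simulate_complete_tree(m, 0, 3, seed = 31)
  rec <- reconstruct_tree(tab2, n_sampling(0))
  expect_equal(rec$status, "ok")
  nwk <- write_newick(rec$table, "reconstructed")
  phy <- ape::read.tree(text = nwk)
  depths <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
  expect_lt(max(depths) - min(depths), 1e-9)
  bt_rt <- branching_times_from_newick(nwk)
  expect_equal(bt_rt$internal, rec$bt$internal, tolerance = 1e-9)
  expect_equal(bt_rt$t_p - bt_rt$t_c, 3, tolerance = 1e-9)
  # complete mode keeps extinct tips at their death times (non-ultrametric)
  if (any(!is.na(tab2$death))) {
    phy_c <- ape::read.tree(text = write_newick(tab2, "complete"))
    d_c <- ape::node.depth.edgelength(phy_c)[seq_len(ape::Ntip(phy_c))]
    expect_gt(max(d_c) - min(d_c), 1e-6)
  }
})

test_that("survival fraction: certainty under pure birth, agreement with P_c", {
  yule <- constant_rates(0.8, 0)
  s <- survival_fraction(yule, 0, 1.5, replicates = 150, seed = 4)
  expect_equal(s$fraction, 1)
  m <- constant_rates(0.8, 0.4)
  s2 <- survival_fraction(m, 0, 3, replicates = 2000, seed = 9)
  pc <- conditioning_probability(m, 0, 3)
  expect_lt(abs(s2$fraction - pc), 3 * s2$se)
})

test_that("Yule tip counts follow the two-lineage geometric convolution", {
  lam <- log(2)
  yule <- constant_rates(lam, 0)
  reps <- 2000L
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    set.seed(100000 + r)
    tab <- divlik:::sim_core(yule, 0, 1.5)
    counts[r] <- sum(is.na(tab$death))
  }
  ana <- single_lineage_distribution(yule, 0, 1.5, 120)$probabilities
  conv <- vapply(0:120, function(n) {
    sum(ana[(0:n) + 1L] * ana[(n:0) + 1L])
  }, numeric(1))
  tabn <- tabulate(counts, nbins = 121)  # counts >= 1; index n
  expected <- conv[-1] * reps
  keep <- expected >= 5
  obs <- c(tabn[keep], reps - sum(tabn[keep]))
  exps <- c(expected[keep], reps - sum(expected[keep]))
  gof <- suppressWarnings(stats::chisq.test(obs, p = exps / sum(exps)))
  expect_gt(gof$p.value, 1e-3)
})
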