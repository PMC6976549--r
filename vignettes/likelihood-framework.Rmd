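---
title: "The diversification likelihood framework in divlik: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The diversification likelihood framework in divlik}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`divlik` computes likelihoods of *branching-time vectors* of ultrametric
reconstructed phylogenies under birth–death diversification models.  The
process starts at the crown age $t_c$ from two ancestor species and runs to
the present $t_p$ (time increases from past to present throughout).  With
$n$ species present, each speciates at per-species rate $\lambda_n(t)$ and
goes extinct at rate $\mu_n(t)$; the species-count distribution obeys the
forward Kolmogorov (master) equation

$$\dot P_n = \mu_{n+1}(n+1)P_{n+1} + \lambda_{n-1}(n-1)P_{n-1}
           - (\lambda_n + \mu_n)\,n P_n .$$

The data are the tip count $k_p$, the ordered branching times
$t_2 < \dots < t_{k_p-1}$ (the time at which the reconstructed tree goes
from $k$ to $k+1$ branches), and a sampling scheme: either a known number
$m_p$ of unsampled extant species (*n-sampling*) or an independent
per-species sampling probability $f_p$ (*ρ-sampling*).  Topologies are
deliberately ignored: for the model families covered, all topologies with
the same branching times are equally probable, so the likelihood is a
density over the branching-time vector.  The reported values are densities
with the time differentials dropped, the convention used across this model
family; users comparing against simulation histograms must apply bin widths
themselves.

Conditioning follows standard practice: the likelihood is divided by the
probability $P_c(t_c, t_p)$ that both crown lineages have extant
descendants at the present (survival, not sampled survival — with one
deliberate exception for ρ-sampling discussed below).

# The Q-vector framework

The central object is $Q^k_m(t)$, proportional to the probability that a
realization of the process is consistent with the phylogeny up to time $t$
and carries $k$ observed lineages plus $m$ *missing* species (extinct-to-be
or unsampled).  Missing species cannot be ignored under diversity
dependence: they feed back on the rates.  Along a branch interval the
vector obeys a tridiagonal linear ODE system (`q_rhs()`), at each branching
time the diagonal node operator $Q_m \leftarrow k\,\lambda_{k+m}(t_k)Q_m$
fires (`apply_node()`; the factor $k$ because no topology is specified),
and the chain starts from $Q^{k=2}_m(t_c) = \delta_{m,0}$: no missing
species at crown age.  The n-sampling likelihood is

$$L = \frac{Q^{k_p}_{m_p}(t_p)}{\binom{k_p+m_p}{m_p} P_c(t_c,t_p)},
\qquad
P_c = \sum_m \frac{6}{(m+2)(m+3)} Q^{k=2}_m(t_p),$$

where the $P_c$ weights are the probability that a uniformly chosen
labelled pair among $m+2$ exchangeable survivors consists of the two crown
lineages' descendants.

Two remarks that shaped the implementation and its tests:

* **Pure birth does not empty the upper components.**  With $\mu = 0$ the
  inflow $\lambda_{k+m-1}(m-1+2k)Q_{m-1}$ still populates $m > 0$; those
  components encode configurations with unsampled survivors and matter for
  $m_p > 0$ and ρ-sampling.  What *is* special about pure birth is that the
  $m = 0$ equation decouples, $\dot Q_0 = -k\lambda_k Q_0$, which yields
  the closed-form product likelihood for the fully sampled pure-birth case.
* **Whether individual $Q^k_m$ are probabilities is not relied upon.**  The
  code asserts nonnegativity and finiteness, never $\le 1$; all results are
  ratios in which the normalization cancels.

## ρ-sampling and its conditioning

ρ-sampling is equivalent to a mass extinction of intensity $-\ln f_p$
concentrated just before the present.  The corresponding operator on the
Q-vector is $C_{m,n}(f_p) = \binom{n}{m} f_p^{k+m}(1-f_p)^{n-m}$
(`sampling_operator_apply()`); its $m = 0$ row gives the numerator
$P_s = \sum_m f_p^{k_p}(1-f_p)^m Q^{k_p}_m(t_p)$.

The conditioning for this variant is a genuinely open design point: one can
divide by the survival-only $P_c$ above, or by the probability that both
crown lineages have *sampled* descendants.  The two differ by
$[(1-\xi_c)/(1-\tilde\xi_c)]^2$, which is far from negligible (about 0.10
in log-likelihood at $\lambda=0.8$, $\mu=0.3$, $\Delta=5$, $f_p=0.5$).
`divlik` conditions the ρ-variant on **sampled** crown survival, computed
inside the framework by thinning the crown vector with the full $C(f_p)$
operator before applying the $P_c$ weights.  This choice is the one
consistent with the mass-extinction construction itself (the thinning is
part of the process, so survival means surviving it), it reproduces the
standard constant-rate ρ-sampling likelihood in the literature exactly, and
it makes the package's analytic and ODE routes agree to solver precision —
the survival-only alternative provably cannot.  The survival-only $P_c$ is
still reported in the result diagnostics for users who prefer to
recondition.  At $f_p = 1$ the two choices coincide and the ρ-route equals
the n-sampling route with $m_p = 0$ exactly.

# Analytical special cases

For diversity-independent rates everything reduces to the two Kendall
functions of the single-lineage descendant distribution,
$\xi(t,t_p)$ (extinction probability) and $\eta(t,t_p)$ (geometric decay),
built from $\alpha(t,s) = \exp\int_t^s(\mu-\lambda)$.  The package
evaluates both printed integral forms (the $\lambda$-integral and the
$\mu$-integral variants) by solving one initial-value problem for
$(\alpha, \int\lambda\alpha, \int\mu\alpha)$ — avoiding $O(n^2)$ nested
quadrature — and raises a consistency error if they disagree beyond 100×
the solver tolerance.  Constant rates use the closed forms, switching to
the analytic limit $\xi = \eta = \lambda\Delta/(1+\lambda\Delta)$ when
$|\lambda-\mu|\Delta < 10^{-8}$, where the printed expressions are 0/0.
The missing-species sum over all ways to distribute $m_p$ species over the
broken-tree branches is evaluated as the coefficient of $z^{m_p}$ in
$\prod_j (1-\eta_j z)^{-2}$ by truncated series convolution,
$O(k_p m_p^2)$, with exhaustive enumeration retained only as a test oracle.

The pure-birth diversity-dependent likelihood multiplies
$\exp(-j\int_{t_{j-1}}^{t_j}\lambda_j)$ survival factors over the
inter-node intervals; time-constant rates take the exact product
$\lambda_j (t_j - t_{j-1})$, time-dependent ones adaptive quadrature.

# The generating-function oracle

An independent route to the same numbers, used to validate the ODE path
without sharing code with it: the generating function of the Q-vector for
diversity-independent rates factorizes into
$H^2(z,t_c,t)\prod_j j\lambda(t_j)H(z,t_j,t)$ with
$H = (1-\xi)(1-\eta)/(1-z\eta)^2$, whose coefficients are known in closed
form.  Truncated series products (`f_series()`) then deliver any
$Q^{k_p}_{m_p}(t_p)$ by coefficient extraction (`q_oracle()`).  The test
suite closes a three-way triangle — ODE propagation, series coefficients,
closed form with composition sums — pairwise to $10^{-8}$ relative.

# Numerical choices

* **Truncation.**  The missing-species dimension is truncated at $M$;
  closure is reflecting-at-top (no inflow from $M+1$; outflow past $M$ is
  lost and surfaces as a diagnostic).  After every branch propagation the
  ratio $Q_M / \max_m Q_m$ must stay below $10^{-8}$, otherwise a typed
  truncation error asks for a larger $M$.  `choose_truncation()` starts at
  $\max(3k_p, m_p+20, 30)$ and doubles until one further doubling moves the
  log-likelihood by less than $10^{-9}$, recording the probe history.  Near
  criticality with old crowns $\eta \to 1$ and $M$ can reach $\sim 10^3$;
  the geometric tail makes this benign but not free.
* **Stiff solver with banded structure.**  The generator is tridiagonal, so
  branches are integrated with `deSolve::ode` (lsoda, `jactype = "bandint"`,
  bandwidth 1), relative tolerance $10^{-10}$ and absolute tolerance
  $10^{-16}$ *after* rescaling each branch start to maximum 1; the true
  magnitude lives in a `log_scale` accumulator, which prevents underflow on
  old or species-rich trees.  Matrix exponentials are never formed.
* **Log-space accumulation** everywhere: factorials via `lfactorial`,
  binomials via `lchoose`, products as sums of logs.  The thinning weights
  $\binom{n}{m}f^{k+m}(1-f)^{n-m}$ are assembled fully in log space —
  `choose(1900, 900)` alone overflows double precision.
* **Quadrature tolerances** default to $10^{-12}$ (Kendall IVPs and
  pure-birth integrals); there is no externally mandated precision for the
  cross-route agreement, so these defaults are the package's own choice,
  surfaced in the configuration.
* **Degenerate inputs**: zero-length branches return their input unchanged;
  tied branching times are rejected at construction; $f_p = 1$ and
  $m_p = 0$ reduce by construction, not by special-cased arithmetic.

# The simulator and what the tests do (and do not) show

`simulate_complete_tree()` is an exact Gillespie simulation from the crown:
with $n$ species the total event rate is $n(\lambda_n + \mu_n)$;
time-independent models use exponential waiting times, time-dependent ones
thinning against an envelope of 1.2× the maximum total rate over a
33-point bracketing grid, refreshed after every event and checked at every
acceptance (an envelope violation is an error, not a silent bias).
Reconstruction applies the sampling scheme at the present (n-sampling drops
a fixed-size uniform subset, matching its definition; infeasible draws are
flagged, never silently resampled) and prunes lineages without sampled
descendants.  Replicates use substreams derived from one root seed by
counter, so any replicate is reproducible in isolation.

The simulation-closure checks run at $\lambda = 0.8$, $\mu = 0.4$,
$\Delta = 5$ (mean diversity $2e^{(\lambda-\mu)\Delta} \approx 14.8$):
crown survival against the framework's $P_c$ within 3 Monte-Carlo standard
errors at $10^4$ replicates, the occupancy histogram against the master
equation by a $\chi^2$ test at significance $10^{-3}$, and the mean against
the first-moment equation.  The randomized equivalence suites use 200
diversity-independent configurations ($\lambda \in [0.1,1]$,
$\mu \le 0.9\lambda$, $k_p \in 2..6$, $m_p \in 0..4$, crown ages up to 4)
and 50 pure-birth diversity-dependent trees; these sizes keep the default
suite at a few minutes while leaving the tolerances ($10^{-6}$, $10^{-8}$)
far above solver noise.

What these tests show: the implementation of the framework agrees with
independently derived formulas wherever such formulas exist, and the
simulator realizes the same process the equations describe.  What they do
not show: that the framework is exact for diversity-dependent models *with*
extinction — no analytical formula exists there, the equivalences cover
only the proven special cases, and the package makes no stronger claim.
Synthetic trees are clean by construction: no dating error, no topological
uncertainty, no rate heterogeneity across lineages — agreement here says
nothing about robustness to those features of real data.

## Parameter-recovery check

The recovery study simulates 100 Yule trees at $\lambda = 0.8$ and asks the
per-tree grid-search MLE under the n-sampling likelihood ($\mu$ fixed at 0,
$m_p = 0$, grid step 0.005) to average within 10% of truth.  The crown age
is set to 4 ($E[k_p] \approx 49$) deliberately: the crown Yule MLE
$(k_p-2)/\mathrm{TBL}$ carries an intrinsic finite-size bias of roughly
$-2/E[k_p]$, because the two crown branches contribute branch length but no
counted speciation event.  At $E[k_p] \approx 22$ that bias alone is
$\approx -9.5\%$ and the check would measure the estimator, not the
implementation; at $E[k_p] \approx 49$ it is $\approx -4\%$, leaving the
10% budget to detect genuine likelihood errors.

# Known limitations

* Crown start only: stem-age starts and stem conditioning are out of scope,
  as are conditioning on $k_p$ and missing species already present at the
  crown age.
* Rates may depend on diversity and time, not on lineage age, traits or
  environments; extinction is Markovian.
* The master-equation and Q-vector truncations are finite; both fail loudly
  rather than approximately when undersized, but very old, near-critical
  trees can demand large $M$.
* The CLI's `compare` and `validate` subcommands and the grid-search MLE in
  the test suite are diagnostics, not an inference interface; no standard
  errors or model selection are provided.
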