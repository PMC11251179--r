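---
title: "Stochastic journeys of cells across compartment chains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic journeys of cells across compartment chains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellchains)
```

## The model

`cellchains` implements a continuous-time Markov model of a cell population
distributed over an ordered chain of compartments $C_1, \ldots, C_N$. A
compartment is a set of cells sharing a phenotype or location, and therefore
identical per-cell event rates. Each cell in $C_i$ can, independently of all
others:

* **self-renew** at rate $\lambda_i$ — both daughters stay in $C_i$
  (population change $+1$ in $C_i$);
* **divide symmetrically** at rate $s_i$ — both daughters move on
  ($-1$ in $C_i$, $+2$ in $C_{i+1}$);
* **divide asymmetrically** at rate $a_i$ — one daughter stays, one moves on
  ($+1$ in $C_{i+1}$);
* **differentiate** forwards at rate $\nu_i$ or backwards at rate $\xi_i$
  (one cell moves between adjacent compartments);
* **die** at rate $\mu_i$.

Cells in the terminal compartment cannot divide symmetrically or
asymmetrically, nor differentiate forwards, and cells in the first
compartment cannot differentiate backwards; the constructor forces
$s_N = a_N = \nu_N = \xi_1 = 0$. The *irreversible* model is the special
case $\xi_i = 0$ everywhere. All rates carry the reciprocal of whatever time
unit the user adopts; the shipped presets are per day.

Two composite rates organise every analytic result: the **net loss rate**
$\Delta_i = \mu_i + \nu_i + s_i + \xi_i - \lambda_i$ and the **forward
flux** $\Lambda_i = \nu_i + a_i + 2 s_i$. Some published parameterisations
(the hematopoietic preset among them) report only $(\Delta, \Lambda)$, from
which the six per-event rates are not identifiable; `reduced_model()` exists
for exactly that situation. Operations that genuinely need the raw rates —
progeny statistics, lifeline statistics, stochastic simulation — refuse a
reduced model with an explanatory error rather than inventing a
decomposition.

A compartment whose rates are all zero is *inert*: cells reaching it
accumulate and undergo no further events. This is how the four-compartment
presets encode their terminal compartment, and the analytic machinery treats
the degenerate first-step equation $0 = 0$ of an inert compartment as having
the natural solution (no progeny, no events) rather than as a finiteness
violation.

## Mean compartment dynamics

The mean counts obey $d\mathbf{C}/dt = \mathbf{A}\,\mathbf{C}$ with a
tridiagonal generator (diagonal $-\Delta_i$, subdiagonal $\Lambda_{i-1}$,
superdiagonal $\xi_{i+1}$). `solve_mean_matrix_exp()` evaluates
$e^{\mathbf{A}t}\mathbf{C}_0$ by a dense scaling-and-squaring matrix
exponential (`Matrix::expm`); the solution is exact in $t$, so time grids
are user-supplied and there is no adaptive stepping. $N$ is at most a few
tens in any application we know of, so no sparse machinery is warranted.

For the irreversible model started from one progenitor in $C_1$,
`mean_irreversible_closed_form()` uses the classical closed forms: a sum of
exponentials $\big(\prod_{l<i}\Lambda_l\big)\sum_j e^{-\Delta_j t}
\prod_{m \ne j}(\Delta_m - \Delta_j)^{-1}$ when the $\Delta_i$ are pairwise
distinct, the gamma-shaped profile
$\big(\prod_{l<i}\Lambda_l\big)\,t^{i-1}e^{-\Delta t}/(i-1)!$ when they are
all equal, and, for an accumulating terminal compartment
($\Delta_N = 0$) with the remaining $\Delta$ equal, the complementary form
expressing $E[C_N(t)]$ through the upstream compartments together with the
limit $\prod_{i<N}\Lambda_i/\Delta_i$ (`terminal_limit()`). Whether two
$\Delta$ values "coincide" is decided at a relative tolerance of
$10^{-9}\max|\Delta|$, because the distinct-value form divides by the
pairwise gaps. Mixed multiplicity patterns (some tied, some not) fall back
to the matrix exponential with a notice; the fully general confluent form
adds complexity for no practical gain when the exact matrix exponential is
available. The closed form is stated for a progenitor in $C_1$; other
starting compartments go through the matrix exponential.

Numerical caveat for validation work: a dense matrix exponential is accurate
relative to the norm of the result, not entrywise, so at times where a mean
has decayed to $10^{-9}$ of its scale the two routes can disagree at
relative order $10^{-7}$. The package's cross-validation tests therefore
compare entries above $10^{-6}$ cells, and require $10^{-8}$ relative
agreement there.

## Progeny of a single progenitor

$G_i$ counts the descendants of one cell starting in $C_i$ — daughters,
granddaughters, and so on, excluding the progenitor. Our counting convention
treats every division as consuming the mother and producing two daughters,
both of which are progeny: self-renewal contributes two cells born in
$C_i$, asymmetric division one in $C_i$ and one in $C_{i+1}$, symmetric
division two in $C_{i+1}$. A differentiation event moves a cell but creates
none. This convention is forced by the first-step systems for the means
(source terms $2(\lambda_i + a_i + s_i)$, and $2\lambda_i + a_i$ /
$2 s_i + a_i$ for the per-compartment split) and is applied consistently by
the simulator.

`mean_total_progeny()` solves the tridiagonal first-step system
$\mathbf{J}\mathbf{m} = \mathbf{b}$ by forward elimination and backward
substitution (the Thomas algorithm), exactly as the recursion is usually
written; a generic dense solve is kept in the test suite as an independent
check, not as the implementation. The means are finite precisely when
$\Delta_1 > 0$ and every elimination pivot $\Delta_i + \xi_i\gamma_{i-1}$
is positive; a violated pivot raises an "infinite progeny" error naming the
failed condition. `mean_progeny_by_compartment()` solves the same system
once per birth compartment (or uses the explicit product formulas in the
irreversible case); rows sum to the totals by linearity.

### Distributions via generating functions

For the irreversible model the full distribution of $G_i$ is computed from
probability generating functions. The terminal compartment is a linear
birth-death process with discrete birth/death probabilities
$p_b = \lambda_N/(\lambda_N + \mu_N)$, $p_d = 1 - p_b$, whose progeny pgf
has the Catalan closed form
$\Phi_N(z) = p_d \sum_n C_n (p_d p_b)^n z^{2n}$; only even progeny sizes
occur, and `last_compartment_progeny_distribution()` evaluates the terms in
log space so that Catalan numbers beyond $n \approx 85$ do not overflow.
Upstream compartments satisfy, conditioning on the first event, the
quadratic functional equation
$$
\lambda_i z^2 \Phi_i^2
  + \big(a_i z^2 \Phi_{i+1} - \Sigma_i\big)\Phi_i
  + \Phi_{i+1}\big(\nu_i + s_i z^2 \Phi_{i+1}\big) + \mu_i = 0 ,
\qquad \Sigma_i = \mu_i + \nu_i + \lambda_i + a_i + s_i .
$$
A derivation note: each division-type term carries one factor of $z$ per
newborn cell, and the forward-differentiation term carries none, because a
differentiating cell is the same cell in a new compartment, not a new
progeny member. One occasionally sees this equation written with an
extraneous $z$ on the $\nu_i$ term; differentiating at $z = 1$ shows that
version is inconsistent with the mean recursion
$\Delta_i m_i = \Lambda_i m_{i+1} + 2(\lambda_i + a_i + s_i)$, which the
form above reproduces exactly (this identity is asserted in the test
suite). `progeny_distribution_irreversible()` evaluates $\Phi_i$ backwards
from $\Phi_N$, at each evaluation point selecting the quadratic root that
is analytic in the unit disk — computed in the numerically stable form
$2C/(-B + \sqrt{B^2 - 4AC})$, which is the minimal root, degrades
gracefully to the linear solution when $\lambda_i = 0$, and is continuous
with $\Phi_i(0) = (\mu_i + \nu_i \Phi_{i+1}(0))/\Sigma_i$.

Probabilities are recovered by Cauchy contour inversion: $\Phi$ is sampled
at $M$ points on a circle of radius $r < 1$ and the series coefficients are
read off a discrete Fourier transform, $P(G = k) \approx
\mathrm{Re}(\hat c_k)/r^k$. Defaults are $r = 0.9$ and $M = 4(k_{\max}+1)$.
The radius trades two error sources: a small $r$ amplifies FFT round-off by
$r^{-k}$ (at $r = 0.9$, double-precision noise reaches $10^{-8}$ near
$k \approx 150$), while $r \to 1$ slows the decay of the aliasing tail.
Both $r$ and $M$ are exposed; for coefficients beyond $k \approx 150$ move
the contour towards the unit circle (e.g. $r = 0.98$). Inverted mass more
negative than $10^{-8}$ raises an error; round-off-level negative mass is
clipped to zero. For supercritical chains (some non-inert
$\Delta_i \le 0$) the distribution is defective; the tail then includes
$P(G = \infty)$ and a warning reports $1 - \Phi_i(1^-)$.

A printed-expansion note: the successive even-order probabilities satisfy
$P(G_N = 2n+2)/P(G_N = 2n) = \frac{2(2n+1)}{n+2} p_d p_b$, the Catalan
ratio $C_{n+1}/C_n$; the package follows the general Catalan term
throughout, and the test suite pins the ratio to it.

## Lifeline statistics

When every division is a self-renewal ($s_i = a_i = 0$) one daughter of
each division can be identified with the mother, so a *lifeline* — a track
containing exactly one cell at all times — is well defined; it moves
through compartments and terminates at a death event. With symmetric or
asymmetric division the "continuation" daughter would be arbitrary, so the
lifeline API enforces $s = a = 0$ rather than silently ignoring those
rates.

All lifeline statistics solve first-step tridiagonal systems sharing one
elimination backbone, with diagonal $\bar\Delta_i = \mu_i + \nu_i + \xi_i$
(self-renewal does not change the tracked cell's state):

* mean lifespan $\tau_i$ (source $1$), and, for the irreversible model,
  the lifespan second moment through the closed recursion with
  $R_i = 2(\nu_i\tau_{i+1}+1)/(\mu_i+\nu_i)^2$, $R_N = 2/\mu_N^2$. The
  reversible second moment would require transform inversion and is not
  provided.
* mean divisions $\eta_i$ (source $\lambda_i$) and the per-compartment
  split $\eta_i(j)$ (source $\lambda_i 1_{i=j}$). The split for the
  reversible chain is the package's own extension — it follows from the
  identical first-step argument used for the death-compartment
  probabilities, and linearity guarantees $\sum_j \eta_i(j) = \eta_i$.
* death-compartment probabilities $\beta_i(j)$ (source $\mu_i 1_{i=j}$),
  with rows summing to one whenever absorption is certain; a non-positive
  pivot (an immortal line) raises an error.
* the full division-count distribution $\omega_i(n)$, whose system uses
  the total exit rate $\hat\Delta_i = \mu_i + \lambda_i + \nu_i + \xi_i$
  because a division is itself an event of the embedded chain. The
  recursion couples $n$ to $n-1$ and all start compartments to each other,
  so it is run jointly over compartments for increasing $n$
  (default $n_{\max} = 200$, with a tail-mass warning).

`elasticity()` computes $(\partial f/\partial\theta)\,\theta/f$ for any
scalar statistic by central finite differences with relative step
$10^{-6}$. At $\theta = 0$ the elasticity is undefined and the raw
sensitivity is returned, flagged; at $f = 0$ an error carries the raw
sensitivity.

## The thymocyte topology

The bifurcated thymic route (pre-DP $\to$ post-DP $\to$ CD4 SP / CD8 SP
$\to$ periphery) is implemented as a dedicated small module rather than by
generalising the linear-chain types: every statistic of interest — six fate
probabilities, SP division counts, journey duration — is a short product of
competing-risk ratios $\theta/(\text{sum of stage rates})$, and keeping the
topology bespoke leaves the linear-chain code honest to its own recursions.
The probabilities sum to one as an algebraic identity.
`thymic_elasticity_table()` differentiates the products in closed form
(elasticity of each factor is $1_{\theta=\text{num}} -
\theta/\text{denominator}$), which the test suite cross-validates cell by
cell against finite differences at $10^{-6}$. `simulate_thymocyte()` is a
vectorised Monte-Carlo check: stage sojourns are exponential, SP division
counts geometric with Erlang sojourns, which is distribution-exact for this
topology.

## Stochastic simulation

`simulate_population()` is a plain Gillespie direct-method loop over
per-compartment total rates; states are recorded on a save grid (full event
logging is opt-in, and is replayed event by event in the test suite to pin
the state-update table). `simulate_lifelines()` advances all live
replicates one embedded-chain event per sweep, which keeps $5\times10^4$
lifelines to a couple of seconds without altering the sampled law.
`simulate_progeny()` runs the branching process from one cell and counts
newborns at their birth compartment under the division convention above;
caps (`max_progeny` $10^6$, `max_events` $10^7$) convert supercritical
runaway into flagged records instead of hangs.

Replicate seeds are derived deterministically from (master seed, replicate
index), so replicate sets are reproducible and order-independent; all
randomness flows through R's RNG.

## Validation scale and what it shows

The test suite validates every analytic route against an independent one
(dense solves, matrix exponentials, closed forms, generating-function
derivatives) at tolerances of $10^{-8}$–$10^{-12}$ on batches of seeded
random chains of 2–7 compartments, and validates the simulators against
the analytics at Monte-Carlo scale: $10^3$ population replicates,
$5\times10^4$ lifelines, $2\times10^4$ progeny trees, $10^5$ thymocytes,
compared at three standard errors (with an absolute floor of $0.01$ cells
for ensemble means far below one cell, where the empirical standard error
of an integer ensemble degenerates to zero) and a 1% goodness-of-fit level
for histograms. These sizes keep the whole suite under a minute while
leaving comparisons well inside asymptotic normality.

Passing these checks shows internal consistency of the mathematics and the
simulators under the model's assumptions — independent cells, exponential
waiting times, homogeneous rates within a compartment. It does not validate
those assumptions against real populations: crowding, feedback regulation,
age structure within a compartment, and rate heterogeneity between cells
are all outside the model class.

## Known limitations

* Progeny distributions (not means) are available for the irreversible
  model only; the reversible pgf system is not implemented.
* The lifeline second moment requires irreversibility, as noted.
* Reduced $(\Delta, \Lambda)$ models support mean dynamics and stability
  only; nothing in the package attempts to invent the unidentifiable raw
  rates, and the per-compartment progeny of the hematopoietic preset is
  deliberately not reproduced for that reason.
* No fitting of rates to data is provided; the package computes forward
  predictions from given rates.
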