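---
title: "Exact random-walk analysis of the flashing Brownian ratchet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact random-walk analysis of the flashing Brownian ratchet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratchetwalk)
```

## The model

A **Brownian ratchet** is a one-dimensional diffusion with unit diffusion
coefficient whose drift pushes it toward the minima of a periodic asymmetric
sawtooth potential

$$V(x) = \begin{cases} x/\alpha, & 0 \le x \le \alpha L,\\
(L - x)/(1-\alpha), & \alpha L \le x \le L,\end{cases}$$

extended with period $L$, where $\alpha \in (0,1)$ is the shape parameter
($\alpha \ne 1/2$ gives the asymmetry driving directed transport) and $L > 0$
is a scale.  The drift is $\mu(x) = -\gamma V'(x)$ for a strength
$\gamma > 0$: $-\gamma/\alpha$ on the rising flank, $+\gamma/(1-\alpha)$ on
the falling flank, right-continuous at the kinks.  The **flashing** ratchet
alternates this diffusion (potential *on*, duration $\tau_2$) with free
Brownian motion (potential *off*, duration $\tau_1$).  Although both phases
are individually unbiased — the ratchet's equilibrium law
$C e^{-2\gamma V(x)}$ has exactly zero mean drift, and Brownian motion is
symmetric — the alternation produces net motion toward $+\infty$ when
$\alpha < 1/2$.  This is the continuous analogue of Parrondo's paradox, and
molecular-motor models in biophysics are built on the same mechanism.

`ratchet_params(l, L_int, L, gamma | lambda)` holds the model.  The shape is
kept as a reduced fraction $\alpha = l/L_{\mathrm{int}}$ because the walk
approximation needs the rational structure; `lambda` is the drift rate on the
walk side and is linked to the diffusion side by
$\gamma = \lambda(1-\alpha)/2$, so either may be supplied.

## From games to walks

Discretizing one period of the drift yields a capital-dependent game: move up
with probability $p_0$ at residues $j \bmod L_{\mathrm{int}} < l$ and $p_1$
otherwise.  Requiring the walk to be recurrent (detailed balance of the
periodic environment) forces
$(1-p_0)^l (1-p_1)^{L-l} = p_0^l\, p_1^{L-l}$, a one-parameter family
conveniently written with $\rho \in (0,1)$:

$$p_0 = \frac{\rho^{(1-\alpha)/\alpha}}{1+\rho^{(1-\alpha)/\alpha}},
\qquad p_1 = \frac{1}{1+\rho}.$$

`probs_from_rho()`, `game_b_spec()` and `game_b_invariant_profile()`
implement this family and its reversible invariant measure per period;
`mean_profit()` confirms the game is asymptotically fair for every
$(\rho, l, L_{\mathrm{int}})$.  Mixing with a fair coin
(`mixture_mean_profit()`) or alternating in a periodic pattern
(`pattern_mean_profit()`) produces the Parrondo effect — a strictly winning
combination of two fair games — when $\alpha < 1/2$, and the losing
anti-Parrondo effect when $\alpha > 1/2$.  Pattern profits are time-averages
under the stationary law of the chain on (capital residue, pattern phase),
solved as a dense linear system; the state spaces involved are tiny, so a
direct solve is preferred to iteration and is exact to rounding.

## The walk approximation

Refining the lattice to spacing $1/n$, taking $\rho = 1 - \lambda/n$ (valid
for $n > \lambda$), letting the environment have period
$n L_{\mathrm{int}}$ sites, running $n^2$ steps per time unit and rescaling
space by $1/n$ makes the walk converge to the Brownian ratchet with
$\gamma = \lambda(1-\alpha)/2$.  The flashing version alternates
$n^2\tau_1$ simple-symmetric steps with $n^2\tau_2$ ratchet steps.  For the
step counts to be integers, $n$ must be a multiple of the smallest integer
$m$ with $m^2\tau_1, m^2\tau_2 \in \mathbb{Z}$ (computed exactly from the
rational representations of the durations; for $\tau_1 = \tau_2 = 2.4$,
$m = 5$).  Non-multiples are refused rather than rounded: rounding the step
counts would silently change the time being simulated.

Rather than simulating paths, `walk_evolve()`/`flash_evolve()` propagate the
**exact** probability mass function: one step replaces the mass $p_j$ at
site $j$ by contributions $p_j u_j$ at $j+1$ and $p_j(1-u_j)$ at $j-1$.  The
support grows by one site per step and nothing is ever pruned, so after the
48 000 steps of the reference configuration the pmf is exact up to
double-precision rounding (total-mass error below $10^{-12}$ is asserted in
the tests).  The inner loop is compiled (Rcpp) with a fixed summation order,
making runs bit-reproducible.  A 48 000-step run at $n = 100$ takes on the
order of ten seconds on one CPU; the path-enumeration oracle in the test
suite verifies the propagation exhaustively for up to 12 steps, where all
$2^{12}$ weighted paths can be enumerated.

## Density statistics

After an even number of steps from a point start, the walk occupies sites of
one parity, so positions $x = j/n$ carry mass in bins of width $2/n$:
`density_nodes()` assigns node height $p_j \cdot n/2$ and interpolates
linearly (zero-padding one empty site beyond each end, so the interpolant
integrates to exactly 1).

The density of the flashing walk started at 0, observed at
$\tau_1 + \tau_2$, has pointed peaks at the potential minima
$0, \pm L, \dots$, separated by the potential maxima
$x \equiv \alpha L \pmod L$ (`peak_boundaries()`).  Two conventions needed
fixing where the reference computations are silent:

* **Boundary-site mass.** Regions are half-open $[b, b')$: a site lying
  exactly on a separator belongs to the region on its right.  This is the
  convention under which every row of the two reference tables is reproduced
  to all printed digits; an equal-split alternative
  (`boundary_mass = "split"`) is provided and matters only when the density
  at the separators is appreciable (weak drift).
* **Peak heights.** The height of a peak is the interpolated density *at
  the potential minimum*, not the maximum over the region.  The two differ
  for weak drift, where the monotone tail of the dominant central peak can
  exceed, just inside a neighbouring region, the value at that region's own
  minimum; the reference heights are reproduced only under the
  at-the-minimum convention.  `max_density_height()` exposes the plain
  regional maximum as well.

`mean_displacement()` gives $\sum_j (j/n) p_j - x_0$.
`symmetric_peak_displacement()` evaluates $\sum_i c_i a_i$, the mean the
density would have if its peaks were symmetric about their centres; the gap
to the true mean quantifies peak asymmetry.  `gaussian_reference_areas()`
integrates a normal law with mean `start` and **variance** $\tau_1$ over the
regions: these are the areas the peaks approach as
$\lambda \to \infty$, when the on-phase pins all mass to the minima and the
off-phase diffusion alone (variance $\tau_1$) sets the split.  The test
suite checks the monotone approach of the first peak area along
$\lambda \in \{1, 5, 25\}$.

## The wrapped chain and the stationary mean displacement

Because the kernels have period $n L_{\mathrm{int}}$ sites, the walk wrapped
onto that circle is Markov.  Sampling it once per flash period gives a
finite chain whose transition matrix `period_matrix()` builds by propagating
all start sites simultaneously (an $S \times S$ occupation matrix updated by
circular shift-adds in compiled code, $S = n L_{\mathrm{int}}$).  When $S$
and the period step count are both even the sampled chain splits into two
parity classes; one extra step is then appended to make it irreducible.  The
natural choice for that step — taken here — is the symmetric kernel, i.e.
the first step of the next flash period.  With the reference parameters
($n = 100$, $\tau_1 = \tau_2 = 2.4$) the matrix is $400 \times 400$ built
from 48 001 steps.

The stationary law $\bar\pi$ (`stationary()`, direct linear solve, residual
below $10^{-12}$) is U-shaped on $[0, L)$; `remap_to_unimodal()` shifts the
upper arc down by $L$ to display it as a unimodal law on
$[-(1-\alpha)L, \alpha L)$.  The **stationary mean displacement** over one
flash period is

$$\bar\mu = \sum_i \bar\pi(i)\, d(i)/n,$$

where $d(i)$ is the expected unwrapped displacement of one flash period
started at circle site $i$.  Two conventions are deliberate here.  First,
$d(i)$ is accumulated during the matrix propagation as the running expected
one-step drift $\sum_r w(r)\,(2u_r - 1)$ of the wrapped occupation law —
valid precisely because the kernels are periodic, so the unwrapped drift
depends on the position only through its residue.  Second, $d(i)$ covers
exactly the $n^2(\tau_1+\tau_2)$ steps of one period and **excludes** the
extra irreducibility step, which exists only to make $\bar\pi$ well defined;
with it the reference value $\bar\mu = 0.684827$ is reproduced.  $\bar\mu$
exceeds the point-start mean displacement (0.678364) slightly: under the
stationary start the mass already sits concentrated in a well, which the
subsequent flash transports a little more efficiently than the spread-out
point-start density.

## Monte-Carlo oracle

`simulate_flashing()` and `simulate_ratchet_wrapped()` implement explicit
Euler–Maruyama for $dY_t = dB_t + \eta(t)\mu(Y_t)\,dt$, with drift and flash
indicator evaluated at the left endpoint of each step and no smoothing of
the drift discontinuities; the step should satisfy
$\Delta t \ll (\alpha L/\gamma)^2$ (default $10^{-3}$).  Each call runs
under its own seed and restores the caller's RNG state.  The oracle is
stochastic and first-order, so it is used only for consistency bands: the
tests require agreement with the exact lattice statistics within four
standard errors (at $1.5\times 10^4$ paths) and total-variation closeness
of the wrapped-endpoint histogram to the closed-form equilibrium density
$C e^{-2\gamma V}$ at a scale set by the binomial sampling error.  Test
problem sizes (paths, $\Delta t$, durations) are chosen so the whole suite
runs in about two minutes while keeping those bands diagnostic.

## Numerical choices and limitations

* Stationary and profit computations use dense direct solves; state spaces
  here are at most a few hundred states.  For much larger $n L_{\mathrm{int}}$
  an iterative solver would be preferable.
* `flashing_schedule()` derives rationals for $\tau_1, \tau_2$ by continued
  fractions (denominators up to $10^6$); genuinely irrational durations are
  outside the method, which needs integer step counts.
* The equilibrium normalizer, CDF and mean drift use the closed-form
  piecewise-exponential integrals, keeping equilibrium identities exact to
  rounding (the mean drift cancels structurally, not just numerically).
* Uniqueness of the stationary laws is asserted only through the solve
  residuals and the irreducibility fix, not proved.
* The walk pmf is exact for the *walk*; it approximates the continuous
  flashing ratchet with an $O(1/n)$-scale bias visible in the reference
  convergence table (mean displacement decreasing in $n$, checked for
  $n \in \{10, 20, 30\}$).  Nothing here addresses tilted ratchets or
  schedule optimization.
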