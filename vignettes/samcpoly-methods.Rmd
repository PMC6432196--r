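---
title: "Flat-histogram sampling of sterically stiff square-well chains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flat-histogram sampling of sterically stiff square-well chains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samcpoly)
```

## The model

`samcpoly` simulates a single coarse-grained homopolymer: $N$ hard spheres of
diameter $\sigma = 1$ joined by bonds of fixed length $L \in (0.5, 1]$, with a
square-well attraction between every non-bonded pair ($|i-j| \ge 2$),

$$U(r) = \begin{cases} \infty & r < 1 \\ -\epsilon & 1 \le r \le \lambda \\ 0 & r > \lambda. \end{cases}$$

Bonded pairs are exempt from both the core and the well: the spheres are
*fused*, and for $L < 1$ they overlap.  That overlap is the interesting part
of the model.  The hard cores of monomers $i-1$ and $i+1$ restrict the
internal bond angle to $\vartheta \ge \vartheta_{\min} = 2\arcsin(1/2L)$,
so the bond length alone controls the chain stiffness — an *entropic*
(steric) stiffness, as opposed to the energetic stiffness of a bending
potential.  At $L = 0.5$ only $\vartheta = \pi$ survives (rigid rod); at
$L = 1$ (tangent spheres) the chain is fully flexible.

Two derived boundaries organise the phase behaviour at the default well
width $\lambda = 1.1$:

* **stiff regime**, $2L \le \lambda$ ($L \le 0.55$): the next-nearest
  distance lies in $[1, 2L] \subseteq [1, \lambda]$ in *every* conformation,
  so all $N-2$ next-nearest pairs interact permanently and the whole energy
  spectrum is shifted to $E \le -(N-2)\epsilon$;
* **flexible limit**, $L = 1$; everything between is semi-flexible.

Energies are exact negative integers (minus the number of in-well
non-bonded pairs), which is why the density of states lives on an integer
grid with no real-valued binning.  The well boundaries $r = 1$ and
$r = \lambda$ — a measure-zero set — are counted as in-well, so that the
straight rod at exactly $2L = \lambda$ is a valid bound state; this keeps
the stiff-regime boundary at $L = \lambda/2$ inclusive.

## Density of states by stochastic approximation

All thermodynamics derives from the micro-canonical entropy
$S(E) = \ln g(E)$.  `run_samc()` estimates it with Stochastic Approximation
Monte Carlo: a random walk with symmetric, bond-preserving proposals is
accepted with the flat-histogram rule
$A = \min(1, g(E_{\text{old}})/g(E_{\text{new}}))$ (hard-core violations are
rejected outright), and after every step the estimate of the *retained*
energy — old on rejection, new on acceptance — is updated,

$$\ln g(E) \mathrel{+}= \gamma_t\,(\delta_{E,E'} - 1/M),$$

with $M$ the current number of grid bins.  The gain follows
$\gamma_t = \gamma_0 \min(1, t_0/t)$, which satisfies the two
stochastic-approximation convergence conditions ($\sum_t \gamma_t = \infty$,
$\sum_t \gamma_t^\nu < \infty$ for $\nu \in (1,2)$).  Unlike Wang–Landau
sampling there is no flatness-triggered gain halving; the schedule is fixed
in advance.

Three numerical choices matter in practice:

* **Adaptive grid with an unvisited baseline.**  The ground-state energy is
  unknown a priori, so the default grid grows as new integer energies are
  visited.  A new bin enters at the running *baseline* — the value a bin
  would hold had it sat in the grid unvisited from the start, receiving only
  the $-\gamma_t/M$ subtractions.  This reproduces the exploration pull of a
  full-range grid initialised at $g_0(E) = 1$: unvisited energies always sit
  below visited ones, so the walk is driven into them.  (Initialising new
  bins at $0$ instead stalls low-energy discovery badly: in an
  $N = 20$, $L = 1$ test run of $10^8$ steps the walk reached only
  $E = -16$ with 0-initialised bins versus $E = -45$ with the baseline
  rule.)  A `fixed` grid policy over a declared range is available; visiting
  an energy outside it is an error, never silent.
* **Polyak–Ruppert averaging.**  The SAMC iterate fluctuates around the
  fixed point with standard deviation $\sim\sqrt{\gamma_t \tau}$ ($\tau$ the
  bin correlation time); the `ln_g` column reported by `run_samc()` is the
  time average of the iterate over the second half of the run, which removes
  most of that variance (for the 3-mer test case: sd $\approx 0.5$ for the
  final iterate at $\gamma = 10^{-2}$, $\approx 0.002$ for the average).
  The final iterate is kept in `ln_g_final` and used for bit-exact
  checkpoint resumes (`init =`).
* **Finite-$\gamma$ bias.**  At constant gain the stationary estimate is
  biased by $O(\gamma\tau)$; the 1/t decay drives this to zero, but the
  plateau length $t_0$ should end well before the steps one intends to
  trust.  The quantitative small-chain validations in the test-suite use
  $t_0 = 10^3$ with $10^7$-step runs ($\gamma_{\text{end}} = 10^{-4}$); the
  $N = 20$ collapse run uses $t_0 = 10^5$ with $10^8$ steps, where early
  exploration of the wide entropy range matters more than the tail bias.

Moves are pivot, crankshaft and terminal-monomer rotation with equal
weights and maximum angle $\pi$ — the minimal standard ergodic set for
fixed-bond continuum chains.  Axes are isotropic and angles symmetric about
zero, so the proposal density is symmetric and the acceptance rule applies
as written.  All randomness flows from R's RNG: a seed makes a run
bit-reproducible.

## The uniform-sampling oracle

Because the bond lengths are fixed, the configuration integral factorises
over bond directions: drawing every bond direction uniformly on the sphere
and discarding hard-core violators samples exactly the finite-energy
configuration measure.  `uniform_dos()` does this brute-force and
histograms survivor energies; log-frequency differences estimate
$\ln g$ differences with multinomial errors.  For the 3-mer there is a
closed form: $r_{13}^2$ is uniform on $[0, 4L^2]$, so the probability of a
surviving conformation being bound is $(\lambda^2 - 1)/(4L^2 - 1)$ (equal to
$0.07$ at $L = 1$, $\lambda = 1.1$, and $1$ in the stiff regime).  This
pair — closed form and uniform sampler — is the anti-regression anchor for
the whole engine: the test-suite requires SAMC level spacings for
$N \in \{3,4,5\}$ to agree with the oracle within the two-sided 0.27%
("3-sigma") level.  The SAMC error is estimated from $k = 4$ independent
replicates, so its standard error carries only $k - 1$ degrees of freedom;
the comparison therefore uses the matching Welch–Satterthwaite $t$ quantile,
which reduces to $3.0$ exactly where the oracle's high-count binomial error
dominates.  Using a literal $3.0$ with a 3-dof error estimate would reject
a correct engine in roughly 6% of comparisons — a property of the
statistics, not of the sampler.

## Thermodynamic analysis

From a converged $S(E)$ on the unit-spaced integer grid, `micro_curves()`
forms central differences $\beta_\mu(E) = (S(E+1) - S(E-1))/2$ and
$\gamma(E) = S(E+1) - 2S(E) + S(E-1)$ (exact for quadratics).  A local
maximum of $\gamma(E)$ *above* zero marks a first-order pseudo transition
(convex intruder in $S$, equivalently a backbending micro-canonical
temperature); a peak *below* zero marks a second-order one.  Peak calls use
a prominence threshold, default 5% of the curve range, with ties broken
toward lower energy; the threshold is configurable because the distinction
between a genuine peak and small oscillations of a noisy $\gamma(E)$ is a
resolution question, not a sharp one.  Unvisited interior levels are
refused by default (`allow_gaps = FALSE`): silently differencing across a
gap can fabricate transitions.  Optional Savitzky–Golay smoothing of
$S(E)$ before differencing is off by default and always recorded in the
result.

Canonically, $\ln Z(T) = \ln \sum_E g(E) e^{-E/T}$ is evaluated with the
log-sum-exp shift (no raw $Z$ is ever formed), and the specific heat uses
the variance form $C_N = (\langle E^2\rangle - \langle E\rangle^2)/T^2$,
which is non-negative by construction; the equivalent
temperature-derivative form $C_N = 2T (\ln Z)' + T^2 (\ln Z)''$ is provided
as a cross-check and the two agree to $10^{-6}$ relative on smooth test
grids.  Energy-resolved observable means $\bar O(E)$ (squared radius of
gyration; contact-matrix entries) reweight into
$\langle O \rangle(T) = \sum_E \bar O(E)\, g(E) e^{-E/T} / Z(T)$.
Observables are accumulated during the final, small-gain half of a run by
default (early-phase estimates ride a moving $g$), at stride 1; both are
configurable, changing estimator variance but not the estimand.

A transition temperature is located per observable at its main peak
($C_N(T)$, $d\langle R_g^2\rangle/dT$, …); the consensus location is the
mean of the per-observable peaks and the uncertainty interval their min–max
spread — for a finite chain the *shift between observables*, not
statistical error, is what limits how sharply the pseudo transition
temperature is defined.  The energy histogram $P(E|T) \propto g(E)e^{-E/T}$
supplies the canonical order diagnostic: a double peak (valley at least 10%
below the smaller mode by default) indicates first order.  Distribution
end-points count as modes, since the finite spectrum genuinely truncates
there.

## Knot identification

Collapsed stiff chains can knot; the package identifies knot types by the
Alexander determinant $|\Delta(-1)|$.  The open chain is closed with a
single straight end-to-end segment, simplified by triangle elimination (a
vertex is removed when the triangle spanned with its neighbours is pierced
by no other edge — a deformation across an empty triangle never changes the
knot type), projected along a random direction, and the crossing diagram's
Alexander matrix is evaluated at $t = -1$, where its rows are independent
of crossing handedness, so only over/under information is needed.  The
determinant is computed by fraction-free (Bareiss) integer elimination with
an overflow guard (doubles hold integers exactly to $2^{53}$; the guard
errors rather than rounding).  Degenerate projections — crossings at
vertices, parallel overlaps, height ties — are detected by tolerance
($10^{-9}$) and re-drawn.  The determinant separates unknot (1), trefoil
(3) and figure-eight (5), the morphologies of interest; it is not a
complete invariant beyond these, and `knot_label()` says so.

The test-suite validates the pipeline against parametric trefoil and
figure-eight curves (whose Alexander polynomials give $|\Delta(-1)| = 3$
and $5$), against polygons that are unknotted *by construction* (their
planar projection is a simple closed curve), and for invariance under
projections, simplification and rigid motions.

## Problem sizes and what the tests do (and do not) show

The validation suite runs entirely at desk scale, by design:

* quantitative density-of-states validation at $N \in \{3,4,5\}$,
  $10^7$-step runs against a $10^6$-sample oracle;
* the stiff-regime spectrum shift at $N = 20$, $L = 0.53$ ($E \le -18$,
  rod energy $-18$);
* one qualitative $N = 20$, $L = 1$ collapse signature at $10^8$ steps:
  monotone swelling of $\langle R_g^2\rangle(T)$, a single dominant peak in
  its temperature derivative, and a unimodal $P(E|T)$ there — the
  second-order signature expected for a short flexible square-well chain at
  $\lambda = 1.1$.

Mapping full pseudo phase diagrams over the $(L, T)$ plane, or ground-state
searches at $N = 40$ (where the trefoil ground state appears near
$L \approx 0.51$), needs orders of magnitude more sampling per bond length
and is out of scope for the automated suite, though the batch `scan`
subcommand supports such studies.  The synthetic-data generators used by
the thermodynamic tests (tilted two-Gaussian and concave-with-dip entropy
curves) emulate the *shapes* that first- and second-order pseudo
transitions imprint on $S(E)$; they do not emulate sampling noise,
correlated errors between neighbouring bins, or gaps, so passing them
validates the analysis algebra, not the sampler — the oracle comparisons do
that.

## Known limitations

* SAMC error bars come from replicate runs; there is no within-run
  estimator.
* The finite-$\gamma$ bias means a run whose gain never leaves the plateau
  (e.g. $t_0$ of the order of the run length) converges to a visibly
  shifted $\ln g$; schedule choice is the user's responsibility and the
  defaults ($\gamma_0 = 1$, $t_0 = 10^6$) assume runs of $10^7$ steps or
  more.
* The Alexander determinant cannot distinguish knots sharing a determinant
  (e.g. $5_2$ also has determinant 7); for the unknot/trefoil/figure-eight
  calls made here it is sufficient.
* Observables are accumulated at the energies visited by the flat walk;
  levels never visited during the collection window carry no observable and
  canonical averages renormalise (with a warning) over covered levels.
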