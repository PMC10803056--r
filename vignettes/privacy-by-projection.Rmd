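---
title: "Privacy-preserving federated density estimation with random Fourier features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving federated density estimation with random Fourier features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rffkde)
```

## The problem

A server wants a population density surface over an area `A` — for transit
planning, epidemic modelling, or any task that needs to know where people
are — from `N` users who each hold one private location `d_i`. Kernel
density estimation is the natural tool and it federates trivially: the
server picks a `P x Q` grid and a bandwidth `h`, and each user returns
their kernel evaluations

$$G_h(d_i)[p,q] = k_h(g_{pq}, d_i), \qquad
  k_h(x,y) = \exp\!\left(-\frac{\|x-y\|^2}{2h^2}\right),$$

which the server averages into the pooled estimate
$f(g \mid D) = \tfrac1N \sum_i k_h(g, d_i)$. The catch is that each
response is itself a map of the user: it peaks at the grid node nearest
`d_i`, so a malicious server localizes every user to within one grid
spacing (`privacy_scores(..., method = "exact")` measures exactly this).

## The mechanism: project, don't perturb

Instead of exact kernel values, each user returns projections onto a small
number `B` of random Fourier features. By Bochner's theorem the Gaussian
kernel is the expectation of a random cosine,

$$k_h(x, y) = \mathbb{E}_{\omega \sim N(0, h^{-2} I)}
  \cos(\omega^\top (x - y)),$$

so the user draws `B` frequencies, freezes them, and answers each grid
node with $\sum_b \cos(\omega_b^\top (g_{pq} - d_i))$. The server divides
the aggregate by `N B` and gets an unbiased estimate of the pooled kernel
mean — whatever `B` is, even `B = 1`, because averaging over users plays
the same role as averaging over features. Estimation accuracy is governed
by the total feature count `N B`; users and features are exchangeable
currencies.

A single cosine feature, however, is *spatially delocalized*: its maxima
form parallel bands with spacing $2\pi/\|\omega\|$ across the whole plane.
All locations in the equivalence class

$$D(x) = \left\{\, x + \alpha \tfrac{2\pi}{\|\omega\|^2}\,\omega + u :
  \alpha \in \mathbb{Z},\ \omega^\top u = 0 \,\right\}$$

produce *identical* responses at every query point
(`equivalence_class_points()` materializes the class and the tests verify
indistinguishability to `1e-9`), so no number of queries can pin the user
to a single band. Privacy here comes from information destruction, not
noise: the map is many-to-one over the entire area, unlike local-noise
mechanisms whose perturbed release still concentrates around the truth.

## The attacker and the privacy score

The threat model is a malicious server with unbounded computation that
sees only response surfaces. Its optimal move is to predict a surface
maximum. The package implements this attacker literally:
`find_local_maxima()` (8-neighborhood, deterministic plateau
representatives), an evidence filter that keeps maxima within a factor
`epsilon_filter = 1.1` of the global maximum, and the score

$$Z_i = \sum_j e'_{ji}\, \|g_{ji} - d_i\|_2,$$

the attacker's expected localization error in map units, with normalized
kept-maxima weights $e'_{ji}$. The system score is the mean over users.
Two baselines frame the scale: exact federated KDE (one maximum at the
user — `Z` bounded by one grid spacing, no privacy) and the zero-feature
constant response (`Z` equals the mean distance from the user to all grid
nodes — no information, best possible privacy while responses stay
in-area).

One printed form of the score carries both a `1/K_i` factor and
normalized weights; since the score is described as a weighted average of
distances, we implement the weighted average (the double-normalized form
is available via `literal = TRUE`). The weight normalizer is computed over
kept maxima only, which keeps weights positive on signed RFF surfaces; a
surface with no positive maximum falls back to the unweighted mean over
all maxima and is flagged.

## The bandwidth policy

Two adaptive attacks remain, and both are closed by a user-enforced query
policy (`bandwidth_policy()`, `validate_query()`), whose refusals depend
only on public parameters, never on the user's location:

* **Too-large bandwidths.** Rescaling shrinks $\|\omega\|$, so a large `h`
  can leave a single band in the area. Since
  $\|\omega\|^2 \sim h^{-2}\chi^2_2$ and roughly $l\|\omega\|/(2\pi)$
  bands cross a side-`l` square, requiring at least `j` bands with
  probability $1 - C(\gamma)$ ($C$ the $\chi^2_2$ CDF) gives
  $$h_{\max} = \frac{\sqrt{\gamma}\, l}{2\pi j}.$$
  The $\sqrt{\gamma}$ placement follows from this dimensional analysis
  (the threshold enters through $\|\omega\|^2$), and
  `count_bands()` Monte Carlo confirms the coverage guarantee; `j >= 2`
  is enforced because with fewer bands a corner user is effectively
  localized.
* **Multiple bandwidths.** Users freeze their frequencies and answer a
  query at `h` by rescaling, $\tilde\omega = (h_0/h)\,\omega$, which
  preserves band directions. The user's own band never moves, so
  comparing responses across arbitrary bandwidths would reveal it. The
  policy therefore admits only $h \in \{(4n+1)\,h_0\}$: then every maximum
  of the rescaled response coincides with every $(4n+1)$-th base band
  (`band_overlap()` demonstrates the period-5 overlap at `n = 1`, and
  that an incommensurate bandwidth leaves only the true band invariant —
  which is exactly what the policy exists to prevent). `n = 0` is allowed:
  the base bandwidth itself must be usable. Membership is tested with
  relative tolerance `1e-9` so that decimal round-trips through config
  files do not cause spurious refusals.

The frozen-frequency contract is enforced at the type level: a basis is
drawn once per user (from a per-user substream of one master seed, so
results are independent of evaluation order) and only ever rescaled.
Repeated queries are bit-identical; a moving user's responses are rigid
translates of each other, so even movement direction is concealed.

## The GeoInd baseline

The comparison mechanism perturbs each location once with planar Laplace
noise of density $\tfrac{\epsilon^2}{2\pi} e^{-\epsilon d(x_0, x)}$ and
then runs the exact pipeline. Sampling uses the exact polar decomposition
— uniform angle, Gamma(2, rate $\epsilon$) radius — rather than an
inverse-CDF construction; both are exact and the Gamma route uses a
standard library primitive. Perturbed points are deliberately not clipped
to the area, which is why GeoInd privacy scores can exceed the
zero-feature ceiling at small $\epsilon$. We assume one perturbation per
experiment (one-shot release), mirroring the single-response discipline of
the projection protocol.

## Synthetic study conditions

The generators in `builtin_mixture()` define the experimental conditions:

* `grid9` — nine equal-weight Gaussians on $\{-1,0,1\}^2$ with covariance
  `diag(0.25, 0.25)`: a smooth, near-uniform surface. Evaluation grid
  `50 x 50` on $[-3,3]^2$.
* `octagon8` — eight Gaussians of mean radius 3 with rotated covariances
  $R(\pi i/4)\,\mathrm{diag}(1, 0.16^2)\,R(\pi i/4)^\top$: a heterogeneous
  ring whose printed covariance entries we resolved to this canonical
  rotated-ellipse form (the $\cos^2$/$\sin^2$ diagonal and
  $(1-0.16^2)\sin\cos$ cross-terms match). Evaluation grid `100 x 100` on
  $[-5,5]^2$.
* `tri1d` — the 1D illustration, $N(-10,2^2)$, $N(0,2^2)$, $N(5,2^2)$
  with weights 1:3:1, evaluated at 1000 points on $[-15,15]$.

The 2D evaluation grids are our choice (the extents cover the mixtures to
beyond three component standard deviations); the 1D grid is the stated
illustration grid. Sweep bandwidth defaults to `h = 0.55` for the 2D
mixtures, or to the k-NN heuristic of `select_bandwidth()` (mean k-th
nearest-neighbor distance within a 10% subsample; `k = 200` for synthetic
densities, `500` a sensible default for dense check-in data).

What the generators do *not* emulate: geographic projection distortion
(all coordinates are planar; check-in latitude/longitude are treated as
planar degrees), temporal structure, repeated check-ins by one user, and
population priors an adversary might hold. Passing tests therefore
demonstrate the mechanism's statistical behaviour, not robustness to
side-information attacks, which are out of scope of the threat model.

## Numerical choices

* Local maxima use `>=` against existing neighbors, so boundary cells and
  plateaus are handled; a connected plateau contributes its lowest linear
  index, making attack output reproducible.
* The kernel is unnormalized (peaks at 1, matching the protocol's
  response values); rank utility and the privacy score are invariant to
  the constant, and `normalize = TRUE` recovers the true-density scale.
* Surfaces are dense matrices; pooled estimators evaluate in vectorized
  blocks (`chunk`), making `N = 20000` users on a `50 x 50` grid a
  few-second computation without compiled code.
* Spearman on a constant surface is undefined and raises a classed error
  rather than returning `NA`.
* `gain_per_cost()` defines the privacy cost of `B` features as
  `Z(1) - Z(B)`, so cost is nonnegative and the gain/cost ratio is
  directly interpretable; a zero cost yields `Inf`, not an error.

## Problem sizes used in the checks

The shipped tests and the acceptance script use the study conditions at
desk scale: utility at `N = 20000, B = 1` over 10 replicates; the
convergence ladder `(N, B) in {500, 20000} x {1, 10}` over 10 replicates;
privacy ordering at `N = 2000` over 5 replicates; `1e5` draws for
unbiasedness and the planar-Laplace law; `1e4` draws for the band-count
coverage bound. Larger `N`, `B` or grids change runtimes, not code paths.

## Worked example

```{r example, eval = FALSE}
library(rffkde)

grid <- grid_spec(c(-3, 3), 50, c(-3, 3), 50)
mix  <- builtin_mixture("grid9")
X    <- sample_mixture(mix, 20000, seed = 1)

est   <- federated_rff_kde(X, grid, h = 0.55, B = 1, seed = 1)
truth <- mixture_density(mix, grid)
spearman_surface(est, truth)
#> [1] 0.9487809

mean(privacy_scores(X[1:500, ], grid, "rff", h = 0.55, B = 1, seed = 1)$Z)
#> [1] 2.534535
mean(privacy_scores(X[1:500, ], grid, "exact", h = 0.55)$Z)
#> [1] 0.04644575
```

A single delocalized feature per user already ranks the density surface
almost perfectly, while the attacker's expected error stays at the scale
of the whole area (`~2.5` map units, against `~0.05` — one grid cell —
for exact federated KDE).

## Known limitations

* Distances are Euclidean in map units; no geodesic support.
* The attacker is the maxima-based one of the threat model; continuous
  optimization or Bayesian attackers with area priors are not modelled.
* Dimensions above 2 are not supported (the policy analysis is 2D).
* Secure aggregation and differential-privacy composition are orthogonal
  concerns, deliberately not implemented here.
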