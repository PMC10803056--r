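# rffkde

Privacy-preserving federated population density estimation with random
Fourier features.

## What this is

A server wants a density surface of a user population over an area — for
public-transit planning, epidemiological modelling, or any spatial
analysis — but each location `d_i` is private to its user. Federated
kernel density estimation keeps raw locations on-device: the server
publishes a `P x Q` grid and a bandwidth `h`, each user returns kernel
evaluations on the grid, and the server averages them into the pooled KDE

    f(g | D) = (1/N) Σ_i k_h(g, d_i),      k_h(x,y) = exp(−‖x−y‖² / 2h²).

That protocol has no privacy: each response peaks at the node nearest the
user, so a malicious server reads every location off the argmax.

This package implements the projection alternative. By Bochner's theorem
`k_h(x,y) = E_ω cos(ωᵀ(x−y))` with `ω ~ N(0, h⁻²I)`, so each user draws a
small number `B` of frozen random frequencies and responds with

    G'(d_i)[p,q] = Σ_b cos(ω_bᵀ (g_pq − d_i)),

which the server aggregates as `(1/NB) Σ_i G'(d_i)` — an unbiased
estimate of the pooled KDE for any `B`, even `B = 1`, because users and
features are exchangeable sources of Monte-Carlo averaging. A single
cosine feature is spatially delocalized: its maxima are parallel bands
spanning the whole area, and every location in the equivalence class
`D(x) = {x + α·2πω/‖ω‖² + u : ωᵀu = 0, α ∈ ℤ}` produces identical
responses at every query point, so the user cannot be localized no matter
how often the server asks.

The package contains, fully tested:

* the exact and RFF federated protocols (`federated_kde`,
  `federated_rff_kde`, per-user surfaces, aggregation);
* the maxima-based localization attack and privacy score `Z_i` — the
  attacker's expected localization error in map units
  (`find_local_maxima`, `privacy_score_user`, `privacy_scores`);
* the user-enforced bandwidth policy: maximum bandwidth
  `h_max = √γ·l/(2πj)` from a χ²₂ band-count guarantee, the `(4n+1)·h0`
  rescaling set that keeps invariant bands across multi-bandwidth
  queries, and query refusal (`bandwidth_policy`, `validate_query`,
  `max_bandwidth`, `band_overlap`);
* the geo-indistinguishability baseline (planar Laplace noise, exact
  Gamma radial sampling: `planar_laplace_sample`, `geoind_surface`);
* Gaussian-mixture generators for the synthetic studies
  (`builtin_mixture("grid9" | "octagon8" | "tri1d")`, `sample_mixture`,
  `mixture_density`);
* the privacy–utility evaluation harness: Spearman utility, k-NN
  bandwidth selection, trade-off sweeps and gain-per-privacy-cost
  analysis (`spearman_surface`, `select_bandwidth`, `tradeoff_sweep`,
  `gain_per_cost`);
* CSV/JSON readers and writers for datasets, surfaces, policies and
  attack reports, plus a thin command-line front end
  (`inst/cli/rffkde.R`: `simulate`, `estimate`, `attack`, `policy`,
  `sweep`).

## Worked example

```r
library(rffkde)

grid <- grid_spec(c(-3, 3), 50, c(-3, 3), 50)   # 50x50 nodes on [-3,3]^2
mix  <- builtin_mixture("grid9")                # 3x3 lattice of Gaussians
X    <- sample_mixture(mix, 20000, seed = 1)    # 20000 private locations

# one delocalized feature per user
est   <- federated_rff_kde(X, grid, h = 0.55, B = 1, seed = 1)
truth <- mixture_density(mix, grid)
spearman_surface(est, truth)
#> [1] 0.9487809

# what the malicious server could do with those same responses
mean(privacy_scores(X[1:500, ], grid, "rff", h = 0.55, B = 1, seed = 1)$Z)
#> [1] 2.534535
mean(privacy_scores(X[1:500, ], grid, "exact", h = 0.55)$Z)
#> [1] 0.04644575
```

With one feature per user the estimated surface rank-correlates with the
true density at 0.95, while the attacker's expected localization error is
~2.5 map units — the scale of the whole 6-unit area — versus ~0.05 (one
grid cell) under exact federated KDE on identical data.

From a shell:

```sh
Rscript inst/cli/rffkde.R simulate --mixture grid9 --n 1000 --seed 1 --out pts.csv
Rscript inst/cli/rffkde.R estimate --method rff --data pts.csv \
    --grid "-3,3,50,-3,3,50" --h 0.55 --b 1 --seed 1 --out surf
Rscript inst/cli/rffkde.R policy --h0 0.5 --gamma 0.5 --j 2 --l 10 --check-h 1.25 --bmax 8
# -> exit code 2: 1.25 is not in the (4n+1)*h0 rescaling set
```

## Documentation

The methods vignette (`vignettes/privacy-by-projection.Rmd`) explains the
model, the threat model and policy analysis, the synthetic study
conditions, numerical choices and limitations. Every exported function
has reference documentation.
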