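---
title: "Methods: barcode-based historical biogeography with mkareas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode-based historical biogeography with mkareas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkareas)
```

## Overview

`mkareas` implements a desk-scale pipeline for reconstructing the historical
biogeography of a large clade sampled through public barcode sequences
(ITS-like markers), of the kind used for speciose ectomycorrhizal fungal
groups. The stages are:

1. **OTU clustering** — greedy centroid clustering of sequences at a fixed
   identity threshold (0.97 by default), standing in for species units.
2. **Supertree assembly** — relatively calibrated subclade trees (root crown
   age = 1) are grafted into a unit-root backbone, rescaling each subtree by
   the crown age of the clade it replaces; the composite is then scaled to
   absolute time by a point calibration with an uncertainty range.
3. **Area assignment** — each sequence is assigned to one of nine
   biogeographic areas by a deterministic cascade (country, then
   coordinates, then a manual code); OTU ranges are unions over members,
   with overrides for introduced occurrences.
4. **Ancestral areas** — a one-parameter equal-rates Markov (Mk) model over
   the k areas is fitted by maximum likelihood and marginal relative
   likelihoods are computed for every node.
5. **Stochastic mapping** — full area histories are sampled conditional on
   the tips and the fitted rate; dispersal events are counted per ordered
   area pair and through time windows.
6. **Lineage extraction** — maximal connected node sets with relative
   likelihood > 0.5 for a focal area become lineages, with stem/crown ages
   reported under calibration uncertainty and intersected with geological
   event windows.
7. **Rate partitioning** — per-branch diversification-rate posterior samples
   are randomly paired with stochastic maps, branches are segmented by joint
   (area, rate) regime, and net rates are summarized per area overall and in
   time windows.

All stages run on synthetic data with known ground truth (the
`sim_*` generators), so every property of the pipeline is testable offline.

## The Mk area model

The model has a single free parameter: the transition rate $q$ between any
ordered pair of distinct areas. With $k$ areas the rate matrix has
off-diagonal entries $q$ and diagonal $-(k-1)q$; transition probabilities
have the closed form

$$P_{ii}(t) = \frac{1}{k} + \frac{k-1}{k}e^{-kqt}, \qquad
  P_{ij}(t) = \frac{1}{k} - \frac{1}{k}e^{-kqt}\ (i \ne j),$$

which the implementation uses directly (no matrix exponentials). The
likelihood is computed by Felsenstein pruning with per-node rescaling, so
trees with thousands of tips do not underflow. Polymorphic tips enter as
indicator vectors over their observed areas and missing tips as all-ones
vectors — i.e. the likelihood integrates over the states such tips may
occupy; a tip observed in all $k$ areas is mathematically identical to a
missing tip, and the tests assert this.

**Root weighting.** The root is combined with a uniform $1/k$ prior, which
for this model equals the stationary distribution. The original analysis
tool's root treatment is not documented, so the likelihood-proportional
(FitzJohn-type) alternative is available via
`area_model(..., root_prior = "fitzjohn")`; the default is the
least-assumption choice.

**Rate units.** Branch lengths are relative (root = 1) through most of the
pipeline, so $q$ is per unit root height; divide by the absolute root age
(e.g. 60 Myr) for a per-Myr rate.

`fit_rate()` maximizes the likelihood over $\log q$ in a bounded interval
(default $[10^{-8}, 10^{3}]$) and flags an optimum within 1% of a bound.
Identifiability needs at least two informative, non-identical tip states;
degenerate data warn and slide to the lower bound.

## Stochastic mapping by uniformization

Maps are drawn in two stages: joint node states are sampled root-to-tips
from the conditional distribution given the tips (reusing the pruning
partials), then each branch's internal history is sampled conditional on
its endpoint states. For endpoint conditioning we use uniformization with
dominating rate $\Lambda = kq$. For the equal-rates model this choice makes
the uniformized jump chain *exactly uniform* over all $k$ states (including
self-jumps): $R = I + Q/\Lambda$ has every entry $1/k$. Consequently
$R^n_{ab} = 1/k$ for every $n \ge 1$, the number of virtual jumps $N$ given
endpoints $(a, b)$ satisfies

$$P(N = n \mid a, b) \propto \mathrm{Pois}(n; \Lambda t)\cdot
  \begin{cases}[a = b] & n = 0\\ 1/k & n \ge 1,\end{cases}$$

and the intermediate virtual states are iid uniform with the last fixed at
$b$; jump times are sorted uniforms and self-jumps are discarded. This is
exact, needs no rejection, and is robust for large $qt$. A forward-simulate
rejection sampler is retained in the test suite as an independent oracle;
the two agree in distribution (chi-squared, $\alpha = 0.01$, 10,000 draws
per endpoint pair) and node-state frequencies across 10,000 maps match the
marginal reconstruction within Monte-Carlo error.

**Event dating and windows.** A dispersal event is dated at the age where
the new state begins. Time windows partition $[\text{root age}, 0]$ into
equal spans (10 for dispersal counting, 20 for rate partitioning); an event
exactly on a boundary belongs to the older window. "95% quantile range"
means the 2.5% and 97.5% quantiles with linear interpolation between order
statistics (R type 7) — stated explicitly because the phrase is otherwise
ambiguous; a dispersal edge is drawn when its 2.5% quantile exceeds zero.

## Supertree grafting

`graft()` replaces the backbone clade spanned by the shared tips (crown age
$c$ in backbone units) with the subtree, multiplying every subtree branch
length by $c$. The stem branch is untouched, grafting is local (node ages
outside the replaced clade are unchanged to 1e-9), the result is
ultrametric with root age 1, and scaling to absolute time commutes with
grafting. Shared tips are matched through an explicit two-column table —
never by name fuzzy-matching, which is the classic silent failure of
supertree builds. Subtrees whose root age differs from 1 by more than 1e-6
are renormalized with a message.

The long-branch screen used on barcode trees is visual in practice; the
package's `flag_long_branches()` substitutes an explicit rule — terminal
branches longer than `factor` (default 10) times the median terminal branch
— which is a stated stand-in, not a reconstruction of any author's
criterion.

Calibration uses a point age with a low/high range (default 60 and 57–64
Myr). Ages print half-up-rounded to 0.1 Myr, whole values without decimals,
as `"point (low–high)"`. Because printed tables round each of the three
values independently, recovering a relative age from a printed point value
and re-multiplying need not reproduce the printed bounds; the acceptance
test instead inverts the rounding (it intersects the three intervals of
relative ages consistent with the printed values, which is non-empty for
every table cell it checks).

## OTU clustering

Greedy centroid clustering processes sequences by decreasing length (ties:
input order); each query joins the first centroid (default) or best
centroid with identity at or above the threshold, else founds a new
cluster, so centroids are always the longest members. Identity comes from a
global affine-gap alignment (match +1, mismatch −1, gap open −2, gap extend
−1; a gap of length $L$ scores $-2-(L-1)$) as matching columns over all
alignment columns — gaps count against identity, matching the common
clustering-tool dialect; an `ignore_terminal_gaps` mode is available since
the underlying tool's dialect is not documented in typical methods
sections. No k-mer prefilter is used: at desk scale the exact dynamic
program (implemented in C++) is affordable, and correctness is preferred
over speed. Ties in the traceback are broken deterministically
(diagonal, then gap-in-second, then gap-in-first) so identities are
reproducible; the test oracle uses the same preference order.

## Geography

The assignment cascade is: (1) country, if it maps to exactly one area; (2)
coordinates, if they fall in exactly one area polygon (even–odd rule;
boundary points belong to the polygon, for determinism at borders;
overlapping polygons are an error, not a silent choice); (3) a manual area
code. The original workflow's web geocoding of free-text localities is
non-reproducible and is replaced by the manual column at the same cascade
position. The shipped nine-area polygons are synthetic rectangles (the real
merged-ecoregion polygons are not redistributable) and are labelled as such
— they support tests and format examples, not real assignments. The country
table is user-editable YAML; countries spanning several areas map to sets
and therefore never resolve by the country route, by design.

## Diversification-rate partitioning

Each (rate sample, stochastic map) pair segments every branch at all
change-points of either map, then subdivides so no segment exceeds 2% of
the root height. Per-area rates are **duration-weighted** means over
segments. The weighting matters: unweighted segment means would depend on
the arbitrary subdivision density, whereas duration weighting makes
summaries invariant to refinement (asserted to 1e-9 in the tests); an
unweighted mode exists for comparison. Across pairings the mean and
2.5/97.5% quantiles are reported, overall and in 20 time windows (segments
split at window boundaries, so windowed summaries aggregate exactly to the
overall mean). Pairing is a permutation when the two sample lists have
equal length, otherwise the shorter list is resampled with replacement.
Areas with no duration in a window are absent from the output, not zero.

BAMM-style event tables are consumed by reconstructing each event's regime
downstream with $\lambda(t) = \lambda_0 e^{zt}$ evaluated at segment
midpoints; running the diversification MCMC itself is out of scope and the
synthetic tests use plain per-branch tables.

## The synthetic world

`sim_bd_tree()` simulates birth–death trees forward (Gillespie) from two
crown lineages, stopping when the extant count reaches `n_tips` — simple
stop-at-n, not GSA sampling, which is adequate for generator-scale testing
but would bias tree-prior inference; the final speciation leaves two
zero-length tip branches, which downstream code tolerates. Rate shifts move
one random extant lineage (and its descendants) to new rates at a stated
time, and the true per-branch net rates are returned as a rate map with
exact change-points. Defaults (`lambda` = 0.3, `mu` = 0.1 events/Myr, `q` =
0.05/Myr, k = 9 areas, 10% polymorphic, 10% missing tips) describe a
moderate-sized temperate-tropical clade and are fixed; tests never tune
them toward outcomes. Sequence families are centroid copies with iid
per-site substitutions (no indels or rate heterogeneity — so a green
clustering test establishes correct clustering semantics, not robustness to
alignment-hostile sequences). Generated metadata exercises every cascade
route with known truth.

What green tests do *not* establish: performance of the Mk model under
heterogeneous dispersal regimes (the generator and the model share the
equal-rates assumption), behaviour under real ITS indel structure, or
calibration of the stop-at-n tree prior.

## Numerical choices

- Ultrametricity tolerance: 1e-8 × root age on input, 1e-9 in graft
  invariants; piece-tiling tolerance 1e-9.
- Likelihoods in log space with per-node scaling; `optimize()` on $\log q$
  with tolerance well below the contract's 1e-8 on $q$.
- Quantiles: R type 7 everywhere a "95% range" is reported.
- Rounding for report strings: half-up at 0.1 Myr (`floor(10x + 0.5)/10`),
  avoiding R's banker's rounding.
- Support values in (1, 100] are treated as percentages and rescaled with a
  warning; internal nodes without support are treated as unsupported when
  extracting constraints (logged).
- Polytomies are accepted throughout (pruning, mapping, segmentation).

## Known limitations

- The Mk model ignores range inheritance at cladogenesis
  (dispersal–extinction–cladogenesis-type events); this mirrors the upstream
  analysis choice, made there for computational feasibility.
- $q$ is fixed at its ML estimate during mapping; parameter uncertainty is
  not propagated into dispersal counts.
- The default area polygons are synthetic; real analyses must supply real
  GeoJSON polygons and a complete country table.
- `pair_samples()` records the pairing but the diversification and area
  processes remain independent by construction — the package partitions
  rates by area, it does not jointly model them.
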