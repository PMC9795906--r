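# mkareas

Historical biogeography of large clades sampled through public barcode
sequences — an end-to-end, offline-testable R pipeline.

## Who this is for

Researchers studying speciose clades (the motivating case is
ectomycorrhizal fungi barcoded with ITS) where species units must be built
from sequence clusters, the phylogeny is a composite of calibrated subclade
trees, and biogeographic inference has to scale to thousands of tips. The
package covers:

- **OTU clustering**: greedy centroid clustering at a fixed identity
  threshold (default 0.97), longest sequence as centroid, exact global
  affine-gap alignment (no k-mer heuristics).
- **Supertree assembly**: graft relatively calibrated subclade trees
  (root = 1) into a unit-root backbone, rescaling by the replaced clade's
  crown age; scale to Myr under a point calibration with a low/high range.
- **Area assignment**: deterministic cascade (unambiguous country →
  coordinates in exactly one polygon → manual code), OTU ranges as member
  unions with introduced-occurrence overrides.
- **Ancestral areas**: the equal-rates Mk model over k areas — one free
  transition rate q, closed-form transition probabilities
  `P_ii(t) = 1/k + ((k-1)/k) e^(-kqt)` — fitted by ML with polymorphic and
  missing tips handled as ambiguity, marginal relative likelihoods at every
  node.
- **Stochastic mapping**: endpoint-conditioned area histories by
  uniformization, dispersal counts per ordered area pair with 95% quantile
  ranges, immigration/emigration in equal time windows, and network
  filtering (keep pairs whose 2.5% quantile exceeds zero).
- **Focal lineages**: maximal connected node sets with relative likelihood
  > 0.5 for a focal area; stem/crown ages under calibration uncertainty;
  intersection with geological event windows.
- **Rate partitioning**: random pairing of per-branch diversification-rate
  posterior samples with stochastic maps, branch segments of at most 2% of
  root height with constant (area, rate), duration-weighted per-area means
  with 95% bounds, overall and in 20 time windows.

A synthetic-data module (`sim_bd_tree`, `sim_mk_tips`,
`sim_sequence_family`, `sim_metadata`) generates every input with known
ground truth, so the whole pipeline is exercised without any downloads.

## Worked example

```r
library(mkareas)

# a 120-tip birth-death tree with known per-branch rates,
# tip areas evolved under the equal-rates process (k = 9, q = 0.05)
bd   <- sim_bd_tree(sim_config(n_tips = 120, birth_rate = 0.3,
                               death_rate = 0.05, rng_seed = 42))
tree <- bd$tree
mk   <- sim_mk_tips(tree, q = 0.05, k = 9, polymorphic_fraction = 0.1,
                    missing_fraction = 0.1, seed = 43)

fit <- fit_rate(tree, mk$tips, 9)
#> q_true = 0.05, q_hat = 0.0419  loglik = -200.27

model <- area_model(fit$q_hat, 9)
marg  <- marginal_ancestral(tree, mk$tips, model)   # rows sum to 1

maps <- sample_maps(tree, mk$tips, model, n_maps = 100, seed = 44)
disp <- filter_network(count_dispersals(maps, k = 9))
head(disp[order(-disp$mean), ], 3)
#>    from to mean median q2.5 q97.5
#> 66    2  9 3.68      3    1 8.000
#> 26    2  4 3.41      3    1 7.000
#> 59    3  8 3.35      3    1 7.525

rel <- tree; rel$edge.length <- rel$edge.length / root_age(tree)
lin <- find_focal_lineages(rel, marg, mk$tips, focal_areas = 1:4)
tabulate_lineages(lin, calibration_spec(60, 57, 64))
#>   area n_lineages n_clades     oldest_crown      oldest_stem
#> 1    1          6        2    6.8 (6.4-7.2) 32.5 (30.9-34.7)
#> 2    2          8        3    9.1 (8.7-9.7)   35.6 (33.9-38)
#> 3    3          8        2  10.2 (9.7-10.9)   22.1 (21-23.6)
#> 4    4         10        4 17.3 (16.4-18.4) 58.7 (55.8-62.6)
```

The ML rate lands near the generating `q = 0.05`; the dispersal table lists
the ordered area pairs whose 95% quantile range of counts excludes zero
(mean/median counts across the 100 maps); the lineage table reports, per
focal area, lineage and clade counts and the oldest crown/stem ages in Myr
as `point (low-high)` under the 60 (57-64) Myr calibration.

A command-line interface wrapping the same steps (cluster / assign / graft
/ scale / fit-areas / simmap / rates-by-area) is installed at
`system.file("cli", "mkareas.R", package = "mkareas")`.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) documents the model and its
assumptions, the uniformization sampler, the identity/rounding/quantile
conventions, what the synthetic generators do and do not emulate, and known
limitations.
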