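# shipflow

Gravity-informed forecasting of maritime shipping flows, with a
ballast-water invasion-risk stage.

Global shipping moves non-indigenous aquatic species between ports in
ballast water, and the risk of an introduction depends on how many voyages
connect environmentally similar ports. `shipflow` is for researchers and
analysts who need to forecast origin–destination vessel flows on a port
network and turn them into risk summaries: it builds the directed, weighted
shipping network from trip records, computes the port centralities used as
model features, screens which port pairs plausibly carry traffic, predicts
flows from each source port into destination regions with an
attention-based gravity model, and compares trip-weighted
environmental-distance distributions between predicted and observed flows.

## The model

A scoring network `f` (a small transformer encoder over each source's
destination set, or a deep MLP baseline) turns the 10 gravity features
`x_ij` (port fluxes, distance to the region centroid, bilateral trade,
betweenness/closeness/PageRank at the origin and region medians) into
flows through a softmax allocation that conserves the observed outflow
`O_i`:

    ŷ_ij = O_i · exp(f(x_ij)) / Σ_k exp(f(x_ik))

Training minimises the multinomial cross-entropy between predicted shares
and observed flows; model selection uses the Common Part of Commuters

    CPC(ŷ, y) = 2 Σ_j min(ŷ_j, y_j) / (Σ_j ŷ_j + Σ_j y_j),

averaged over source ports, alongside NRMSE and Pearson correlation. The
forward and backward passes of both models are implemented in the package
as dense matrix code (no deep-learning framework), with gradients verified
against finite differences. Because real AIS-derived trip data is
proprietary, a seeded synthetic-world generator (gravity-law Poisson
flows, heavy-tailed port masses, country/region structure, trade and
environmental fields) makes the whole pipeline testable end to end.

## Worked example

```r
library(shipflow)

world <- generate_synthetic_world(world_config(n_ports = 60, seed = 7))
#> <synthetic_world> 60 ports, 30 countries, 12 regions, 5086 trips on 520 links

net <- build_network(world$trips, world$ports)
metrics <- node_metrics(net)
head(metrics, 3)
#>   port_id betweenness closeness pagerank straightness
#> 1 P001          169.      0.461   0.0245        0.950
#> 2 P002           68.4     0.347   0.0513        0.962
#> 3 P003          133.      0.393   0.0220        0.938

regions <- encode_regions(world$ports, world$country_regions)
samples <- assemble_samples(net, metrics, regions, world$trade)
fit <- train_gravity(transformer_gravity_spec(encoder_layers = 3), samples,
                     train_config(max_epochs = 60, seed = 7))
fit
#> <gravity_fit> transformer_gravity_spec | 150,721 params | best epoch 29 | validation CPC 0.927
glance(fit)
#>   model                    n_params epochs_run best_epoch val_cpc val_nrmse val_corr n_train n_val
#> 1 transformer_gravity_spec   150721         49         29   0.927   0.00489    1.00       45    15
```

The fitted model explains the held-out sources with a CPC of 0.927 — the
predicted flow vectors overlap the observed ones by 93% — against 0.532
for allocating each source's outflow uniformly over its destination
regions (`uniform_baseline_cpc()`). `predict()` returns per-(source,
region) flows that sum exactly to each source's outflow, and
`weight_distribution()` + `compare_distributions()` turn observed and
predicted flows into comparable risk distributions. `run_pipeline()`
chains every stage (network → metrics → link screening → features →
training → risk) with seeded, content-hashed, bit-reproducible artifacts;
`inst/cli/shipflow` exposes the same stages as shell subcommands.

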