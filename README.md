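# agglomnet

Spatial correlation networks of regional health-resource agglomeration
capacity.

## What problem this addresses

Health resources — hospitals, physicians, nurses, beds, health assets — do
not stay put: they concentrate in regions that can attract them, and the
pull one region exerts on another creates a *directed spatial network* of
agglomeration capacities. `agglomnet` is for health-services researchers and
regional scientists who want to go from a plain region-by-indicator panel to
that network and its structural story:

1. **Composite capacity scores** by the entropy weight method. Indicators
   are min-max standardized, turned into column proportions
   *y<sub>ij</sub> = x<sub>ij</sub> / Σ<sub>i</sub> x<sub>ij</sub>*, scored by
   information entropy *e<sub>j</sub> = −(1/ln n) Σ y<sub>ij</sub> ln y<sub>ij</sub>*,
   and weighted by normalized difference coefficients
   *ω<sub>j</sub> = (1 − e<sub>j</sub>) / Σ(1 − e<sub>j</sub>)*; a region's
   capacity is *A<sub>i</sub> = Σ<sub>j</sub> ω<sub>j</sub> x<sub>ij</sub>*.
2. **A modified gravity model** producing directed pull
   *X<sub>ef</sub> = [N<sub>e</sub>/(N<sub>e</sub>+N<sub>f</sub>)] ·
   (P<sub>e</sub>N<sub>e</sub>G<sub>e</sub>)<sup>1/3</sup>(P<sub>f</sub>N<sub>f</sub>G<sub>f</sub>)<sup>1/3</sup> ·
   |g<sub>e</sub>−g<sub>f</sub>| / D<sub>ef</sub>* from population *P*, GDP
   *G*, per-capita GDP *g*, capacity *N* and distance *D*, binarized at a
   mean critical point (row mean by default) into a 0/1 adjacency matrix.
3. **Network characterization**: density, level (hierarchy), efficiency;
   degree, betweenness and closeness centrality per region.
4. **CONCOR blockmodeling** (convergence of iterated correlations, depth 2,
   tolerance 0.2) with a four-role spillover typology per block:
   net spillover, bidirectional spillover, mediator, net beneficial.
5. **QAP correlation** (quadratic assignment procedure) of the network
   against covariate difference matrices (PGDP, Pop, Urb, Stu, Wag, Exp),
   with simultaneous row-and-column permutation inference.
6. **A synthetic-data generator** emulating a 31-region, multi-year panel
   with an east-to-west capacity gradient, planted block structure and
   covariates of controllable network association — so the entire pipeline
   is testable without yearbook data.

## Worked example

```r
library(agglomnet)
cfg <- run_config(years = 2018, n_perm = 999, seed = 42)
rep <- run_pipeline(cfg)          # synthetic world: 31 regions, 10 indicators
y <- rep$years[["2018"]]
```

This run prints (via the summaries below) the following numbers:

```
density 0.366  level 0.506  efficiency 0.678
```

36.6% of region pairs are correlated in at least one direction; 50.6% of
connected pairs are one-way (an asymmetric, hierarchical network); and
redundancy beyond a spanning tree is moderate.

```
block table:
 block size intra_ties out_ties in_ties                    role
     1    8         44       37       3 bidirectional_spillover
     2    7         30       23      15 bidirectional_spillover
     3   10         29       41      44                mediator
     4    6         10       40      79                mediator
```

Blocks 1–2 (the "eastern" planted groups) are internally dense and send
ties outward; blocks 3–4 relay and absorb ties.

```
QAP table:
 factor       r p_one_tailed p_two_tailed
   PGDP  0.1831        0.001        0.002
    Pop -0.0577        0.911        0.187
    Urb  0.2127        0.002        0.002
    Stu  0.0423        0.156        0.350
    Wag  0.1315        0.037        0.037
    Exp  0.1606        0.006        0.006
```

The factors the generator plants with positive association (PGDP, Urb, Wag,
Exp) come out significant; the unplanted Stu and the weakly-tied Pop do
not — exactly the behavior the permutation test should show.

## Command line

```sh
Rscript inst/cli/agglomnet.R simulate --n-regions 31 --from 2004 --to 2018 --seed 1 --out data/
Rscript inst/cli/agglomnet.R score    --panel data/panel_2018.csv --out capacity.json
Rscript inst/cli/agglomnet.R network  --regions data/regions.csv --capacity capacity.json --dist data/dist.csv --out net.csv
Rscript inst/cli/agglomnet.R metrics  --net net.csv --out metrics.json
Rscript inst/cli/agglomnet.R blocks   --net net.csv --depth 2 --tol 0.2 --out blocks.json
Rscript inst/cli/agglomnet.R qap      --net net.csv --covariates data/covariates.csv --nperm 8000 --seed 1 --out qap.json
Rscript inst/cli/agglomnet.R run      --from 2004 --to 2018 --seed 1 --out run_output
Rscript inst/cli/agglomnet.R validate --panel data/panel_2018.csv --dist data/dist.csv
```

## Documentation

The methods vignette (`vignettes/agglomeration-networks.Rmd`) explains the
model, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, and known limitations.
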