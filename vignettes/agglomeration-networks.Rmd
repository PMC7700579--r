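---
title: "Methods: spatial correlation networks of health-resource agglomeration capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial correlation networks of health-resource agglomeration capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agglomnet)
```

## The model and its assumptions

`agglomnet` analyzes how strongly regions pull health resources toward
themselves and how those pulls knit regions into a directed network. The
pipeline has five stages, each a separate module with a programmatic API.

### 1. Entropy-weight capacity scores

Given a nonnegative region-by-indicator matrix $x_{ij}$ ($n$ regions, $m$
indicators, e.g. hospital counts, nurses, beds per 1,000 people), columns
are min-max standardized to $[0,1]$ (removing unit effects), converted to
proportions $y_{ij} = x_{ij} / \sum_i x_{ij}$, and scored by information
entropy

$$e_j = -\frac{1}{\ln n} \sum_i y_{ij} \ln y_{ij}, \qquad 0 \le e_j \le 1,$$

with the continuity convention $0 \ln 0 = 0$. Low entropy means high
dispersion, hence more discriminating information, hence more weight:
$\omega_j = (1 - e_j) / \sum_k (1 - e_k)$. Regional capacity is the weighted
sum $A_i = \sum_j \omega_j \tilde x_{ij}$ over *standardized* values, so
$A_i \in [0,1]$.

Assumptions and edge cases:

* All indicators are treated as positive-direction (more is better) — they
  are resource counts and assets.
* Proportions are computed on the standardized matrix, not raw values, so
  weights are unit-free.
* A constant column standardizes to zeros; its proportion column is all
  zero and is assigned entropy 1 (no information), hence weight exactly 0.
  If *every* column is uninformative the scorer refuses with
  "no discriminating indicator" rather than returning arbitrary weights.
* Weighting can be computed per year (the default in the pipeline: each
  year is an independent cross-section) or on a pooled panel by passing the
  stacked matrix; the run report records which mode produced the numbers.

### 2. Modified gravity model and binarization

The directed pull of region $e$ on region $f$ is

$$X_{ef} = \underbrace{\frac{N_e}{N_e + N_f}}_{\lambda_{ef}}
  (P_e N_e G_e)^{1/3} (P_f N_f G_f)^{1/3}
  \frac{|g_e - g_f|}{D_{ef}},$$

with $P$ year-end population, $G$ real GDP, $g$ per-capita GDP, $N$ the
capacity score and $D$ geographic distance. $\lambda_{ef} + \lambda_{fe} = 1$:
the higher-capacity region of a pair projects the stronger pull, which is
what makes the matrix — and the network — directed. The classical
$X_{ef} = \lambda P_e G_e P_f G_f / D_{ef}^2$ form is provided for
comparison (`traditional_gravity()`).

Numerical choices:

* The economic gap enters as $|g_e - g_f| / D_{ef}$ with exponent 1 on
  distance. The absolute value keeps gravity nonnegative, which the
  thresholding step requires.
* Two regions with *identical* per-capita GDP (possible in synthetic data)
  would annihilate the cell; the gap is floored at
  $\varepsilon = 10^{-9}\,\overline g$ (configurable), so the cell is tiny
  but well-defined.
* **Binarization**: each cell is compared with the mean of its row over
  off-diagonal cells (`row_mean`, default): $a_{ef} = 1$ iff
  $X_{ef} \ge \bar X_{e\cdot}$. Ties ($=$) count as 1. The row rule makes
  the critical point sender-relative, which produces the out/in asymmetry a
  directed network of this kind should show; `col_mean` and `grand_mean`
  are selectable for sensitivity analysis, and the choice is logged in the
  run report. One deliberate refinement: an exactly zero gravity cell never
  becomes a tie, even in an all-zero row where the row mean is also zero —
  zero pull is "no interaction", and an all-zero matrix yields an empty,
  not complete, network.

### 3. Network statistics

With $t$ regions, $s$ = number of *unordered* region pairs connected in at
least one direction, $\alpha$ reciprocated pairs and $\beta$ one-way pairs:

* density $NI = s / [t(t-1)/2]$;
* level $NR = \beta / (\alpha + \beta)$ (1 = fully hierarchical);
* efficiency $NE = 1 - (s - (t-1)) / [t(t-1)/2 - (t-1)]$ (1 at the
  spanning-tree minimum, 0 at the complete maximum; clamped to $[0,1]$ for
  networks sparser than a tree, where the formula exceeds 1).

The unordered-pair convention for $s$ is forced by the denominators
$t(t-1)/2$: with directed tie counts the "densities" would exceed 1. The
directed tie count is reported separately (`tie_counts()`).

Centralities over $L$ nodes:

* degree $PC_i = (\text{out}_i + \text{in}_i)/(2L-2)$;
* betweenness: on the directed graph, $q$'s raw score is half the sum over
  ordered pairs $(j,k)$ of the fraction of $j\to k$ geodesics through $q$
  (so a symmetric network reproduces the classic unordered count, e.g. a
  5-star center scores 6); normalized by $2/(L^2-3L+2)$. Raw values are the
  headline output because published tables of this statistic are raw
  (values like 98.37 exceed any normalized bound).
* closeness: on the *symmetrized* graph, normalized
  $AC_q = (L-1)/\sum_j d_{qj}$, matching published values in $(0,1)$.
  Unreachable pairs get distance $L$ — bounded, standard, and logged with a
  warning; an isolate thus scores $1/L$, small but defined.

The aggregate "out-degree vs in-degree centralization" is reported as
Freeman centralization $\sum_i(\max c - c_i)/(L-1)^2$ per direction and is
flagged descriptive: no standard formula exists for the published aggregate
percentages of this kind, so the package does not claim to reproduce them.

### 4. CONCOR blockmodel and spillover roles

CONCOR partitions regions by iterated correlation: each node's profile is
its out-row and in-column stacked (`cbind(A, t(A))`), the node-by-node
correlation matrix is correlated with itself until every off-diagonal entry
is within the tolerance (default 0.2) of $\pm 1$ (cap: 100 iterations), and
the group splits by the sign structure; recursion to depth 2 gives at most
four blocks.

Two details matter more than they look:

* Profiles keep the structurally zero diagonal positions. Deleting each
  node's own position (a tempting "remove the diagonal" cleanup) misaligns
  the profile vectors across nodes — entry $k$ of one node's trimmed row is
  a different region than entry $k$ of another's — which silently makes the
  partition depend on the input ordering of regions. With aligned profiles
  CONCOR is label-permutation equivariant, and the test suite checks this.
* Zero-variance profiles (isolates) have no defined correlation; each is
  attached after the split to the block holding most of its ties, ties
  broken toward the lowest block id — deterministic and documented.

Per block the package tabulates internal ties, external ties sent and
received, the expected internal share under random mixing
$(\text{size}-1)/(t-1)$ and the actual internal share
$\text{intra}/(\text{intra} + \text{sent})$, then classifies:

| internally dense? | sends $\ge$ receives | receives $>$ sends |
|---|---|---|
| yes | bidirectional spillover | net beneficial |
| no  | net spillover | mediator |

"Internally dense" means the actual share is at least `density_margin`
(default **1.5**) times the expected share. The margin is the genuinely
open design choice here: with a strict margin of 1, almost any clustered
network counts every block as dense, and the four-way typology collapses to
two roles — on the reference 2018 block table all four blocks exceed their
expectation (ratios 1.19, 1.69, 1.44, 1.74), yet two of them are
qualitatively "sparse" blocks. A multiplicative threshold of 1.5 — "half
again as dense inside as chance" — is the smallest round multiplier that
separates the two regimes in that table, reproduces all four reference
roles, and reads as a meaningful definition rather than a fitted constant.
It is a configurable argument, and ties on the send/receive axis resolve
toward the sending-side roles, as printed in the table above.

### 5. QAP correlation

Association between the adjacency matrix and a covariate's
absolute-difference matrix $M_{ij} = |v_i - v_j|$ is the Pearson
correlation over all off-diagonal cells (both orders — the network is
directed, $M$ symmetric). Inference permutes the rows and columns of $M$ by
one node relabeling at a time (the defining QAP move, preserving dyadic
dependence), default 8,000 permutations; the one-tailed p-value uses the
add-one estimator $(\#\{r^\ast \ge r\} + 1)/(B+1)$, which can never return
an exact zero. Both one- and two-tailed values are reported since published
tables rarely say which they used. At $n \le 7$ an exhaustive mode
enumerates all $n!$ relabelings; the sampled null is tested against it.
Covariates may be log-transformed before differencing (`log = TRUE`); the
default is raw.

## The synthetic world

The generator (`synthetic_spec()` / `generate_synthetic()`) emulates the
*kind* of data a provincial yearbook panel provides, not its values:

* 31 regions on a plane with an eastward axis; Euclidean distances
  (pseudo-km). Real studies use road or great-circle distances — supplied
  as input in real runs.
* Latent capacity $c_i = \exp(a\,x_i + \varepsilon_i)$ with eastward slope
  $a$ = `gradient_strength` (default 1) and stable regional noise
  (`noise_sd`, default 0.3); a 5%-per-year growth trend makes capacity
  strengthen over the 15 default years (2004–2018).
* Indicators $x_{ij} = \ell_j\, c_i\, e^{\eta_{ij}}$ with lognormal
  loadings $\ell_j$ spanning several orders of magnitude — positive,
  right-skewed, unit-heterogeneous, exactly what entropy weighting is for.
* Population ($\approx$ 40M median) and per-capita GDP (RMB $3\times10^4$
  scale) rise eastward, so the east is both populous and rich — the
  gradient the method should detect.
* **Planted blocks** (default sizes 8, 7, 7, 9): contiguous east-order
  groups whose intra-block gravity is multiplied by `block_boost`
  (default 5; the recovery experiment uses 20 as "strong"), and
  same-super-group (east pair / west pair of blocks) gravity by
  $\text{boost}^{1/3}$. The hierarchy is deliberate: a two-level bisection
  method can only recover four blocks whose first cut is two-vs-two, and a
  flat plant frequently presents a one-vs-three first cut, which no boost
  strength repairs. This was established empirically before freezing the
  design.
* **Covariates**: PGDP and Pop are the natural regional quantities; Urb,
  Stu, Wag, Exp are planted at configurable strengths (defaults 0.5, 0,
  0.4, 0.5 — a qualitative echo of which factors an analysis of this kind
  finds significant). Planting mixes the scaled total degree of the induced
  network into the log attribute: $\log v_i = 2 s\, z_i +
  \sqrt{1-s^2}\,\epsilon_i$. At $s=0$ the covariate is exactly independent
  of the network; the type-I calibration of QAP is tested against that.

What a green test does **not** establish: that real yearbook data would
reproduce any published density, centrality or QAP coefficient. Those
depend on data the package does not ship; the acceptance suite instead
pins (a) the fully self-contained block-table arithmetic and role labels,
(b) exact agreement of every network statistic with brute-force oracles,
(c) planted-structure recovery, and (d) the statistical calibration of the
permutation test.

## Degenerate inputs and tie-breaks (summary)

| situation | behavior |
|---|---|
| constant indicator column | weight 0, entropy 1 |
| all columns constant | error "no discriminating indicator"; the generator falls back to uniform capacity |
| equal per-capita GDP pair | gravity floored at $\varepsilon$, cell $\approx 0$ |
| zero gravity cell | never a tie, even in an all-zero row |
| gravity cell equal to its row mean | tie, recorded as 1 |
| empty network | level undefined (NA + warning) |
| unreachable pair (closeness) | distance $L$, warning |
| CONCOR isolate | attached to block with most ties, then lowest id |
| role-rule ties (send = receive) | bidirectional (dense) / mediator (sparse) |

## Known limitations

* CONCOR's recursive bisection caps blocks at $2^{\text{depth}}$ and cannot
  represent genuinely odd block counts well; no goodness-of-fit statistic
  for the partition is computed.
* The QAP module does correlation only; QAP regression (MR-QAP) and any
  panel-data extension are out of scope, and each year is analyzed as an
  independent cross-section.
* The out/in centralization summary is descriptive, not a reproduction of
  any published aggregate.
* Synthetic distances are planar Euclidean; no GIS input or map rendering
  is provided (a plain adjacency/edge-list export stands in for network
  drawings).
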