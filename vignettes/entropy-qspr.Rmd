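---
title: "Entropy descriptors and curvilinear QSPR: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy descriptors and curvilinear QSPR: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entroqspr)
library(dplyr)
```

## The model

A compound is represented by its hydrogen-suppressed molecular graph: heavy
atoms are vertices, bonds are edges. Bond orders, aromaticity, charges and
metal coordination are deliberately ignored — every bond is one simple edge
and degrees are taken in that simple graph. This is not an approximation made
for convenience: the published degree-pair partition of Oxaliplatin (a
platinum complex) is only reproducible under exactly this convention, so it
is the convention the whole pipeline uses. Disconnected graphs are accepted
with a warning rather than rejected, because every quantity below is
edge-local.

All descriptors factor through the **degree-pair edge partition**: the counts
$n_{ij}$ of edges whose endpoint degrees are $(i, j)$ with $i \le j$,
$\sum n_{ij} = m$ the bond count. A topological index is

$$T_\phi(G) = \sum_{(i,j)} n_{ij}\, \phi(i,j)$$

for one of ten edge-weight rules $\phi$ (ABC, F, GA, H, ISI, M1, M2, S, SO,
R; see `?edge_weight`). Its entropy counterpart is the Shannon entropy of the
normalized edge-weight distribution $p_e = \phi_e / T$:

$$\mathrm{Ent}_\phi(G) = \ln T - \frac{1}{T}\sum_{(i,j)} n_{ij}\,
  \phi(i,j)\ln\phi(i,j), \qquad 0 \le \mathrm{Ent}_\phi \le \ln m ,$$

with equality on the right exactly when all edge weights are equal (any
regular graph, any index). Two conventions matter and are fixed here:

* **The logarithm is natural.** The published worked example
  ($\mathrm{Ent}_F(\text{Oxaliplatin}) = 2.7843$ from $T = 238$) is
  reproduced by $\ln$ and by no other base; we verified this numerically
  before freezing the choice.
* **$0\ln 0 = 0$.** The only weight that can vanish is ABC on a $(1,1)$
  edge (an isolated two-atom component); its entropy term is taken as zero
  by continuity, with a warning. A graph consisting *only* of such edges has
  zero total ABC weight and its ABC entropy is an error, not a number.

Entropy is always computed cell-wise from the partition, at $O(\#\text{cells})$
cost; equality with the per-edge Shannon form is a tested invariant
(to $10^{-12}$ over random graphs), not an implementation path.

Worth knowing when comparing against the published tables: the printed GA sum
for Oxaliplatin (16.3826) disagrees with its own formula, which gives
16.3821 — the package follows the formula, and the GA *entropy* (2.8323)
reproduces either way. The printed ABC entropy 2.8317 is a truncation of the
true 2.83176. The drug descriptor fixture `crc_descriptors()` is transcribed
verbatim, including two entries (the GA entropies of Carboplatin and
Fluorouracil) that exceed the $\ln m$ bound for any plausible bond count and
are evidently data-entry slips; they are shipped as data because the
regression tables were computed from them, and they are not reproduced from
structures.

## The regression families and their statistics

`fit_model()` fits one property on one descriptor under five families:
linear, quadratic, cubic (ordinary least squares on the raw polynomial
design), logarithmic ($y$ on $\ln x$, needs $x > 0$) and exponential
($\ln y$ on $x$, needs $y > 0$, reported multiplicatively as
$Y = a e^{b_1 X}$). The statistics block follows the curve-estimation
convention throughout: $r^2 = 1 - SSE/SST$;
$r = \mathrm{sign}(b_1)\sqrt{r^2}$ for single-predictor families and
$+\sqrt{r^2}$ for polynomials; adjusted
$R^2 = 1-(1-r^2)(n-1)/(n-k-1)$; $SE = \sqrt{SSE/(n-k-1)}$;
$F = (r^2/k)\,/\,((1-r^2)/(n-k-1))$ with $k$ slope coefficients; coefficient
CIs from the $t$ distribution on $n-k-1$ degrees of freedom. For the
transformed families every statistic lives on the transformed scale — this
is what the published tables print (e.g. $SE = 0.2$ for an exponential fit
of molecular weight). No multiple-testing correction is applied anywhere,
matching the source analysis; the report exposes raw p-values and a
$p \le 0.05$ indicator, and the renderer prints p-values to three decimals
(so anything below 0.0005 shows as `0.000`).

### The cubic parameterization behind the published tables

While reproducing the fourteen-drug tables we found that the published
"cubic" rows are **not** least squares on $\{1, x, x^2, x^3\}$: the full
cubic of molecular weight on the ABC entropy has $r^2 = 0.920$, while the
tables print $a = 323.0$, $x^2$ and $x^3$ coefficients $-75.9$ and $24.7$,
$SE = 66.5$, $F = 39.4$, $r^2 = 0.877$ — all of which are reproduced *exactly*
by OLS on $\{1, x^2, x^3\}$, i.e. with the linear term excluded. On this
narrow descriptor range (entropies span roughly 2.2–4.1) the three powers
are almost collinear (tolerances near $10^{-4}$), and curve-estimation
software silently drops terms in that regime.

```{r cubic}
d <- inner_join(crc_descriptors(), crc_properties(), by = "compound")
glance(fit_model(d, "cubic", x = Ent_ABC, y = MW))$r.squared                    # full cubic
glance(fit_model(d, "cubic", x = Ent_ABC, y = MW, powers = c(2, 3)))$r.squared  # published
```

The package therefore keeps `family = "cubic"` as the genuine full cubic
(anything else would break exact recovery of noiseless cubic data and the
nesting of $r^2$ across degrees) and exposes the published parameterization
through `powers = c(2, 3)`. The printed linear-term coefficients of those
cubic rows (18.4 and so on) match no least-squares fit of these data that we
could identify; they are honoured only where the source uses them — inside
the printed validation equations, which `crc_validation_models()` carries
verbatim as literature-coefficient models and which do reproduce the printed
held-out predictions.

### Model selection and validation

`best_model()` selects, per descriptor–property pair, the family with the
largest $r^2$, breaking ties toward fewer slope coefficients (a flat
parsimony rule; with nested polynomials an exact tie essentially only occurs
on degenerate data). On the drug tables the cubic wins for every predictable
property; topological surface area and density stay below $r^2 = 0.35$ under
every published parameterization and are reported, not suppressed.

`validation_table()` treats printed-coefficient models (`qspr_model()`) and
fitted `qspr_fit` objects identically, so held-out validation never requires
regenerating training structures. Calculated values are kept at full
precision and rounded (2 d.p.) only in `write_validation_csv()`. Of the
twelve published held-out predictions, six reproduce exactly from the
printed inputs; the remainder deviate by 0.1–0.7 units, consistent with the
authors having evaluated at higher-precision descriptor values than they
printed. The package reports what the printed inputs give.

## The synthetic-data generator

`gen_graph()` grows a degree-capped random tree (each new atom attaches
uniformly to an atom with free valence) and then closes rings between
non-adjacent degree-deficient pairs; the result is connected, simple, with
degrees in $[1, \texttt{max\_degree}]$. `gen_dataset()` computes one entropy
descriptor $h$ per generated graph and simulates the property as
$y = f(h) + N(0, \sigma^2)$ under a known family.

Defaults are fixed once and mirror the real study: 14 compounds, 8–40 heavy
atoms (the span from fluorouracil to docetaxel), valence cap 4, ring
intensity 0.15 (small-molecule ring counts scale roughly with a sixth of the
atom count), cubic ground truth with the published molecular-weight
coefficients and $\sigma = 65$, the residual scale of that model. A single
integer seed drives everything; per-compound substreams are derived by
counter so compound order is irrelevant.

What the generator emulates is the *shape* of the problem: connected
chemistry-like degree sequences and a curvilinear descriptor–property link
with Gaussian noise. What it does not emulate: element identities, valence
chemistry, realistic ring systems, correlated measurement error across
properties, or the strong inter-correlation of the ten entropy indices seen
in real drugs. Passing synthetic tests therefore demonstrates correctness of
the machinery (descriptor computation, fitting, coverage of intervals), not
predictive validity on new chemistry.

Problem sizes used by the test-suite experiments, chosen as comfortable for
the statistics they probe: 100 random graphs for the entropy/index oracle
equivalences; $n = 50$ compounds, 200 noise replicates at $\sigma$ equal to
1% of the response range for the confidence-interval coverage experiment
(observed coverage must stay at or above 0.90 for nominal 0.95); 150–200
compounds for the ML experiments.

## The machine-learning stage

The source study *proposes* an ML extension but publishes no numbers, so
this stage is property-tested only. `ml_preprocess()` standardizes features
(zero-variance columns are dropped with a warning). `select_features()`
offers recursive feature elimination (backward elimination by random-forest
importance, 200 trees, deterministic under seed) and PCA projection.
`cv_evaluate()` runs seeded k-fold cross-validation of a random forest
(500 trees), $\varepsilon$-SVR (radial kernel defaults) or gradient-boosted
trees (200 rounds, depth 3, learning rate 0.1, single-threaded for exact
reproducibility), reporting per-fold and mean MSE, RMSE and $R^2$. These
hyperparameters form the small fixed grid we settled on; with only fourteen
real compounds any real-data ML output should be treated as exploratory, and
the tests run on synthetic data where the answer is known (noiseless signal
must beat a permuted-target baseline for every learner).

## Known limitations

* Only degree-based, edge-local descriptors: no distance-based (Wiener-type)
  or vertex-partition indices, no 3D or stereochemical information.
* The regression layer is deliberately single-descriptor curve estimation,
  matching the source methodology; it is not a general modelling toolkit
  (no multi-descriptor models, regularization or robust fits).
* $n = 14$ training compounds: every statistic inherits the fragility of
  small-sample regression, and the near-collinearity of the polynomial
  design on this descriptor range is exactly what produced the published
  reduced cubics.
* The SMILES adapter collapses bond orders and ignores charges by design;
  structures whose published descriptor values were computed under different
  perception conventions may disagree with regenerated values, which is why
  the drug tables ship as fixtures.
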