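---
title: "Methods: from pooled drug perturbations to a consensus apoptosis network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pooled drug perturbations to a consensus apoptosis network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoptonet)
```

`apoptonet` turns a pooled drug-perturbation expression compendium into a
small, validated gene interaction network. This vignette is the package's
own account of the statistics involved: the models, the parameters that
matter, what the synthetic data do and do not emulate, and the numerical
and design choices a maintainer should know about.

## 1. Pooled differential expression

All compound-treated samples are pooled into one "perturbed" group and
compared with the controls through a per-gene linear model with an
intercept and a binary perturbation indicator. Pooling is a deliberate
bias–variance trade: per-compound contrasts at 2–5 samples each have almost
no power, while a pooled contrast across thousands of samples recovers the
genes of the *shared* response program (cell death being the dominant one
for anticancer agents). The cost is that compound-specific responses are
averaged away; the package makes no attempt to model them.

The moderated *t* shrinks each gene's residual variance $s^2$ (on
$d = n-2$ df) toward a prior value $s_0^2$ estimated across genes:
$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},\qquad
t = \frac{\widehat{\mathrm{logFC}}}{\sqrt{\tilde s^2\,(1/n_c + 1/n_p)}},$$
with a two-sided p-value on $d + d_0$ df (standard normal when
$d_0 = \infty$). The hyperparameters $(d_0, s_0^2)$ come from moment
matching on $\log s^2$ (`limma::fitFDist()`, the estimator of the cited
moderated-t methodology); with fewer than 10 usable variances the package
refuses to moderate ($d_0 = 0$, classical pooled *t*), and exactly equal
variances give the degenerate $d_0 = \infty$. Multiplicity is controlled by
Bonferroni, $\min(1, p \cdot m)$, with $m$ defaulting to the number of
tested rows; on the real array platform this multiplier is the full 22,268
probe sets. Note that this is a family-wise error control even though such
thresholds are often loosely referred to as FDR cutoffs; the package names
the column `adjusted_p`. Probes collapse to genes by minimum raw p-value
— the most significant probe represents the gene; the rule is a package
choice, as collapsing conventions vary.

## 2. Apoptosis enrichment

Two complementary tests ask whether apoptosis genes are over-represented
in the perturbation signature.

*Hypergeometric over-representation.* With $N$ universe genes (the rows of
the collapsed expression matrix), $K$ of them in the set, and $k$ of the
$n$ signature genes in the set, the p-value is the upper tail
$P(X \ge k)$ *including* the observed count — the standard
over-representation convention. The set is intersected with the universe
before testing, which is how a 380-gene annotation list becomes a 368-gene
set on a 12,632-gene array.

*Absolute-mean permutation enrichment.* Selection-free: the enrichment
score is the mean $|t|$ of the set members (apoptosis genes are both up-
and downregulated under perturbation, so a signed mean would cancel), and
the null is built by drawing equally many gene names uniformly without
replacement, `n_perm = 10000` times by default. The p-value uses the
add-one convention $p = (1 + \#\{ES_{\mathrm{null}} \ge ES\})/(1 + B)$,
so it is never zero and is super-uniform under the null. The statistic fed
to the test is the moderated $t$ (variance-stabilized, the pipeline's own
test statistic); the log fold-change can be substituted by passing a
different score vector.

## 3. The network model and its score

The joint distribution of the module genes is modeled as a Gaussian
Bayesian network: given a DAG $G$,
$$g_i \mid \mathrm{parents}(g_i) \sim
  N\!\Big(\textstyle\sum_j \beta_{ij}\,\mathrm{parent}_j(g_i) + \alpha_i,\ \sigma_i^2\Big),$$
i.e. every local distribution is a linear regression with Gaussian noise.
Structures are compared through the exact log marginal likelihood
$\mathrm{score}(G : D) = \log \int p(D \mid \theta, G)\, p(\theta \mid G)\,
d\theta$, which under a uniform structure prior makes the difference of two
scores the log Bayes factor.

**Prior construction.** The conjugate prior (Gaussian coefficients given
the variance, Inverse-Gamma variance) must satisfy parameter modularity
and *likelihood equivalence* — Markov-equivalent DAGs must score equally,
since observational data cannot distinguish them. A free-standing
Normal–Inverse-Gamma prior applied independently to every family does
**not** have this property. The package therefore ties all families to one
joint Normal–Wishart prior over the genes (parametric matrix $2b_0 I$,
equivalent sample size $\nu$, degrees of freedom chosen so a parent-free
family has exactly an $\mathrm{Inv\text{-}Gamma}(a_0, b_0)$ variance
prior). The family score is then the ratio of joint subset marginals,
$\log m(\mathrm{Pa} \cup \{i\}) - \log m(\mathrm{Pa})$, and equivalence
holds by construction. With prior mean 0 this is *identical* to a
Normal–Inverse-Gamma regression marginal with variance prior
$\mathrm{Inv\text{-}Gamma}(a_0 + p/2,\ b_0)$, coefficient precision
$2 b_0$, and intercept precision $\nu$ — the form the quadrature oracles
in the test suite integrate numerically.

Defaults: $\mu_0 = 0$, $\nu = 1$, $a_0 = 1$, $b_0 = 1$ — a unit
equivalent-sample-size prior centered at zero. Data are centered per gene
before scoring (scale preserved), which makes $\mu_0 = 0$ exact rather
than approximate; centering is configurable. The closed form is primary;
`fit_local_params(n_draws = ...)` samples the exact posterior for
MCMC-style parameter summaries and for cross-checking, since the conjugate
model admits exact integration and simulation-based estimation would add
only Monte-Carlo error.

**Search.** The number of labeled DAGs explodes combinatorially —
`count_dags(13)` evaluates Robinson's recurrence in exact big-integer
arithmetic and yields ≈ 1.87×10³¹ — so the package uses hill climbing
over single-edge moves (add, delete, reverse; the classical move set) with
random restarts. The first climb starts from the empty graph (a
reproducible baseline), later restarts from random DAGs at edge
probability 0.2; `n_restarts = 2` by default. Score decomposability means
a move's gain is one or two family-score differences, and family scores
are cached by (node, parent set), so a climb rescores only what changed.
Ties among equally improving moves break lexicographically by (move type,
source, target), making search deterministic given the seed. The search
trace counts every candidate structure scored, including rejected ones —
the package's reading of "structures compared", documented because the
alternative (counting accepted moves only) gives much smaller numbers.

## 4. Bootstrap model averaging

A single optimum overfits: small data perturbations can redirect many
edges. The package therefore learns one network per bootstrap resample of
the samples (columns, drawn with replacement; `B = 200` by default — the
replicate count is a stability choice, larger is better and 200 gives
stable 75%-threshold estimates), then:

* **Score-interval filter.** Replicates whose total score falls outside
  the central 95% empirical interval (between the 2.5% and 97.5%
  score quantiles, inclusive) are dropped. The interval convention is a
  package decision; the underlying idea — discard structurally atypical
  replicates before averaging — admits several readings and this is the
  symmetric one.
* **Edge confidence.** The confidence of a directed edge is its frequency
  among retained replicates. A *skeleton* confidence (frequency of the
  unordered pair in either direction) is always reported alongside,
  because direction flips *within* a Markov equivalence class are an
  expected feature of score-equivalent learning, not noise: the data
  cannot orient covered edges, so a pair may appear 50/50 in the two
  directions while being present in every single replicate.
* **Consensus.** Edges with confidence strictly above 0.75 (configurable;
  a flag switches to ≥) form the consensus network. `level = "directed"`
  (default, matching the directed presentation of a consensus interaction
  network) thresholds the directed frequency; `level = "skeleton"`
  thresholds the pair frequency and orients by majority — the latter is
  what the package's structure-recovery experiments use, precisely
  because recovery is measured on the skeleton and the directed reading
  double-counts orientation uncertainty. The consensus is *not* forced
  acyclic: averaging DAGs does not yield a DAG, and the result is an
  interaction network, not a probability model.

## 5. Validation against a reference network

The reference interaction network is an undirected simple graph read from
an edge-list TSV or SIF file (symbols uppercased; self-loops and duplicate
pairs dropped and counted). Each consensus edge, direction ignored, is
**direct** if the pair is a reference edge, otherwise **indirect** if any
path connects the two genes — all *shortest* paths are recorded, since
with only 13 analysis genes most true dependencies are mediated by genes
outside the analysis set — otherwise **unsupported**. The evidence
subnetwork is the union of direct-validated edges and every node and edge
on a recorded shortest path. Path length is not bounded by default; any
path counts as indirect support, which is deliberately permissive and
should be read accordingly.

## 6. What the synthetic generator emulates — and what it does not

`simulate_cmap_like()` produces, at desk scale, the structure of the real
input: 1,000 null background genes, 178 signature genes with
perturbed-group shifts of magnitude 0.06–0.32 (log2 units, random sign —
the magnitude range of a pooled perturbation contrast), a 13-gene module
with 15 edges whose joint law follows a known linear-Gaussian SEM
($|\beta| \in [0.5, 1.5]$, unit noise), 100 control + 400 perturbed
samples, residual noise SD 0.5, GMT gene sets splitting an apoptosis list
into pro/anti with overlap, and a reference network containing the true
skeleton plus decoy nodes and planted two-hop paths (so direct,
indirect, and unsupported validation outcomes all occur). Module genes
additionally receive a perturbed-group mean shift drawn as 0.5–0.8 of
each gene's marginal SD, so that the module reliably lands inside the
differential-expression signature — mirroring the intended analysis flow,
in which the network genes are by construction signature members. The shift
moves only the group means; the within-group covariance that structure
learning consumes is untouched.

Not emulated: probe-level intensity models and normalization (the
pipeline consumes normalized matrices), batch effects, per-compound
heterogeneity, and any relation between the gene sets and real biology.
Passing recovery tests on this generator therefore demonstrates
correctness of the *inference machinery* under the stated model — linear
dependencies, Gaussian noise, i.i.d. samples — not robustness to the
violations real compendia add (heavy tails, batch structure,
nonlinearity).

All randomness descends from one master seed through named substreams
(`substream_seed()`), so every artifact of an end-to-end run is
bit-reproducible.

## 7. Numerical choices and degenerate inputs

* Subset marginals are evaluated via Cholesky factors of the posterior
  scatter matrix $R = 2b_0 I + S + \tfrac{\nu n}{\nu+n}\bar x \bar x^\top$;
  a family score needs one factorization of the parent block plus a Schur
  complement. Scores are finite for any data with $n \ge 1$.
* Hill-climb acceptance requires an improvement above 1e-9 to keep
  floating-point ties from cycling; equivalence assertions in the tests
  use 1e-8 relative, quadrature comparisons 1e-6 relative.
* Zero moderated variance makes $t = \pm\infty$, $p = 0$, and the row is
  flagged rather than silently dropped.
* Statistical guarantees (family-wise error, super-uniformity) are
  asserted in the tests with exact binomial Monte-Carlo tolerance at the
  0.995 level: an unbiased estimate of a probability sitting exactly at
  its bound exceeds it about half the time, so a hard inequality on the
  point estimate would reject correct code.
* Test problem sizes: recovery experiments use 13 genes, 15 edges,
  1,000 samples, 100 bootstrap replicates, 5 master seeds; calibration
  sweeps use 200 null replicates; exhaustive scoring covers all 25
  three-node and 543 four-node DAGs.

## 8. Known limitations

* The consensus can contain cycles and is not a generative model.
* Observational, linear-Gaussian learning cannot orient covered edges;
  directed confidences for such pairs are intrinsically split, which is
  why the skeleton table exists.
* Pooling compounds assumes a shared response program; compound classes
  with opposing transcriptional effects partially cancel.
* The hypergeometric and permutation tests share the signature and score
  vector; they are complementary views, not independent replications.
* With 13 analysis genes, "indirect" validation via unbounded shortest
  paths is permissive; interpret validated counts together with the path
  lengths the report records.
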