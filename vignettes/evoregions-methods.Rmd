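---
title: "Delimiting evolutionary regions from phylogenies and assemblages: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting evolutionary regions from phylogenies and assemblages: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoregions)
```

`evoregions` implements a complete workflow for asking how the
evolutionary composition of tree assemblages is structured across a
continent-scale landscape: compute phylogenetic beta diversity between all
assemblages, group them, ordinate them, find the lineages that diagnose
each group, decompose phylogenetic diversity (PD) into group-restricted
versus shared parts, and test whether climate or geographic position
better predicts group membership. This vignette documents the models, the
tunable parameters, and the places where a design decision had to be made.

## Dissimilarity: the PhyloSor complement

For assemblages $i$ and $j$ on a rooted, dated phylogeny,

$$d_{ij} \;=\; 1 - \frac{BL_{ij}}{\tfrac12\,(BL_i + BL_j)},$$

with $BL_{ij}$ the summed length of branches having at least one
descendant tip in both assemblages and $BL_i$ the rooted PD of assemblage
$i$. The Jaccard-type analogue (`unifrac_complement()`, unique over union
branch length) is provided as a secondary metric; PhyloSor similarity
always dominates UniFrac similarity, as Sørensen dominates Jaccard.

Two conventions matter.

* **Rooted PD.** $BL_i$ includes the path from the assemblage's most
  recent common ancestor up to the global root; the root edge itself is
  excluded, so PD is invariant to a zero-length root stalk. The
  alternative (unrooted PD at the assemblage MRCA) changes single-clade
  assemblages most; the rooted choice makes the "reciprocally
  monophyletic $\Rightarrow d = 1$" identity hold exactly only when the
  two clade stems carry no length, which is how the boundary fixture in
  the tests is built. Users probing sensitivity can compare against
  unrooted conventions implemented elsewhere.
* **Shared branch = shared tip-descendant incidence.** "Shared clades"
  is operationalized as branches whose descendant tips occur in both
  sites — the standard PhyloSor construction.

All pairs are computed from one post-order branch-incidence pass and dense
matrix products ($O(S^2 B)$ in BLAS), never per-pair subtree extraction; a
400-site × 150-genus dataset takes about a second, and thousands of sites
remain practical on one CPU.

## Grouping: k-means with Elbow and silhouette diagnostics

K-means needs points in a feature space, not a dissimilarity matrix. The
default representation feeds the *rows* of the symmetric matrix to
Lloyd's algorithm — exactly what happens when a dissimilarity matrix is
coerced to a matrix and handed to `stats::kmeans()`, the most plausible
reading of how this analysis is usually run — while `representation =
"pcoa"` offers the statistically cleaner principal-coordinates embedding.
Each call runs `n_init` (default 25) random restarts and keeps the lowest
total within-cluster sum of squares (TSS); empty clusters are re-seeded
deterministically from the point farthest from its centroid, so all
groups are non-empty and results are bit-reproducible given `seed` (a
required argument: the package never reads hidden global RNG state).

`select_k()` summarizes the TSS curve by its discrete second difference
$tss(k{-}1) - 2\,tss(k) + tss(k{+}1)$, returning the interior $k$ where
curvature peaks — a formalization of the visual "elbow" judgement, which
is why the full curve is always returned too. Silhouette widths
$s(i) = (b_i - a_i)/\max(a_i, b_i)$ are computed on the *original*
phylogenetic dissimilarities, not the k-means feature space, because fit
should be measured in the quantity of scientific interest; members of
singleton groups get $s(i) = 0$ by convention.

## Ordination: evolutionary PCA

The site × branch matrix holds $x_{ib}\,\ell_b$ (presence of any
descendant of branch $b$ at site $i$, weighted by branch length
$\ell_b$). Rows are Hellinger-transformed
($y_{ib} = \sqrt{w_{ib}/\sum_b w_{ib}}$, giving each row unit sum of
squares), columns centred, and the matrix decomposed by SVD. Site scores
are $U\Sigma$; branch loadings are $V$, reported with a readable clade
label (the first and last descendant tips). Variance explained per axis is
$\sigma_k^2 / \sum \sigma^2$. The sign of each axis is fixed by making its
largest-magnitude loading positive. The family of evolutionary ordinations
admits several weighting variants; this presence/absence × branch-length
construction is anchored by an exact limit: on a star phylogeny with unit
branch lengths it reduces to an ordinary centred PCA of the
Hellinger-transformed genus matrix, which the tests assert to 1e-8.

## Indicator genera and clades

For genus $g$ and a candidate set $c$ of groups (all non-empty proper
subsets, capped at 5 groups): specificity $A$ = (occupied sites within
$c$)/(occupied sites), fidelity $B$ = (occupied sites within $c$)/(sites
in $c$), statistic $\sqrt{A B}$. The best combination per genus is
reported; ties break to the smaller, then lexicographically earlier,
combination, for determinism. $A$ is the unweighted (site-count) version
matching the probability definition above; a group-size-corrected variant
is available via `correct_group_size`. No permutation p-values are
computed: indicators are ranked by the statistic.

The same machinery runs on the site × node matrix (a node is present
where any descendant tip is). `indicator_nodes()` then walks nodes by
decreasing statistic (ties to larger clades) and keeps each node only if
it is not nested with an already-kept node, yielding the non-nested
indicator clades per group.

## PD partition

With threshold $t$ (default 0.6), the PD restricted to group/combination
$c$ is the PD lost when the genera whose best-combination specificity
exceeds $t$ *for $c$* are pruned; the shared component is the remainder,
so restricted components plus shared equal the total exactly. Two choices
keep the decomposition honest: a genus belongs to at most one pruning set
(its best combination — the source analysis is silent on overlap, and
disjoint assignment prevents double counting that would break the
identity), and PD is computed over the genera present anywhere in the
data, so taxa never observed cannot inflate totals. Raising $t$ shrinks
every pruning set, so each restricted component is monotone non-increasing
in the threshold (a tested invariant).

## Climate versus geography

`compare_classifiers()` fits two random forests (500 trees) on the same
sites: climate = {MAT, MAP, TS, CWD}, geography = {continent, latitude,
longitude}. Out-of-bag accuracy operationalizes "proportion of
assemblages correctly classified" — it is the natural averaged estimate a
forest provides, and a k-fold alternative would measure the same contrast;
importances are mean decreases in Gini impurity. Sites without a continent
assignment are dropped from both models so the accuracies are comparable.

`rank_climate_variables()` fits, per candidate variable, a binomial
regression of a binary within-region split on the standardized variable
with a varying intercept per 1° × 1° grid cell (Laplace-approximated via
`lme4::glmer`) to absorb spatial autocorrelation, and ranks models by AIC.
When the grid degenerates to essentially one site per cell (fewer than
10% of cells shared), the random intercept is not estimable and the
function falls back to a plain binomial GLM with a message; z-scoring
makes the ranking invariant to affine rescaling of the inputs.

`delimitation_correspondence()` compares the K = 2 labels with binary
tropics delimitations: the latitude band |lat| ≤ 23.4° is computed
internally, anything else (e.g. a freezing-regime flag) is read from
logical covariate columns. The match fraction is maximized over the two
cluster-to-class mappings, hence always ≥ 0.5.

## The synthetic generator: what it emulates, and what it does not

`simulate_dataset()` produces the full study input with known truth:

* **Phylogeny** — a pure-birth (Yule) tree (`ape::rphylo`, extinction 0)
  with branch lengths in Myr. Default `birth_rate = 0.05`/Myr puts a
  150-genus tree's root near 100 Myr (root age grows like
  $\log n/\lambda$), the magnitude of a dated angiosperm genus tree.
  Birth-death trees would add realism but nothing the recovery tests need.
* **Niche traits** — two independent Brownian traits (cold tolerance,
  drought tolerance), variance `sigma2 = 0.01`/Myr so tip variance is
  near 1 on that tree. Brownian covariance = `sigma2` × shared path
  length is the operational meaning of niche conservatism here, and is
  verified against the closed form by Monte-Carlo.
* **Landscape** — latitude −47..49°, longitude −120..−35°, elevation
  skewed low up to 4000 m; a minimum-temperature proxy declining with
  |latitude| and elevation sets the freezing flag at the
  `freezing_fraction` quantile (default 0.3, shifted so "freezing" means
  below 0). MAT tracks minimum temperature; TS rises with |latitude|; an
  independent dryness gradient drives MAP down and CWD (≤ 0) more
  negative. The continent label is a longitude split. Covariates are
  generated before occupancy, so environment is exogenous to composition
  — the causal direction the niche-conservatism hypothesis assumes.
* **Assembly, niche-conservatism scenario** — frost is modelled as a hard
  physiological filter, reflecting that only lineages evolving freezing
  tolerance persist where it freezes: the standardized cold trait is cut
  at fixed quantiles into a tropical-only band, a generalist band
  (`generalist_fraction`, default 0.23), and a cold-specialist band
  (`specialist_fraction`, default 0.12) confined to freezing sites —
  planting, through the Brownian clustering of the trait, roughly a tenth
  of the realized PD as cold-restricted. Within the allowed sites,
  occupancy probability is `base_prob` (0.6) times a Gaussian niche on
  the drought axis with breadth `filter_width` (0.9 SD of the
  standardized gradient). Geography plays no role.
* **Assembly, dispersal-limitation scenario** — a third Brownian trait
  thresholded at its median assigns each genus a home continent;
  occurrence off-continent is down-weighted to `leak = 0.02`, and the
  drought niche still applies. Climate (beyond drought) plays no role, so
  the climate-vs-geography contrast reverses. `mixed` applies both.
* **Truth** — `true_labels` follow the planted mechanism
  (freezing/continent), and `true_restricted_fraction` is computed by the
  generator from the realized data: the share of PD (over genera present
  anywhere) lost by pruning the cold-specialist band. Setting
  `filter_width = Inf` switches all filtering off — the structureless
  null, under which clustering finds no stable groups (mean silhouette
  below 0.15 in the tests).

Sites drawn with fewer than 5 genera are redrawn (up to 100 attempts,
then an error naming the site), so the generator's output is valid
pipeline input while the ≥ 5-genera site filter (`filter_min_genera()`,
applied after reconciling names with the tree) is still a real,
exercised stage for external data.

What the generator does **not** emulate: species-to-genus aggregation
noise, spatial autocorrelation of occupancy beyond what the environment
induces, realistic paleogeography or diversification linked to niche
state, and the detailed climatologies behind most published tropics
delimitations (only the latitude band and the freezing line are
generated; the others are accepted as user-supplied flags). Passing
recovery tests therefore show the pipeline recovers *planted* structure
of the hypothesized kind at realistic sizes — not that any particular
empirical dataset will behave as cleanly.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on 150 genera × 400 sites ×
10 seeds per scenario — large enough for stable clustering (the K = 2
split matches the planted freezing delimitation at ≥ 95% on average, and
the planted restricted-PD fraction is recovered within 5 percentage
points) while a complete run stays near a minute. Brute-force oracles
(explicit root-path branch sets, double-loop silhouettes, contingency
counting) pin the fast implementations to 1e-10/1e-12 on dozens of random
instances. Dissimilarities are symmetrized and clamped to [0, 1] after
the matrix products to absorb last-bit floating-point asymmetry;
eigenvalue ties in the ordination are resolved by the sign convention
only, so axes within a tied eigenvalue block are identified only up to
rotation (as in any PCA).

## Known limitations

* K-means on dissimilarity-matrix rows is a heuristic embedding; PCoA is
  one flag away and hierarchical alternatives are deliberately out of
  scope.
* Indicator statistics come without permutation inference; ranking, not
  testing, is the goal.
* The PD partition depends on the disjoint best-combination assignment;
  with many groups and diffuse indicators, per-combination restricted
  components can be small even when group-level restriction is real —
  inspect the full indicator table in that case.
* The grid-cell mixed model absorbs, but does not model, spatial
  autocorrelation; autoregressive structures are out of scope.
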