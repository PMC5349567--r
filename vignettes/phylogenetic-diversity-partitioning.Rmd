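---
title: "Partitioning microbial diversity with phylogenetic entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning microbial diversity with phylogenetic entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopart)
```

## The model

`phylopart` measures the diversity of a community of sequences (reads
assigned to OTUs) placed on a rooted phylogeny, and partitions it across a
grouping of the samples (sites, treatments, compartments). The central
quantity is the phylogenetic generalization of Shannon entropy: every
branch $i$ of the tree, with length $L_i$, carries the frequency $p_i$ of
observations descending from it, and

$$H_\gamma = -\sum_i \frac{L_i}{\bar T}\, p_i \ln p_i,
\qquad \bar T = \sum_i L_i\, p_i .$$

$\bar T$ is the abundance-weighted mean root-to-observation path length;
dividing by it makes the entropy unitless and valid for non-ultrametric
trees. We report the exponential $D_\gamma = e^{H_\gamma}$, an
*equivalent number of lineages*: the number of branches of a star tree
with equally abundant tips that would show the same diversity. This is
the only depth scaling under which that star-tree identity holds exactly,
which is why the package uses it (and why the identity is one of the test
suite's anchor properties).

Within groups, $a_{ig}$ is the frequency of branch $i$ among the reads of
group $g$ alone, and $p_{ig} = w_g\, a_{ig}$ the joint frequency under
group weights $w_g$. Alpha diversity is the weighted mean per-group
entropy, evaluated with the *pooled* $\bar T$:

$$H_\alpha = \sum_g w_g\, H_p(g), \qquad
H_p(g) = -\sum_i \frac{L_i}{\bar T}\, a_{ig} \ln a_{ig},$$

and beta diversity is the mutual information between an observation's
lineage and its group,

$$H_\beta = \sum_i \underbrace{\frac{L_i}{\bar T}
\sum_g p_{ig} \ln \frac{p_{ig}}{p_i\, w_g}}_{H_{\beta i}} .$$

Because the same $\bar T$ is used throughout, the decomposition is
additive, $H_\gamma = H_\alpha + H_\beta$, exactly — per-group $\bar T_g$
values would break it, which is why the package does not offer them. Each
per-branch term $H_{\beta i}$ is a scaled Kullback–Leibler divergence,
hence nonnegative; summed over a lineage (a node and all its descendants)
and divided by $H_\beta$, it says how much of the between-group signal
that lineage carries. This is how individual clades — including ones with
no useful taxonomic annotation — are flagged as the drivers of community
differences.

Mutual information is bounded by the entropy of the fixed margin, the
grouping: $H_\beta \le H(G) = -\sum_g w_g \ln w_g$. The ratio

$$\text{turnover} = H_\beta / H(G) \in [0, 1]$$

is the package's headline between-group statistic. For two equal-weight
groups it has a concrete reading: the fraction of observations sitting on
lineages not shared between the groups (0 = identical communities, 1 =
disjoint). The test suite checks this identity on star trees for planted
unshared fractions over the whole grid $x \in \{0, 0.1, \dots, 1\}$.

## Equal group weighting

Sequencing depth routinely differs by orders of magnitude across
compartments. With read-proportional weights, the deeper compartment
dominates $p_i$ and every statistic derived from it. The default
estimator therefore pools reads within each group, normalizes to
$a_{ig}$, and weights groups equally, $w_g = 1/G$: each group contributes
equally, not proportionally to its read count. A consequence worth
stating: turnover becomes invariant to multiplying any one group's depth
by any constant (a tested property). `weighting = "proportional"`
restores the unmodified estimator for comparison. Within a group,
samples are pooled rather than re-weighted — replicates of one
compartment are treated as more observations of the same community; a
sample-level equalization would be a different design and is deliberately
not the default.

The natural logarithm is used throughout so that `exp()` converts
entropies to equivalent-number units; `H_beta` and `exp(H_beta)` are both
reported, but the normalized turnover is preferred as the summary because
an "equivalent number of samples" is ambiguous when samples have unequal
sizes.

## Significance

Whether $H_\beta > 0$ reflects structure rather than sampling noise is
assessed by permutation: group labels are randomly re-assigned to
*individual reads* (not samples, not OTUs), preserving each group's read
total exactly. Conditional on the margins this is a multivariate
hypergeometric redistribution of each OTU's pooled count, and the package
draws it with Patefield's algorithm (`stats::r2dtable`). The full
statistic, including equal weighting, is recomputed on every permuted
table; the one-sided p-value uses the add-one Monte Carlo estimator
$p = (1 + \#\{H_\beta^{perm} \ge H_\beta^{obs}\})/(1 + B)$, so $p$ can
never be 0 and its floor is $1/(B+1)$. The default is $B = 999$. Because
the test conditions on total counts there is no rarefaction anywhere in
the pipeline — subsampling would discard exactly the rare-lineage signal
the per-branch decomposition is meant to expose. A sample-level
permutation (`unit = "sample"`) is available as a sensitivity check when
reads within a sample cannot be treated as exchangeable.

Calibration is tested, not assumed: under exchangeable labels (replicates
drawn from one shared profile) the rejection rate at $\alpha = 0.05$ over
200 simulated null datasets with 999 permutations each must fall inside
the 99% binomial band [0.02, 0.09].

## Pairwise turnover and ordination

`pairwise_turnover()` treats every pair of samples as a two-group design
with weights (1/2, 1/2), which makes the resulting distance matrix
independent of per-sample depth. `pcoa_turnover()` applies classical
metric scaling (`stats::cmdscale`): square, double-center, keep the top
positive eigenvalues. Turnover is not guaranteed Euclidean-embeddable;
negative eigenvalues are dropped — no Lingoes or Cailliez correction —
and their share of total inertia is reported so the user can judge the
distortion. Requesting more axes than there are positive eigenvalues
truncates with a warning.

## Filters and lineage addressing

Two standard pre-processing steps are built in, applied in this order:
`filter_min_count()` drops OTUs with fewer than 75 reads in total
(overridable), then `subset_by_taxa()` keeps OTUs whose lineage string
matches a target list — by default the eight candidate phyla / CPR names
(Parcubacteria, Microgenomates, Saccharibacteria, Dependentiae, OP3, OP1,
BRC1, WS3) shipped in `inst/extdata/candidate_phyla.txt`. The order
matters (the threshold is applied to totals *before* subsetting) and the
non-commutativity is documented by a test rather than hidden.

Lineages are addressed by internal node label when the newick provides
one, otherwise by a deterministic `L<node number>` naming, so reports can
point at unnamed clades. OTUs present in the counts but absent from the
tree are a hard error — silently dropping them would bias $\bar T$ —
while tree leaves without counts are retained at zero frequency
($0 \ln 0 \equiv 0$) so the branch set, and hence the depth
normalization, does not depend on which OTUs happen to be observed.

## What the synthetic generator emulates — and what it does not

Real drinking-water surveys of this kind have no public read archive to
regress against, so the package ships a generator whose defaults encode
the study structure the pipeline targets: three compartments
(groundwater GW, carbon filters CF, post-chlorination CHL), four
replicate samples each, unequal per-sample depths (8000 / 2000 / 4000
reads) to exercise the equal-weighting estimator, and two planted
lineages — a "treated-water" clade expected to hold 4%, 68% and 58% of
GW, CF and CHL reads respectively, and a near-groundwater-exclusive clade
at 58%, 7% and 10%. The remaining mass sits in a pool shared at
identical conditional frequencies, so the expected between-group signal
comes only from the planted shares.

Design choices inside the generator, made once:

* **Trees.** Clades are pure-birth (Yule) subtrees rescaled to unit
  root-to-tip depth and attached on unit stems. Equalizing clade depths
  keeps branch-length geometry from confounding the planted abundance
  structure — recovery experiments then measure the statistic, not the
  tree simulator's variance. The `star` model is kept as the analytic
  reference geometry.
* **Within-clade weights** are log-normal (sd 0.5) and *shared across
  groups*, adding rank-abundance realism while keeping clade shares — and
  therefore expected turnover — exactly at their planted values.
* **Reads** are plain multinomial draws per sample. This is the simplest
  defensible observation model and makes "recovery within 3 multinomial
  standard errors" a well-defined acceptance check. A Dirichlet
  overdispersion knob exists for stress-testing, but it is off in the
  preset: with it on, the 3-SE recovery bound would no longer be the
  right yardstick.

Consequences to keep in mind when extrapolating to real data: replicates
are idealized (multinomial noise only), so within-group mean turnover on
the preset is far smaller than the several percent typical of real
surveys; there is no compositional drift over time, no chimeras, no
PCR bias, and no sequence-level error. Passing the recovery tests shows
the estimator chain is correct and calibrated under its own assumptions —
not that those assumptions hold in any particular plant.

## Numerical choices and degenerate inputs

* $0 \ln 0 \equiv 0$; branches with $p_i = 0$ are skipped. The root has
  no branch; any branch with $p_i = 1$ contributes nothing ($\ln 1 = 0$).
* All entropies are invariant to a global rescaling of branch lengths
  ($\bar T$ rescales identically) — tested to $10^{-12}$.
* A single group is valid for $\gamma$/$\alpha$ but makes $H_\beta$ and
  turnover undefined: these error rather than return 0.
* Missing branch lengths parse to 0 with a warning; negative lengths are
  rejected.
* p-values are reproducible given `seed`, which is stored in every
  result object and output file.

The test suite's problem sizes are chosen for exhaustiveness per CPU
minute: oracle cross-checks run on 200 random instances of at most 8
leaves against a first-principles summation, the additivity and
conservation properties on 500 random instances, calibration on 200 null
datasets of 1200 reads, and recovery on 100 preset seeds of 56,000 reads
each. The identities being checked are scale-free, so small instances
are the efficient place to detect algebraic errors.

## Known limitations

Only the Shannon (order-1) member of the Hill family is implemented;
there is no rarefaction (by design) and no analytic null — significance
is always Monte Carlo. Pairwise turnover matrices are computed densely,
O(S²) partitions, which is fine for tens to hundreds of samples but not
for thousands. The iTOL export writes annotation datasets
(branch-gradient colors and per-group multibars); it does not render
trees.
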