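# phylopart

Phylogenetic entropy partitioning of microbial communities.

## What it is for

Amplicon surveys of low-biomass environments — drinking water is the
motivating case — are dominated by lineages with little or no taxonomic
annotation (candidate phyla, CPR, ultra-small bacteria). Checklist-style
analyses over named taxa miss them. `phylopart` instead measures
diversity directly on a rooted phylogeny of the OTUs and asks, branch by
branch, *which lineages make the communities in different compartments
different* — no taxonomy required, and no rarefaction that would throw
away rare-lineage signal.

It is aimed at microbial ecologists with an OTU-by-sample count table
(TSV), a rooted tree with branch lengths (newick), and a sample-to-group
mapping.

## The statistic

For each branch $i$ with length $L_i$, let $p_i$ be the frequency of
reads descending from it, $a_{ig}$ the frequency within group $g$, and
$p_{ig} = w_g a_{ig}$ with group weights $w_g$ (equal by default, so a
deeply sequenced compartment cannot dominate). With
$\bar T = \sum_i L_i p_i$:

- **Gamma**: $H_\gamma = -\sum_i (L_i/\bar T)\, p_i \ln p_i$, reported as
  $D_\gamma = e^{H_\gamma}$ *equivalent lineages* — the size of a star
  tree of equally abundant tips with the same diversity.
- **Alpha**: $H_\alpha = \sum_g w_g H_p(g)$ with
  $H_p(g) = -\sum_i (L_i/\bar T)\, a_{ig} \ln a_{ig}$; per-group
  $D_g = e^{H_p(g)}$.
- **Beta**: the mutual information between lineage and grouping,
  $H_\beta = \sum_i (L_i/\bar T) \sum_g p_{ig} \ln\!\big(p_{ig}/(p_i w_g)\big)
  = H_\gamma - H_\alpha$, decomposed into nonnegative per-branch
  contributions $H_{\beta i}$.
- **Turnover**: $H_\beta / H(G) \in [0,1]$; for two equal groups, the
  fraction of reads on lineages the groups do not share.

Significance of $H_\beta$ comes from re-assigning group labels to
individual reads (margins preserved; `stats::r2dtable`), recomputing the
full statistic each time. See the vignette in `vignettes/` for the
model, design choices and caveats.

## Worked example

The package ships a synthetic three-compartment drinking-water scenario
(groundwater GW, carbon filters CF, chlorination CHL; 4 replicates each,
unequal depths) with a planted treated-water clade and a planted
groundwater-exclusive clade:

```r
library(phylopart)

ds   <- generate_dwtp_preset(seed = 1)
part <- phylo_partition(ds$tree, ds$counts, ds$grouping)
print(part)
#> Phylogenetic diversity partition
#>   H_gamma = 1.708953  D_gamma = 5.5232 equivalent lineages
#>   H_alpha = 1.478064  D_alpha = 4.3844
#>     GW: D = 4.2501
#>     CF: D = 4.2443
#>     CHL: D = 4.6724
#>   H_beta  = 0.230890  (mutual information, max H(G) = 1.098612)
#>   turnover = 0.2102
```

The pooled community behaves like ~5.5 equally abundant independent
lineages; 21% of the grouping information is explained by compartment.
The planted treated-water clade (internal node `L42`) is recovered as the
dominant driver of between-compartment diversity, with per-group read
shares matching the planted 4% / 68% / 58%:

```r
tre <- ds$truth$planted$treated$node   # "L42"
lineage_contribution(part, tre)        # 0.546: 54.6% of beta diversity
group_lineage_proportions(part, tre)
#>    GW    CF   CHL
#> 0.040 0.675 0.577

permutation_test(ds$tree, ds$counts, ds$grouping, 999, seed = 42)
#> Permutation test of phylogenetic beta diversity (read-level)
#>   observed H_beta = 0.230890
#>   null mean 0.000210, sd 0.000051 (999 permutations)
#>   p-value = 0.001
```

The compartment structure is as significant as 999 permutations can
show (p = 0.001, the estimator's floor). Downstream helpers:
`filter_min_count()` and `subset_by_taxa()` (count and candidate-phyla
filters), `pairwise_turnover()` + `pcoa_turnover()` (ordination of
samples by turnover distance), `export_itol_annotations()` (iTOL
branch-gradient and multibar datasets), and `write_dataset()` /
`inst/cli/phylopart.R` for shell use.

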