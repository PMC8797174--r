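---
title: "Simulating poaching in multi-tier elephant social networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating poaching in multi-tier elephant social networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poachnet)
library(dplyr)
```

African savanna elephants live in a nested fission-fusion society: matrilineal
core groups of close kin, aggregated into bond groups of intermediate kin,
aggregated into clans of distant kin; females in different clans are treated
as non-kin. Poaching removes individuals non-randomly -- trophy hunters take
the oldest animals, and the loss of socially central "brokers" is a concern in
any harvested social species. `poachnet` implements a complete in-silico
poaching study on such populations: it assembles a population-wide weighted
association network from field sighting counts, simulates network formation
in virtual populations with an individual-based model, deletes nodes
(targeted by age category or betweenness centrality, or at random), and
quantifies the structural damage with four global indices and Hedges' g
effect sizes.

This vignette documents the models, the assumptions, the tunable parameters
and the numerical choices. It states no empirical result that the package's
tests do not themselves compute.

## Assembling a network from sighting counts

Field protocols yield two tiers of association records. Within a core group
$G$ observed $n_G$ times, a dyad $(i, j)$ is scored by how often the two were
seen together ($x_{ij}$) and how often neither was seen ($d_{ij}$). The
within-group association index is

$$AI_{ij} = \frac{x_{ij}}{n_G - d_{ij}},$$

the fraction of *observable* sightings at which the dyad was together
(`within_group_ai()`). Between-individual associations across core groups are
not observed directly; they are projected from three measurable quantities.
An individual's gregariousness is the mean of its within-group association
indices over the $|G| - 1$ dyads that involve it (`gregariousness()`), which
keeps the score at 1 for an individual seen with every groupmate at every
observable sighting. For two groups $G$ and $B$, the co-sighting fraction is

$$f_{G,B} = \frac{n_{G,B}}{n_G + n_B + n_{G,B}}$$

(`group_pair_fraction()`), and the proxy association between individuals
$i \in G$ and $a \in B$ is the product
$p(i,a) = f_i \, f_a \, f_{G,B}$ (`cross_group_weight()`). `assemble_network()`
applies the within-group index to same-core dyads and the product form to all
cross-core dyads; dyads with weight zero are simply absent edges. Both kinds
of weight live on one $[0,1]$ scale and are recorded without reweighting; the
package makes no attempt to correct association-index bias (half-weight
variants and the like are deliberately out of scope).

`amboseli_population()` ships the multi-tier structure of the reference
free-ranging population (10 core groups, 83 females, eight bond groups, three
clans). Individual ages are not published, so the fixture assigns age
categories by a seeded draw from the same bounded samplers used by the
virtual-population generator, conditioned on each core group's printed size;
the group structure itself is fixed and seed-invariant. The assignment is
synthetic and documented as such.

## Virtual populations

`generate_population()` draws static populations (no births, deaths or
aging). The default composition mirrors the reference population's scale:
3 clans holding 4, 3 and 1 bond groups, and 10 core groups spread over the 8
bonds. Per core group, the age-category counts are drawn independently from
bounded integer samplers:

| category     | bounds  | mean | sampler                      |
|--------------|---------|------|------------------------------|
| young adult  | [1, 5]  | 2    | $1 + \mathrm{Bin}(4, 1/4)$   |
| prime adult  | [0, 7]  | 2    | $\mathrm{Bin}(7, 2/7)$       |
| mature adult | [0, 3]  | 1    | $\mathrm{Bin}(3, 1/3)$       |
| matriarch    | [1, 1]  | 1    | constant                     |

We use shifted binomial samplers rather than discretized triangular laws
because a triangular distribution on $[1, 5]$ cannot have mean 2 (its minimum
achievable mean is about 2.17 with the peak pinned at the lower bound); the
binomial form $\min + \mathrm{Bin}(\max - \min, (\mu - \min)/(\max - \min))$
respects the bounds and hits the stated mean exactly, and is unimodal near
the mean. Every core group gets exactly one matriarch and, because the
young-adult minimum is 1, has at least two members.

## The network-formation simulator

`simulate_network()` runs a spatiotemporally nonexplicit individual-based
model. At initialization every dyad receives a fixed per-step association
probability drawn from a triangular distribution whose (min, mode, max)
depend on the dyad's kinship tier and unordered age-category pair. A
triangular law is used because only the range and a central value of the
empirical association indices are recoverable, not their distribution. At
each time step, one uniform draw per *context* (a core group, or a pair of
core groups) switches that context on when the context probability exceeds
the draw; each dyad in an "on" context then associates when its own fixed
probability exceeds a second uniform draw, incrementing its interaction count
by exactly one. Probabilities are drawn once and held fixed; counts are
nondecreasing and bounded by the elapsed steps. Snapshots store raw integer
counts as edge weights (an optional normalization by $t$ maps them to
$[0,1]$ for qualitative comparison with association-index networks, nothing
more).

Two modelling choices deserve emphasis. First, within-group contexts default
to probability 1 (ungated), so within-core association is driven purely by
dyad probabilities; whether the original design gated within-group dyads on a
group-level event is ambiguous, so the gate is exposed as
`within_context_prob` rather than guessed. Second, between-group context
probabilities are drawn from the pair's tier entry for a matriarch-matriarch
dyad -- the matriarchs standing in for their groups -- which keeps the whole
parameterization inside one probability table.

### The default probability table

The empirical per-tier, per-age ranges are not published; only their ordering
is recoverable. The defaults in `default_probability_table()` are therefore
package constants -- configuration, not ground truth -- chosen once to satisfy
the two qualitative constraints and to place simulated networks in a
realistic saturation regime:

* componentwise tier ordering, core $\ge$ bond $\ge$ clan $\ge$ nonkin, for
  every fixed age pair (base triples 0.30/0.50/0.80, 0.06/0.12/0.22,
  0.02/0.05/0.10, 0.004/0.015/0.04);
* a weak increase with the partners' age ranks (a bump of 0.005 per rank step
  above a young-young pair, added to min, mode and max alike).

Under these defaults a 500-step run of a default population reaches a median
density (fraction of dyads with at least one interaction) of roughly 0.7, with
successive 100-step density gains shrinking -- the plateau regime where the
deletion experiments operate. Mean edge weight at 500 steps ranks
core > bond > clan > nonkin, reproducing the intended kinship structure; both
properties are asserted by the test suite, not merely stated here.

## Deletion experiments

`run_deletion_experiment()` runs the poaching simulation proper: a full
factorial over networks, deletion metrics (betweenness centrality computed
once on the intact network, or age-category rank with matriarchs highest),
deletion types (targeted vs random) and the deletion-proportion grid 0 to
0.20 in steps of 0.04, with `replicates` repetitions of each condition. The
targeted pool is the top 20% of nodes by the metric, fixed per network; each
replicate shuffles the pool and removes prefixes of the shuffle along the
proportion grid, so a replicate's removal sequences are nested (an option
disables nesting; recomputing ranks after each increment is likewise
non-default). Removal counts use round-half-up of proportion x n -- on 83
nodes the grid removes 3, 7, 10, 13 and 17 individuals -- because base R's
banker's rounding would be surprising here and no rounding rule is canonical.
Ties at the pool boundary, and ordering within an age category, are broken by
the seeded RNG.

After every increment the experiment records four global indices
(`network_metrics()`):

* **clustering coefficient** -- global transitivity on the unweighted
  skeleton;
* **weighted diameter** -- the maximum shortest-path distance under
  inverse-weight link lengths (stronger association = shorter link);
* **weighted global efficiency** -- the mean over ordered pairs of the
  reciprocal shortest-path distance, with unreachable pairs contributing 0;
* **weighted modularity** -- Q of the partition found by Newman's
  leading-eigenvector method on the weighted graph;

plus the connected-component count and a fragmentation flag ("breakdown" is
operationalized as at least two components, isolated nodes included). On a
fragmented network the diameter is reported over reachable pairs with the
flag raised, rather than as infinity, so deletion trajectories remain
plottable. Betweenness defaults to weighted geodesics (the footnoted
definition of shortest paths), with Brandes' fractional split among tied
geodesics; an unweighted mode is exposed because the original index may have
been binary. All of these stand on igraph's graph algorithms and are verified
in the test suite against hand-written brute-force oracles (Floyd-Warshall,
exhaustive geodesic enumeration, triplet census, exhaustive bipartition
search) at an absolute tolerance of 1e-9.

`filter_weak_links()` implements the pre-deletion weak-link manipulation:
every weight is divided by the network's maximum and edges at or below 1, 2
or 3 percent of the maximum are removed without replacement (the threshold is
inclusive, reading "values up to x percent" literally).
`filtered_deletion_study()` flags networks that break down from filtering
alone, excludes them, and runs the deletion experiment on the survivors;
`weak_link_census()` tabulates the filtered dyads by age pair and kinship
tier.

## Effect sizes

Because replicate counts are a design choice rather than a biological sample
size, targeted-vs-random contrasts are summarized with standardized effect
sizes instead of hypothesis tests. `hedges_g()` computes

$$g = \left(1 - \frac{3}{4(n_a + n_b) - 9}\right)
      \frac{\bar a - \bar b}{s_p},$$

with the conventional large-sample variance
$(n_a + n_b)/(n_a n_b) + g^2/(2(n_a + n_b))$ for its confidence interval, and
classifies $|g|$ as negligible (< 0.2), small ($\ge$ 0.2), medium ($\ge$ 0.5)
or large ($\ge$ 0.8), all bounds inclusive. `summarize_contrasts()` applies
this per metric, index and proportion (plus any extra grouping columns), also
reporting both samples' means with t-based 95% confidence intervals.
Proportion-zero cells contrast identical distributions and yield $g = 0$; a
zero pooled variance with a zero mean difference resolves to $g = 0$ by the
same logic, while a nonzero difference with zero variance is an error.

## Worked example

A miniature end-to-end run (sizes kept small so the vignette is cheap to
reproduce; the package defaults are 100 populations, 500 steps and 100
replicates):

```{r example}
pop <- generate_population(seed = 1)
net <- simulate_network(pop, n_steps = 500, snapshot_at = 500,
                        seed = 2)$network[[1]]
res <- run_deletion_experiment(net, metrics = "betweenness",
                               replicates = 10, seed = 3)
con <- summarize_contrasts(res)
filter(con, proportion == 0.2)[, c("index", "g", "magnitude",
                                   "mean_targeted", "mean_random")]
```

```{r plots, fig.width = 7, fig.height = 6, eval = FALSE}
autoplot(res)  # mean +/- 95% CI trajectories per deletion type
autoplot(con)  # Hedges' g per index and proportion
```

## Numerical and reproducibility choices

* Every stochastic entry point takes a `seed`; seeding is local (the global
  RNG stream is never clobbered) and two runs with the same seed are
  bitwise-identical. Experiment-level functions seed once for the whole
  factorial.
* "Probability greater than RDN" is implemented as a strict inequality
  against a uniform draw, so probability 0 never fires and probability 1
  always does.
* Triangular sampling uses the closed-form inverse CDF; degenerate supports
  return the constant.
* Floating-point comparisons in tests use an absolute tolerance of 1e-9;
  leading-eigenvector community detection refuses splits without positive
  modularity gain (igraph's stopping rule), and the planted-partition test
  cross-checks its Q against an exhaustive bipartition search.
* Readers (`read_network()`, `read_population()`, ...) validate and reject
  malformed input -- self-loops, duplicate edges, nonpositive weights,
  missing GraphML attributes -- rather than repairing it silently.

## What the synthetic data do and do not show

The generator emulates the *structure* of multi-tier sighting data: bounded
demographic composition, tier- and age-ordered association probabilities, and
within/between count tables that are consistent by construction
($x + d \le n_G$). It does not emulate observation bias, temporal
autocorrelation of sightings, demographic turnover, or post-deletion social
reorganization (the study design is explicitly static, and time steps are
not calibrated to real poaching rates). Passing tests therefore demonstrate
that the pipeline implements its stated models faithfully and reproduces the
study's qualitative findings on data with known structure -- lower clustering
and efficiency and higher diameter after betweenness-targeted deletions, no
fragmentation without prior weak-link filtering -- not that those findings
transfer to any particular field population.

The scaled problem sizes used by the automated checks (20 virtual networks
and 25 replicates for the deletion contrast; 100 populations for the
demographic contracts) were chosen as the smallest batches at which the
Monte-Carlo summaries are stable; the package defaults remain at the full
study scale.
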