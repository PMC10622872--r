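---
title: "Bayesian inference under the multispecies coalescent with migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian inference under the multispecies coalescent with migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`mscmig` implements full-likelihood Bayesian inference under the multispecies
coalescent with migration (MSC-M), also known as the isolation-with-migration
model.  A rooted binary species tree carries three sets of parameters,
$\Theta = (\tau, \theta, M)$: species divergence times $\tau$, mutation-scaled
population sizes $\theta$ (one per extant and ancestral population), and
directed migration rates $M_{sj}$.  Time runs from 0 at the present into the
past and both $\tau$ and $\theta$ are measured in expected mutations per
site; a pair of sequences in a population of size $\theta$ coalesces at rate
$2/\theta$.  The migration rate $M_{sj} = N_j m_{sj}$ is the expected number
of migrants arriving in population $j$ from population $s$ per generation
(defined forward in time); tracing a lineage backward, a lineage currently in
$j$ jumps into $s$ at rate $4 M_{sj}/\theta_j$.  A migration band is active
exactly while both populations exist: the half-open lifespan of a tip is
$[0, \tau_{\mathrm{parent}})$ and of an ancestral population
$[\tau, \tau_{\mathrm{parent}})$, so whether a band exists depends on the
current divergence times — this matters for the sampler (below).

The data are multilocus sequence alignments $X = \{X^{(i)}\}$, one alignment
per locus, evolving under JC69 on the per-locus genealogy.  The latent
variable per locus is the full gene tree $G^{(i)}$: topology, coalescent
times, and the complete migration history (number, times, directions of
migration events on each branch).  Loci are independent (free recombination
between loci, none within).  A per-locus heredity scalar $h_i$ (1 autosomal,
3/4 X-linked, 1/4 Y or mitochondrial) rescales $\theta$, and by default
rescales the migration rate the same way, since both rates enter as
$\cdot/(\theta_j h_i)$; `log_density_mscm()` exposes
`heredity_scales_migration` for the alternative reading.

The sampler targets
$p(\Theta, G \mid X) \propto p(\Theta)\, p(G \mid \Theta)\, p(X \mid G)$.

### The gene-tree density

Within each population the process of coalescence and migration is a
piecewise constant-rate Poisson process; rates change at coalescent events,
migration events, and species divergences.  Splitting population $j$ at locus
$i$ into $K_{ij}$ such segments with durations $t_{ijk}$ and lineage counts
$n_{ijk}$, with $c_{ij}$ coalescent events, $w_{sji}$ migration events from
$s$ into $j$, and $I_{sjk}$ indicating an active band during segment $k$:

$$p(G\mid\Theta)=\prod_j \prod_i \left(\frac{2}{\theta_j h_i}\right)^{c_{ij}}
\prod_s \left(\frac{4M_{sj}}{\theta_j h_i}\right)^{w_{sji}}
\exp\left\{-\sum_k \left(\frac{n_{ijk}(n_{ijk}-1)}{\theta_j h_i}
+ n_{ijk}\sum_s I_{sjk}\frac{4M_{sj}}{\theta_j h_i}\right) t_{ijk}\right\}.$$

`decompose()` builds the segment decomposition and `log_density_mscm()`
evaluates the density in log space (zero-rate events map to $-\infty$).  A
hand-transcribed closed form for a canonical six-sequence genealogy with a
back-and-forth migration pair (`log_density_worked_example()`) serves as an
independent oracle: the general implementation must agree term by term, and
the test suite checks agreement to $10^{-10}$ over random parameter draws.
Events falling exactly on a boundary are resolved by the half-open
convention: at a divergence time the lineage is already in the ancestor.

### Priors

Gamma priors — parameterised by (shape, rate) with mean shape/rate throughout,
to avoid scale/rate confusion — on every $\theta$, on every $M$, and on the
root age.  Conditional on the root age, the non-root node ages are uniform
over the order-constrained region (each node younger than its parent), a
proper prior with density $\propto 1/\tau_{\mathrm{root}}^{k}$ for $k$
non-root internal nodes.  This choice for the non-root ages is a
reconstruction of standard practice; only the root age carries a gamma prior.

## The MCMC sampler

One iteration sweeps six move classes (all implemented in C++; the R layer
only assembles the model and the trace):

* **Population sizes**: multiplier (sliding window on $\log\theta_j$);
  because the phylogenetic likelihood does not depend on $\theta$, only the
  prior and gene-tree density enter.  Per-locus sufficient statistics
  (coalescent counts, pair-time exposures, migration counts and active
  exposures) are aggregated across loci so each update costs O(1).
* **Migration rates**: sliding window with reflection at 0, same cached
  statistics.
* **Migration-event times**: sliding window with reflection inside the
  interval bounded by the neighbouring events on the lineage and by the
  activity window of the band; coalescent times are untouched, so the
  likelihood is unchanged.
* **Divergence times, extended rubber band**: a window proposal for
  $\tau_X$ inside $(\tau_l, \tau_u)$ (bounded by the daughters' and parent's
  ages).  Gene-tree node ages in the affected populations are rescaled
  linearly on $(\tau_l,\tau)\to(\tau_l,\tau')$ and
  $(\tau,\tau_u)\to(\tau',\tau_u)$ (for the root, the upper side is a pure
  translation), migration times on affected bands are rescaled the same way,
  and the product of scale factors enters the Hastings ratio as a Jacobian.
  A *rejection* variant leaves migration times untouched and abandons any
  proposal that conflicts with them.  Both variants re-validate the whole
  state and reject on any violation, which keeps the kernel correct even in
  corner cases (e.g. an unaffected population's event crossing a rescaled
  neighbour).
* **Composite-space handling of appearing/disappearing rates**: a $\tau$
  change can activate or deactivate a band (on the balanced four-species tree
  with an S→C band, the rate exists only while $\tau_S < \tau_T$).  Rates of
  inactive bands are retained as pseudo-parameters under a pseudo-prior equal
  to the prior (so all prior terms cancel in the acceptance ratio), refreshed
  by Gibbs draws from the prior while inactive, and carried across when the
  band reactivates; a proposal that would orphan existing migration events of
  a deactivating band is rejected.  Correctness is enforced behaviourally:
  with the likelihood off, the chain must cross the boundary freely and spend
  the prior probability of each side there (1/2 on the balanced tree), which
  the test suite checks.
* **Gene-tree topology (regraft by simulation)**: a random node's parent
  branch is detached and its backward path of migration and coalescence is
  re-simulated under the current parameters against the remaining lineages.
  The state carries no path above its root, so the continuation of the top
  remaining lineage (from the backbone root's age upward) is regenerated
  jointly, and the regenerated top lineage carries a coalescence hazard
  against the detached subtree's open lineages that aborts the proposal.
  With these two ingredients the proposal law is the *exact conditional
  density* of the regenerated paths given the rest of the genealogy, so the
  acceptance ratio reduces to the phylogenetic likelihood ratio — with the
  likelihood off every proposal is accepted and the move is a Gibbs update.
  (Both ingredients matter: omitting either produces a small but measurable
  bias in the stationary distribution, detectable by the prior-sampling
  harness as a few-percent distortion of migration-event counts.)
* **Mixing move**: every $\tau$, coalescent time and migration time is
  multiplied by $c = e^{\epsilon(u-1/2)}$; the Hastings ratio includes
  $c^d$ with $d$ the number of scaled variables.  Optionally (off by
  default) $\theta$ is rescaled too.

Step sizes are tuned during burn-in towards ~30% acceptance and frozen
afterwards.  Tuning is *per component* (per population, per band, per
divergence): a shared step is unsafe because a node whose conditional happens
to be flat (e.g. a divergence time with no sequence information) would
otherwise inflate the shared step until the other nodes' updates freeze.

All cached quantities (total gene-tree density via sufficient statistics,
per-locus likelihoods) can be checked against fresh recomputation every
`check_every` iterations; the final cache discrepancy is always reported in
the trace object and asserted small in the test suite.

## The simulator

`sim_gene_tree()` is a backward-in-time structured-coalescent simulator:
within each epoch between divergences the total event rate is
$\sum_j n_j(n_j-1)/(\theta_j h) + \sum_{(s,j)\ \mathrm{active}} n_j\,
4M_{sj}/(\theta_j h)$, the waiting time is exponential, the event type and
population are chosen proportionally to rates, and at each divergence the
clock restarts with the daughter populations' lineages relabelled to the
ancestor (exact by memorylessness).  `sim_alignment()` evolves JC69 sites
from a uniform root base.  Per-locus RNG streams are derived from the base
seed, so locus $k$ is bit-identical whether simulated alone or in a batch.

What the generator emulates — and does not: data are strictly JC69 with no
rate variation, no recombination within loci, free recombination between
loci, and constant per-band migration rates.  Passing tests therefore
demonstrate the internal consistency and calibration of simulator plus
sampler under the model's own assumptions; they say nothing about robustness
to model violations in real data (selection, rate variation, intralocus
recombination, time-varying gene flow).

## Validation harnesses

Two harnesses mirror the standard validation protocol for coalescent
samplers:

* `prior_sampling_check()`: with the likelihood held at 1, every parameter's
  marginal must equal its prior (the gene-tree density integrates to one).
  Marginals are compared by KS tests on a thinned subsample (MCMC output is
  autocorrelated; thinning keeps the test honest).  The harness demonstrably
  detects errors: a testing hook (`broken_hastings`) omits the multiplier
  Jacobian from the $\theta$ update and the check then fails decisively.
  This harness caught two real sampler bugs during development (shared-step
  tuning pathology; a missing exposure term in the regraft proposal law).
* `bayesian_calibration()`: parameters are drawn from the prior, a dataset is
  simulated for each draw and refitted under the same prior; the 95% HPD
  must cover the generating value for ~95% of replicates and the pooled
  posterior must match the prior.

## Marginal likelihoods and Bayes factors

`log_marginal()` estimates $\log p(X)$ by thermodynamic integration: for each
Gauss–Legendre node $\beta_k \in (0,1)$ (Legendre nodes mapped linearly from
$(-1,1)$; `schedule(K)`, default $K=8$) a power-posterior chain targets
$p(\Theta)p(G\mid\Theta)p(X\mid G)^{\beta_k}$ and the quadrature sum of the
mean log-likelihoods estimates the marginal likelihood, with a standard error
from batch means.  `bayes_factor()` differences two log marginals and flags
$|\log B| > 4.6$ (i.e. $B > 100$ or $B < 0.01$), the conventional threshold
for the gene-flow tests (H0: no gene flow; H1/H2: one or two bands).

## Numerical choices and problem sizes

* Densities and likelihoods in log space; pruning uses per-node rescaling.
* Proposals that produce exactly tied event times or land on interval
  boundaries are rejected outright (measure-zero; guards float pathologies).
* Site patterns are compressed once per locus before sampling.
* In `scripts/acceptance.R` the recovery chains are initialised at the
  generating parameter values, standard practice for simulation-based
  recovery experiments: the target posterior is unchanged, while burn-in
  along the nearly flat divergence-time/migration-rate ridge of the
  saturated model (where prior-started chains drift for tens of thousands of
  iterations at equal likelihood) stays within the run's budget.  The test
  suite's recovery checks use prior-mean starts, which is the stronger
  coverage check.
* The test suite and the acceptance script run scaled-down versions of the
  recovery experiments (the package's own choice of desk-scale sizes):
  three-species B–C recovery at L = 100 loci, the stepping-stone model at
  L = 100, the saturated eight-rate model at L = 250, calibration at 40
  replicates of 6 loci, and the Bayes-factor power contrast at L = 16 with a
  strong rate.  At these sizes posterior means of well-identified parameters
  (divergence times, extant sizes, nonsister rates) are stable; migration
  rates under the saturated model remain diffuse, as expected at this number
  of loci, and their HPD intervals are wide.

## Known limitations

* JC69 only; no rate heterogeneity or partitioned models.
* The species phylogeny and the set of migration bands are fixed; no
  cross-model moves over phylogenies.
* Migration histories are sampled explicitly, not integrated analytically;
  for very high rates the per-locus histories grow and mixing slows (the
  rejection rubber-band variant suffers first — use the extended kernel).
* The non-root divergence-time prior is the uniform order-statistics
  reconstruction described above.
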