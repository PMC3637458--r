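---
title: "Ranked gene tree probabilities under the multispecies coalescent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked gene tree probabilities under the multispecies coalescent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankedcoal)
```

## The model

Gene trees need not match the species tree that contains them: when two
lineages fail to coalesce in their most recent common ancestral population
(incomplete lineage sorting), deeper populations can join lineages in orders
that contradict the species relationships. The multispecies coalescent (MSC)
makes this precise: each branch of the species tree is a population of
constant size in which every pair of resident gene lineages coalesces
independently at rate 1 (time in coalescent units), and lineages from two
species can only coalesce above the species' divergence.

This package works with *ranked* tree topologies: leaf-labelled binary trees
whose internal nodes carry a total temporal order (rank 1 the most ancient
node, rank $n-1$ the most recent) but no continuous branch lengths. Ranked
topologies sit between unranked topologies and full genealogies: they keep
the order of coalescences -- information a clock-like gene tree estimate
provides -- while discarding the noisy continuous times. Their key
computational property is that, given the number of lineages entering a
species-tree interval, the ranking pins down *which* lineages they are (a
unique ancestral configuration), which is what makes a polynomial-time
dynamic program possible, whereas unranked topology probabilities are still
only computable by exponential-size enumerations of coalescent histories or
ancestral configurations.

### Notation

A species tree $T$ on $n$ species has divergence times
$s_1 > \dots > s_{n-1} > 0$ ($s_0 = \infty$; time 0 today, increasing into
the past), and interval $\tau_i = [s_i, s_{i-1})$ contains exactly $i$
species branches. Adding degree-one "bead" nodes at each $s_i$ gives one
*population* $y_{i,z}$ per branch crossing each interval (`bead()`). For a
ranked gene tree $G$ with nodes $u_1, \dots, u_{n-1}$ (by rank), $\ell_i$
denotes the number of gene lineages at $s_i$ and $g_i$ the minimum number
compatible with embedding $G$ in $T$ (`min_lineages()`); always
$n \ge \ell_i \ge g_i > i$.

### The dynamic program

`ranked_prob()` computes $P[G \mid T]$ in $O(n^5)$:

1. $g_i$ from the species lca of each gene node: a gene node can sit below
   $s_i$ only if the interval above its lca is more recent than $\tau_i$.
2. For each interval $\tau_i$ and each pair
   $(\ell_{i-1}, \ell_i)$, the per-population counts $k_{i,j,z}$ (the number
   of lineages in population $z$ just after the $j$-th coalescence of the
   interval, forward in time) follow from the $\ell_i$-lineage cut of $G$ by
   walking the interval's coalescences backward, decrementing the hosting
   population (`coalescence_schedule()`).
3. Total rates $\lambda_{i,j} = \sum_z \binom{k_{i,j,z}}{2}$, strictly
   increasing in $j$.
4. The probability that exactly these $m_i$ coalescences fit in the interval
   is hypoexponential:
   $$P[G_{i-1,\ell_{i-1}} \mid G_{i,\ell_i}, T]
     = \sum_{j=0}^{m_i}
       \frac{e^{-\lambda_{i,j}(s_{i-1}-s_i)}}
            {\prod_{k \ne j} (\lambda_{i,k}-\lambda_{i,j})}$$
   (`interval_probability()`).
5. A recursion over intervals, conditioning only on $\ell_i$, accumulates
   $P[G_{1,\ell_1} \mid T]$ for $\ell_1 = g_1, \dots, n$.
6. Above the root all orderings of the remaining coalescences are equally
   likely, so each $\ell_1$-term is divided by the number of labelled
   histories $H_{\ell_1} = \ell_1!(\ell_1-1)!/2^{\ell_1-1}$
   (`labeled_histories()`).

```{r}
st <- species_tree(read_ranked_newick("(((A,B)4,C)2,(D,E)3)1;"),
                   times = c(4, 3, 2, 1))
g_c <- read_ranked_newick("(((A,B)3,C)2,(D,E)4)1;")  # D,E coalesce first
min_lineages(g_c, st)$g
coalescence_schedule(g_c, st, i = 3, l_in = 5, l_out = 3)
ranked_prob(g_c, st)
```

## Numerical evaluation of the interval probability

The partial-fraction sum above is an alternating series whose terms are
$O(1)$ while the sum vanishes like $\Delta^{m}$ as the interval length
$\Delta \to 0$: direct evaluation loses all significant digits exactly where
likelihood optimisation needs it (short internal branches). The sum equals
$\Delta^{m}$ times the divided difference of $\exp$ over the nodes
$-\lambda_j \Delta$, and divided differences of $\exp$ are the first row of
the matrix exponential of a bidiagonal matrix. After shifting the nodes to
be nonnegative, every term of that Taylor recursion is nonnegative, so the
evaluation is cancellation-free; we use it whenever
$\Delta(\lambda_m - \lambda_0) \le 600$ (beyond which its terms could
overflow) and fall back to the direct formula in that widely separated
regime, where the leading term dominates and the direct sum is stable. The
unit tests pin both branches to 50-digit reference values at relative error
$10^{-9}$ or better, and to the closed form
$P = (1-e^{-\Delta})^2/2$ for rates $(0,1,2)$ at $10^{-12}$.

Rates are exact small integers by construction, so denominators in the
direct branch are products of exact integers. Repeated rates are impossible
for a valid schedule (each backward coalescence removes a lineage from a
population holding at least two, so rates strictly increase); the code
asserts this and treats a violation as an internal error rather than
implementing a repeated-rate hypoexponential. Coincident divergence times
are rejected when the species tree is built, so $\Delta = 0$ never reaches
the interval probability; $\Delta = \infty$ is supported only as the
documented limit (the hypoexponential CDF at infinity).

Probabilities are stored linearly -- at the tree sizes the exhaustive tools
target ($n \le 7$) they are comfortably within double range -- with log
values available via `ranked_prob(..., log = TRUE)`, which the likelihood
code uses throughout.

## Unranked topologies, MAC, and MDC

The probability of an unranked topology is the sum over its rankings (the
linear extensions of its ancestry order, `enumerate_rankings()`). A
caterpillar has one ranking; a balanced shape has super-polynomially many,
which is why `unranked_prob()` refuses (rather than truncates) beyond a cap,
by default $10^6$ rankings. Ranking counts use the interleaving-binomial
recursion, exact in double precision below $2^{53}$ -- far beyond anything
the enumeration cap allows through -- and correctly rounded above it.

Two parsimony scores complement the likelihood. The Minimize Ancient
Coalescence (MAC) cost $\sum_i (g_i - (i+1))$ counts, per interval row of
the beaded tree, lineages forced to persist beyond the first interval the
ranking would allow; it is zero exactly for a matching *ranked* topology and
so penalises rank discordance that the classical Minimize Deep Coalescence
(MDC) score cannot see (a gene tree can match the species tree's unranked
shape, have MDC 0, and still have MAC 1 because two cherries coalesce in the
wrong order). MDC is implemented in its standard maximal-subtree form purely
as the comparison baseline.

## Likelihood inference

For $N$ observed ranked gene trees with counts $n_i$ per distinct topology
(fractional counts, e.g. per-locus posterior weights, are accepted),
$\log L(T) = \sum_i n_i \log P[G^{(i)} \mid T]$. `mscml()` is the fitting
front end:

* With a fixed ranked species topology it estimates the $n-2$ internal
  interval lengths $d_i = s_{i-1} - s_i$. The likelihood is invariant to
  translating all times and to $s_{n-1}$ itself (with one gene copy per
  species nothing can coalesce below it), so we anchor $s_{n-1} = 1$ and
  optimise the log-gaps -- removing flat directions that stall optimisers.
  Optimisation is multi-start (3 starts by default; Brent line search for a
  single gap, Nelder--Mead polished by BFGS otherwise, tolerance $10^{-8}$),
  and the interval-rate schedules are precomputed once per gene tree
  topology, so each likelihood evaluation only re-runs the DP sums.
  Identifiability is not asserted: a non-converged optimiser warns and
  returns its best value.
* Without a topology it scores every ranked species topology exhaustively
  (guarded to $n \le 6$; there are $n!(n-1)!/2^{n-1}$ of them). Note the ML
  ranked topology need not be the most frequent observed gene tree.

```{r}
truth <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(2, 1))
fit <- mscml(simulate(truth, 400, seed = 11), topology = truth$tree)
fit
coef(fit)
```

For $n = 3$ the ML gap has the closed form $t = -\log(1.5(1-\hat p))$ when
the matching fraction $\hat p$ exceeds $1/3$; the tests require the
optimiser to agree to $10^{-5}$.

## The simulator

`simulate()` on a species tree is an exact MSC simulator and the package's
independent oracle: within each interval (most recent first) it draws the
waiting time to the next coalescence from the total rate
$\sum_z \binom{k_z}{2}$, picks the hosting population proportionally to its
pair count and the pair uniformly, and continues above the root until one
lineage remains. Pair-level simulation (rather than a per-population
Gillespie race) was chosen so each replicate yields a clean event trace
(interval, population, pair, time) from which every $\ell_i$, $m_i$ and
$k_{i,j,z}$ can be replayed -- the trace tests do exactly that. Each
replicate runs on its own RNG stream derived from the master seed and the
replicate index, so replicate $r$ is reproducible regardless of how many are
drawn.

`rspecies_tree()` draws study conditions: ranked Yule topologies (each
extant lineage equally likely to split) with $\mathrm{Exp}(k\cdot
\textrm{birth})$ stage waits, giving strictly distinct times almost surely.
Default birth rate 1 puts internal gaps near one coalescent unit -- the
regime where discordance is common but not saturated, which is what makes
the cross-validation informative.

What the simulator emulates -- and what it does not: one sampled gene copy
per species, a single constant population size, no migration, gene flow,
duplication or estimation error in the gene trees. Tests passing against it
show the DP and the MSC agree, not that real data meet those assumptions;
in particular per-branch population sizes and gene-tree estimation noise
are out of scope.

## Validation design and problem sizes

The checks the package ships (its test suite) were sized to be decisive yet
quick:

* worked five-taxon examples of every intermediate quantity
  ($g$, $k$, $\lambda$, MAC, MDC) asserted exactly;
* total probability $\sum_G P[G \mid T] = 1$ over all 18 ($n=4$) and 180
  ($n=5$) ranked topologies on five random species trees each, within
  $10^{-10}$;
* Monte-Carlo cross-validation at $N = 2 \times 10^5$ replicates for
  $n \in \{3,4,5\}$, every topology within four binomial standard errors;
* brute-force oracles (interval-assignment search for $g$; permutation
  filters for rankings; merge-sequence enumeration for labelled histories;
  nested quadrature and frozen 50-digit values for the interval
  probability);
* parameter recovery on simulated data ($n=4$, $N=2000$, gaps recovered to
  $\pm 0.15$) and ranked-topology recovery by the exhaustive search (ten
  seeded replicates at $N = 300$, at least nine recovering the truth);
* a scaling spot-check: one $n = 50$ ranked probability in well under ten
  seconds, consistent with the $O(n^5)$ design.

## Known limitations

Exhaustive enumeration (and hence `ml_species_tree()`) is deliberately
capped at small $n$; no heuristic search is provided. One gene copy per
species, constant population size, binary trees, and strictly distinct event
times are assumptions throughout -- ties in node ages are reported as
errors, never broken silently, because a tie has probability zero under the
model and silent tie-breaking would corrupt probabilities. Ranking counts
above $2^{53}$ are correctly rounded rather than exact. Estimating ranked
gene trees from sequence alignments is upstream of this package.
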