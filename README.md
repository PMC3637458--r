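# rankedcoal

Probabilities of **ranked gene tree topologies** under the multispecies
coalescent, in polynomial time — with the tools that grow out of that
computation: unranked gene tree probabilities by summation over rankings,
the Minimize Ancient Coalescence (MAC) and Minimize Deep Coalescence (MDC)
parsimony scores, maximum-likelihood inference of a ranked species tree
(with internal branch lengths) from collections of ranked gene trees, and an
exact coalescent simulator.

## Who this is for

Phylogeneticists studying gene tree / species tree discordance caused by
incomplete lineage sorting. Under the multispecies coalescent (MSC), each
species-tree branch is a constant-size population in which every pair of
resident gene lineages coalesces at rate 1 (time in coalescent units).
A *ranked* topology records the temporal order of a tree's internal nodes
(rank 1 = most ancient) but not its branch lengths — an intermediate between
unranked topologies, whose probabilities are only computable by
exponential-size enumerations, and full genealogies with noisy estimated
times. Conditioning on the ranking makes the ancestral configuration unique
given the number of surviving lineages, so `P[G | T]` is computable by
dynamic programming in `O(n^5)` for `n` species.

## The computation

For a species tree `T` with divergence times `s_1 > ... > s_{n-1}` and a
ranked gene tree `G`:

1. minimum lineage counts `g_i` at each `s_i` from the species lca of every
   gene node (`min_lineages()`);
2. per-interval, per-population lineage counts `k_{i,j,z}` and total
   coalescence rates `lambda_{i,j} = sum_z C(k_{i,j,z}, 2)`
   (`coalescence_schedule()`);
3. the probability that an interval of length `Delta` hosts its `m`
   prescribed coalescences,
   `sum_j exp(-lambda_j Delta) / prod_{k != j}(lambda_k - lambda_j)`
   — a hypoexponential CDF/density, evaluated cancellation-free via divided
   differences of `exp` (`interval_probability()`);
4. a recursion over intervals conditioning on the lineage count entering
   each speciation time, and a final division by the labelled-history count
   `H_l = l!(l-1)!/2^(l-1)` for the coalescences above the root
   (`ranked_prob()`).

Likelihood inference maximises the multinomial
`sum_i n_i log P[G^(i) | T]` over the internal interval lengths, and
exhaustively over ranked species topologies for small `n` (`mscml()`).

## Worked example

The five-taxon ranked species tree `(((A,B)4,C)2,(D,E)3)1` with times
`s = (4, 3, 2, 1)`, against the gene tree `(((A,B)3,C)2,(D,E)4)1` — same
unranked shape, but `D,E` coalesce more recently than `A,B` while the
species tree divergence order says the opposite:

```r
library(rankedcoal)
st <- species_tree(read_ranked_newick("(((A,B)4,C)2,(D,E)3)1;"),
                   times = c(4, 3, 2, 1))
g  <- read_ranked_newick("(((A,B)3,C)2,(D,E)4)1;")

min_lineages(g, st)$g
#> [1] 2 3 5 5
coalescence_schedule(g, st, i = 3, l_in = 5, l_out = 3)
#> Lineage schedule, interval tau_3 (5 -> 3 lineages, m = 2):
#>     AB C DE
#> j=0  1 1  1
#> j=1  2 1  1
#> j=2  2 1  2
#> lambda: 0 1 2
mac_cost(g, st$tree); mdc_cost(g, st$tree)
#> [1] 1
#> [1] 0
ranked_prob(g, st)
#> [1] 0.07596589
```

Reading: the gene tree needs `g_3 = 5` lineages at `s_3` (one more than a
matching ranking would), which is one "ancient coalescence" (MAC cost 1)
even though no classical deep coalescence occurs (MDC cost 0). In interval
`tau_3` the two coalescences happen in different populations (`AB` and
`DE`) with rates climbing `0, 1, 2`; the resulting interval probability is
`(1 - exp(-(s_2 - s_3)))^2 / 2`.

Simulation and inference round-trip:

```r
truth <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(2, 1))
fit <- mscml(simulate(truth, 400, seed = 11), topology = truth$tree)
coef(fit)
#>       d2
#> 1.064211
```

A command-line interface (`exec/rankedcoal`) exposes `prob-ranked`,
`prob-unranked`, `mac`, `mdc`, `simulate` and `mle` over Newick/TSV files.

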