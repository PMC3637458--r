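# Shared fixtures and independent oracles used across the test files.

# the worked-example trees: ranked species tree and the three gene trees
fig_species <- function() read_ranked_newick("(((A,B)4,C)2,(D,E)3)1;")
fig_species_timed <- function(times = c(4, 3, 2, 1))
  species_tree(fig_species(), times = times)
fig_gene_match <- function() read_ranked_newick("(((A,B)4,C)2,(D,E)3)1;")
fig_gene_b <- function() read_ranked_newick("((A,(B,C)3)2,(D,E)4)1;")  # deep coalescence
fig_gene_c <- function() read_ranked_newick("(((A,B)3,C)2,(D,E)4)1;")  # rank mismatch only

# Brute-force minimum lineage counts: enumerate every feasible assignment of
# gene nodes to intervals (node u_r may sit in tau_j only if
# j <= rank(lca(u_r)), assignments must respect the temporal order), and take
# the minimum lineage count at each s_i. Exponential; for tiny trees only.
brute_min_lineages <- function(G, T_) {
  Stree <- if (inherits(T_, "species_tree")) T_$tree else T_
  n <- G$n
  lca <- rankedcoal:::gene_lca_ranks(G, Stree)
  best <- rep(n, n - 1L)
  recurse <- function(r, assignment) {
    if (r > n - 1L) {
      for (i in seq_len(n - 1L)) {
        l_i <- n - sum(assignment > i)       # lineages at s_i
        best[i] <<- min(best[i], l_i)
      }
      return(invisible())
    }
    lo <- if (r == 1L) 1L else assignment[r - 1L]
    if (lca[r] >= lo)
      for (j in seq(lo, lca[r])) recurse(r + 1L, c(assignment, j))
  }
  recurse(1L, integer(0))
  best
}

# Independent linear-extension enumerator: filter all permutations of the
# internal nodes by the ancestry constraint (parent rank < child rank).
brute_rankings <- function(x) {
  t <- rankedcoal:::as_topology(x)
  n <- t$n
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  ok <- 0L
  for (p in perms(seq_len(n - 1L))) {        # p[pos] = node given rank pos
    rank_of <- integer(n - 1L); rank_of[p] <- seq_len(n - 1L)
    good <- TRUE
    for (v in seq_len(n - 1L))
      if (t$parent[v] > 0L && rank_of[t$parent[v]] >= rank_of[v]) good <- FALSE
    if (good) ok <- ok + 1L
  }
  ok
}

# Enumerate labelled histories of k lineages by brute force (sequences of
# pairwise merges); independent check of H_k.
brute_labeled_histories <- function(k) {
  count <- 0L
  recurse <- function(active) {
    if (length(active) == 1L) { count <<- count + 1L; return(invisible()) }
    m <- length(active)
    for (a in seq_len(m - 1L)) for (b in seq(a + 1L, m))
      recurse(c(active[-c(a, b)], max(active) + 1L))
  }
  recurse(seq_len(k))
  count
}

# Eq-style daughter-sum recursion for the bottom counts of an interval row:
# the number of lineages available in population z of row i equals the sum of
# the counts exiting its daughter populations of row i+1 (leaves contribute
# one sampled lineage each). Independent of the cut-based construction.
daughter_sum_bottom_counts <- function(G, T_, i, l_in, l_out_next) {
  st <- T_
  n <- st$n
  if (i == n - 1L) {
    # leaf row: one lineage per species
    bd <- bead(st)[[i]]
    return(lengths(bd$delta))
  }
  sched_below <- coalescence_schedule(G, st, i + 1L, l_in = l_in,
                                      l_out = l_out_next)
  exit_below <- sched_below$k[1L, ]          # k_{i+1,0,z}
  bd <- bead(st)
  vapply(seq_len(i), function(z) sum(exit_below[bd[[i]]$daughters[[z]]]),
         numeric(1))
}

# Nested-quadrature oracle for the interval probability: integrate
# exp(-sum_j lambda_j v_j) over v_j >= 0 with sum v_j = Delta (v_0 implicit).
quad_interval_prob <- function(lambda, delta) {
  m <- length(lambda) - 1L
  f <- function(v) exp(-sum(lambda * c(delta - sum(v), v)))
  if (m == 1L)
    return(stats::integrate(function(v1) vapply(v1, function(a) f(a), 1),
                            0, delta, rel.tol = 1e-12)$value)
  if (m == 2L)
    return(stats::integrate(function(v1) vapply(v1, function(a)
      stats::integrate(function(v2) vapply(v2, function(b) f(c(a, b)), 1),
                       0, delta - a, rel.tol = 1e-11)$value, 1),
      0, delta, rel.tol = 1e-10)$value)
  stop("quadrature oracle supports m <= 2")
}

# size-safe uniform draw from a vector (sample() treats scalars as 1:n)
pick <- function(v) v[sample.int(length(v), 1L)]

# random ranked gene tree drawn uniformly over all ranked topologies
random_ranked_topology <- function(labels) {
  all <- enumerate_ranked_topologies(labels)
  all[[sample.int(length(all), 1L)]]
}
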