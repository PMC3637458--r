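# Exact multispecies-coalescent simulation of ranked gene trees, used both as
# a data generator and as the Monte-Carlo oracle for the dynamic program.

#' Simulate ranked gene trees under the multispecies coalescent
#'
#' Draws gene trees on a species tree under the standard multispecies
#' coalescent with constant population size: one lineage is sampled per
#' species; within each interval (visited from the most recent, `tau_{n-1}`,
#' backwards) the waiting time to the next coalescence is exponential with
#' total rate `sum_z choose(k_z, 2)` over the populations crossing the
#' interval, the hosting population is drawn proportionally to its pair
#' count, and the coalescing pair uniformly within it; above the root,
#' coalescence continues until a single lineage remains. Each replicate uses
#' its own RNG stream derived from `seed` and the replicate index, so results
#' are reproducible and independent of `nsim`.
#'
#' @param object a `"species_tree"`.
#' @param nsim number of replicates.
#' @param seed integer master seed; `NULL` uses (and advances) the session
#'   RNG.
#' @param trace also record, per replicate, the event list (interval, host
#'   population as a species set, coalescing pair, time) as attribute
#'   `"trace"` -- enough to reconstruct `l_i`, `m_i` and every `k_{i,j,z}`.
#' @param ... unused.
#' @return a list of `"ranked_tree"` objects (length `nsim`).
#' @examples
#' st <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(2, 1))
#' simulate(st, nsim = 2, seed = 1)
#' @export
simulate.species_tree <- function(object, nsim = 1, seed = NULL, trace = FALSE,
                                  ...) {
  st <- object
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, nsim)
  tabs <- species_pop_tables(st$tree)
  lapply(seq_len(nsim), function(r) {
    set.seed(rep_seeds[r])
    sim_one_replicate(st, tabs, trace)
  })
}

sim_one_replicate <- function(st, tabs, trace = FALSE) {
  n <- st$n
  if (n == 2L) {
    tr <- new_ranked_tree(st$labels, list(c(-1L, -2L)))
    if (trace) attr(tr, "trace") <- data.frame(
      interval = 1L, population = paste(st$labels, collapse = ","),
      child1 = -1L, child2 = -2L, time = st$times[1L] + rexp(1L))
    return(tr)
  }
  # lineages per population of the current row; lineage ids: 1..n leaves,
  # n + j for the j-th merge (j = 1 most recent)
  merges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  ev_interval <- integer(0); ev_pop <- character(0); ev_time <- numeric(0)
  nmerge <- 0L
  pops <- lapply(tabs$row_codes[[n - 1L]], function(code) integer(0))
  leafpop <- tabs$anc[(n:(2L * n - 1L)), n - 1L]
  for (l in seq_len(n)) pops[[leafpop[l]]] <- c(pops[[leafpop[l]]], l)
  for (i in seq(n - 1L, 1L)) {
    dur <- if (i == 1L) Inf else st$times[i - 1L] - st$times[i]
    t0 <- 0
    repeat {
      k <- lengths(pops)
      rates <- k * (k - 1) / 2
      lam <- sum(rates)
      if (lam == 0) break
      t0 <- t0 + rexp(1L, lam)
      if (t0 >= dur) break
      z <- sample.int(length(pops), 1L, prob = rates)
      idx <- if (k[z] == 2L) 1:2 else sample.int(k[z], 2L)
      pair <- pops[[z]][idx]
      nmerge <- nmerge + 1L
      merges[nmerge, ] <- pair
      pops[[z]] <- c(pops[[z]][-idx], n + nmerge)
      if (trace) {
        ev_interval <- c(ev_interval, i)
        codes <- tabs$row_codes[[i]]
        cd <- codes[z]
        dset <- if (cd >= n) st$labels[cd - (n - 1L)] else
          st$labels[st$tree$clade[[cd]]]
        ev_pop <- c(ev_pop, paste(dset, collapse = ","))
        ev_time <- c(ev_time, (if (i == 1L) st$times[1L] else st$times[i]) + t0)
      }
      if (i == 1L && length(pops[[1L]]) == 1L) break
    }
    if (i > 1L) {
      # pour populations of row i into their containing row i-1 populations
      codes_up <- tabs$row_codes[[i - 1L]]
      newpops <- lapply(codes_up, function(code) integer(0))
      codes <- tabs$row_codes[[i]]
      for (z in seq_along(pops)) {
        zz <- tabs$anc[codes[z], i - 1L]
        newpops[[zz]] <- c(newpops[[zz]], pops[[z]])
      }
      pops <- newpops
    }
  }
  # merge j (1 = most recent) has rank n - j
  children <- vector("list", n - 1L)
  for (j in seq_len(n - 1L)) {
    kids <- merges[j, ]
    code <- -kids
    internal <- kids > n
    code[internal] <- 2L * n - kids[internal]
    children[[n - j]] <- code
  }
  tr <- new_ranked_tree(st$labels, children)
  if (trace)
    attr(tr, "trace") <- data.frame(
      interval = ev_interval, population = ev_pop,
      child1 = merges[seq_along(ev_interval), 1L],
      child2 = merges[seq_along(ev_interval), 2L], time = ev_time)
  tr
}

#' Simulated frequency table of ranked gene tree topologies
#'
#' Simulates `N` ranked gene trees on `T` and tabulates the canonical ranked
#' Newick strings, with binomial standard errors. Used to cross-validate the
#' dynamic program: each topology's frequency should sit within a few
#' standard errors of [ranked_prob()].
#'
#' @param T_ a `"species_tree"`.
#' @param N number of replicates, `>= 1`.
#' @param seed integer master seed.
#' @return a data frame with columns `topology`, `count`, `freq`, `se`,
#'   sorted by decreasing count; `sum(count) == N`.
#' @examples
#' st <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(2, 1))
#' sim_topology_freqs(st, 200, seed = 1)
#' @export
sim_topology_freqs <- function(T_, N, seed = NULL) {
  stopifnot(N >= 1)
  trees <- simulate(T_, nsim = N, seed = seed)
  key <- vapply(trees, write_ranked_newick, character(1))
  tab <- sort(table(key), decreasing = TRUE)
  freq <- as.numeric(tab) / N
  data.frame(topology = names(tab), count = as.integer(tab), freq = freq,
             se = sqrt(freq * (1 - freq) / N), row.names = NULL)
}

#' Random ranked species tree (Yule process)
#'
#' Draws a ranked species topology from the Yule process (each extant
#' lineage is equally likely to speciate next) with exponential
#' inter-speciation gaps: the wait between the k-species and (k+1)-species
#' stages is `Exp(k * birth)`, and the most recent divergence sits
#' `Exp(n * birth)` before the present, giving strictly decreasing, strictly
#' positive divergence times almost surely.
#'
#' @param n number of species, `>= 2`.
#' @param birth speciation rate per lineage (coalescent-unit time scale).
#' @param seed integer seed; `NULL` uses the session RNG.
#' @param labels leaf labels; defaults to `A, B, C, ...` (then `t1, t2, ...`
#'   beyond 26).
#' @return a `"species_tree"`.
#' @examples
#' rspecies_tree(5, birth = 1, seed = 42)
#' @export
rspecies_tree <- function(n, birth = 1, seed = NULL,
                          labels = if (n <= 26) LETTERS[seq_len(n)] else
                            sprintf("t%02d", seq_len(n))) {
  stopifnot(n >= 2, birth > 0)
  if (!is.null(seed)) set.seed(seed)
  # grow the ranked topology: slots are unfilled child positions
  children <- vector("list", n - 1L)
  slot_parent <- integer(0)   # parent rank of each open slot (0 = root slot)
  slot_parent <- 0L
  for (r in seq_len(n - 1L)) {
    s <- if (length(slot_parent) == 1L) 1L else
      sample.int(length(slot_parent), 1L)
    p <- slot_parent[s]
    if (p > 0L) children[[p]] <- c(children[[p]], r)
    slot_parent <- c(slot_parent[-s], r, r)
  }
  labs <- sample(labels, n)   # exchangeable labelling
  for (l in seq_len(n)) {
    p <- slot_parent[l]
    children[[p]] <- c(children[[p]], -match(labs[l], sort(labels)))
  }
  tree <- new_ranked_tree(sort(labels), children)
  validate_ranked_tree(tree)
  gaps <- rexp(n - 1L, rate = seq_len(n - 1L) * birth)  # k-species stage waits
  tip <- rexp(1L, rate = n * birth)
  times <- tip + rev(cumsum(rev(gaps[-1L])))            # s_1 .. s_{n-2}
  times <- c(times, tip)                                # s_{n-1}
  species_tree(tree, times = times)
}
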