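# Core algorithm: embedding profile g_i, per-interval lineage schedules
# k_{i,j,z} with total rates lambda_{i,j}, the hypoexponential interval
# probability, and the dynamic program over intervals.

# species lca rank for each gene node: the species node with largest rank
# whose clade contains delta(u_r)
gene_lca_ranks <- function(G, Stree) {
  n <- G$n
  perm <- match(G$labels, Stree$labels)
  par <- sp_parents(Stree)
  vapply(seq_len(n - 1L), function(r) {
    cl <- perm[G$clade[[r]]]                 # leaf indices on the species side
    a <- Stree$n - 1L + cl[1L]               # start at one leaf, climb
    repeat {
      a <- par[a]
      if (all(cl %in% Stree$clade[[a]])) return(a)
    }
  }, integer(1))
}

#' Minimum lineage counts for embedding a ranked gene tree
#'
#' Computes `g_i`, the minimum number of gene tree lineages present at
#' speciation time `s_i` such that the ranked gene tree `G` can be embedded
#' into the species tree `T`, together with the species lca rank of every
#' gene tree node. `g_i = n` minus the number of most-recent gene nodes that
#' can all occur more recently than `s_i` (a gene node `u` fits below `s_i`
#' exactly when the interval above its species lca is more recent than
#' `tau_i`). When `G` and `T` share the same ranked topology, `g_i = i + 1`.
#'
#' @param G a `"ranked_tree"` (the gene tree).
#' @param T_ a `"species_tree"` or `"ranked_tree"` (only the ranked topology
#'   is used).
#' @return an object of class `"lineage_profile"`: list with `g` (integer,
#'   length n-1, indexed by interval) and `lca_rank` (integer, length n-1,
#'   indexed by gene node rank).
#' @examples
#' T_ <- read_ranked_newick("(((A,B)4,C)2,(D,E)3)1;")
#' G  <- read_ranked_newick("(((A,B)3,C)2,(D,E)4)1;")
#' min_lineages(G, T_)$g     # 2 3 5 5
#' @export
min_lineages <- function(G, T_) {
  Stree <- if (inherits(T_, "species_tree")) T_$tree else T_
  stopifnot(inherits(G, "ranked_tree"), inherits(Stree, "ranked_tree"))
  if (!identical(G$labels, Stree$labels))
    stop("gene tree and species tree must share the same leaf set",
         call. = FALSE)
  n <- G$n
  lca <- gene_lca_ranks(G, Stree)
  g <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    if (i == n - 1L) { g[i] <- n; next }
    below <- lca[(i + 1L):(n - 1L)] > i      # u_k may sit below s_i
    g[i] <- n - as.integer(sum(rev(cumprod(rev(below)))))
  }
  structure(list(g = g, lca_rank = lca), class = "lineage_profile")
}

#' @export
print.lineage_profile <- function(x, ...) {
  cat("Embedding profile:\n  g:", x$g, "\n  lca ranks:", x$lca_rank, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Structural preparation shared by every evaluation of P[G|T] on the same
# pair of topologies: lineage-to-population maps, per-cut population counts,
# and all lambda schedules. None of this depends on the divergence times, so
# likelihood optimisation over times reuses one prep.

rgt_prep <- function(G, T_) {
  Stree <- if (inherits(T_, "species_tree")) T_$tree else T_
  prof <- min_lineages(G, Stree)
  n <- G$n
  g <- prof$g
  if (n == 2L)
    return(list(n = 2L, g = g, profile = prof))
  tabs <- species_pop_tables(Stree)
  perm <- match(G$labels, Stree$labels)

  # population of each gene lineage per row: lineage rooted at gene node u_r
  # maps through its species lca; a leaf lineage through its species leaf
  lca <- prof$lca_rank
  gpop <- tabs$anc[lca, , drop = FALSE]                    # (n-1) x (n-1)
  lpop <- tabs$anc[Stree$n - 1L + perm, , drop = FALSE]    # n x (n-1)

  # counts[[i]][l - g_i + 1, z]: lineages of the l-lineage cut of G in
  # population z of row i (the cut applies the coalescences of rank >= l)
  counts <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    k <- tabulate(lpop[, i], nbins = i)
    mat <- matrix(0L, nrow = n - g[i] + 1L, ncol = i)
    mat[n - g[i] + 1L, ] <- k
    if (n - 1L >= g[i]) for (l in seq(n - 1L, g[i])) {
      p <- gpop[l, i]
      if (p == 0L || k[p] < 2L)
        stop("internal consistency failure: cut at ", l,
             " lineages is not embeddable in row ", i, call. = FALSE)
      k[p] <- k[p] - 1L
      mat[l - g[i] + 1L, ] <- k
    }
    counts[[i]] <- mat
  }

  # lambda schedules for every DP transition (interval iv, exiting l_out at
  # s_{iv-1}, entering l_in at s_iv); exact small integers
  lambda <- vector("list", n - 1L)
  for (iv in seq(2L, n - 1L)) {
    sched <- vector("list", (n + 1L) * (n + 1L))
    for (l_in in seq(g[iv], n)) {
      kbot <- counts[[iv]][l_in - g[iv] + 1L, ]
      lam_top <- sum(kbot * (kbot - 1L)) / 2
      for (l_out in seq(g[iv - 1L], min(l_in, n))) {
        m <- l_in - l_out
        lam <- numeric(m + 1L)
        lam[m + 1L] <- lam_top
        if (m > 0L) {
          k <- kbot
          for (j in seq(m - 1L, 0L)) {
            r <- l_out + j                    # (j+1)th coalescence forward
            p <- gpop[r, iv]
            lam[j + 1L] <- lam[j + 2L] - (k[p] - 1L)
            k[p] <- k[p] - 1L
          }
        }
        if (any(diff(lam) <= 0))
          stop("internal consistency failure: rates not strictly increasing",
               call. = FALSE)
        sched[[l_out * (n + 1L) + l_in]] <- lam
      }
    }
    lambda[[iv]] <- sched
  }
  list(n = n, g = g, profile = prof, counts = counts, lambda = lambda,
       gpop = gpop, lpop = lpop, tabs = tabs)
}

# DP evaluation given divergence times; returns list(prob, table)
rgt_eval <- function(prep, times) {
  n <- prep$n
  if (n == 2L)
    return(list(prob = 1, table = matrix(1, 1L, 1L,
      dimnames = list("i=1", "l=2"))))
  g <- prep$g
  delta <- c(NA, times[seq_len(n - 2L)] - times[seq(2L, n - 1L)])
  P <- matrix(0, nrow = n - 1L, ncol = n)    # P[i, l]
  P[n - 1L, n] <- 1
  for (i in seq(n - 2L, 1L)) {
    iv <- i + 1L
    sched <- prep$lambda[[iv]]
    for (l_i in seq(g[i], n)) {
      acc <- 0
      for (l_nx in seq(max(l_i, g[iv]), n)) {
        lam <- sched[[l_i * (n + 1L) + l_nx]]
        acc <- acc + interval_probability(lam, delta[iv]) * P[iv, l_nx]
      }
      P[i, l_i] <- acc
    }
  }
  l1 <- seq(g[1L], n)
  prob <- sum(P[1L, l1] / vapply(l1, labeled_histories, numeric(1)))
  dimnames(P) <- list(paste0("i=", seq_len(n - 1L)), paste0("l=", seq_len(n)))
  list(prob = prob, table = P)
}

#' Per-interval lineage schedule and coalescence rates
#'
#' For one DP transition -- interval `tau_i` with `l_in` lineages entering at
#' `s_i` and `l_out` exiting at `s_{i-1}` (so `m = l_in - l_out` coalescences,
#' the gene nodes of rank `l_out .. l_in - 1`) -- computes the per-population
#' lineage counts `k[j, z]` just after the j-th coalescence (forward in time;
#' row `j = 0` is the exiting configuration) and the total rates
#' `lambda_j = sum_z choose(k[j, z], 2)`.
#'
#' @param G,T_ ranked gene tree and species tree (topologies share a leaf set).
#' @param i interval index, `2 <= i <= n-1`.
#' @param l_in,l_out lineage counts entering (at `s_i`) and exiting (at
#'   `s_{i-1}`) the interval; must satisfy `g_i <= l_in <= n` and
#'   `g_{i-1} <= l_out <= l_in`.
#' @return a list of class `"lineage_schedule"` with `k` (an `(m+1) x i`
#'   integer matrix, rows labelled `j=0..m`), `lambda` (length `m+1`, strictly
#'   increasing), `m`, `i`, and `populations` (the species sets of row i).
#' @examples
#' T_ <- species_tree(read_ranked_newick("(((A,B)4,C)2,(D,E)3)1;"),
#'                    times = c(4, 3, 2, 1))
#' G  <- read_ranked_newick("((A,(B,C)3)2,(D,E)4)1;")
#' coalescence_schedule(G, T_, i = 2, l_in = 4, l_out = 2)$k
#' @export
coalescence_schedule <- function(G, T_, i, l_in, l_out) {
  prep <- rgt_prep(G, T_)
  n <- prep$n
  if (n == 2L) stop("no interior intervals for n = 2", call. = FALSE)
  if (i < 2L || i > n - 1L) stop("interval index i must be in 2..n-1",
                                 call. = FALSE)
  g <- prep$g
  if (l_in < g[i] || l_in > n)
    stop("l_in must be in g_i..n = ", g[i], "..", n, call. = FALSE)
  if (l_out < g[i - 1L] || l_out > l_in)
    stop("l_out must be in g_{i-1}..l_in = ", g[i - 1L], "..", l_in,
         call. = FALSE)
  m <- l_in - l_out
  k <- matrix(0L, nrow = m + 1L, ncol = i,
              dimnames = list(paste0("j=", 0:m), NULL))
  k[m + 1L, ] <- prep$counts[[i]][l_in - g[i] + 1L, ]
  if (m > 0L) for (j in seq(m - 1L, 0L)) {
    r <- l_out + j
    p <- prep$gpop[r, i]
    k[j + 1L, ] <- k[j + 2L, ]
    k[j + 1L, p] <- k[j + 1L, p] - 1L
  }
  lam <- rowSums(choose(k, 2))
  if (any(diff(lam) <= 0))
    stop("internal consistency failure: rates not strictly increasing",
         call. = FALSE)
  Stree <- if (inherits(T_, "species_tree")) T_$tree else T_
  codes <- prep$tabs$row_codes[[i]]
  pops <- lapply(codes, function(cd)
    Stree$labels[if (cd >= n) cd - (n - 1L) else Stree$clade[[cd]]])
  structure(list(i = i, m = m, l_in = l_in, l_out = l_out, k = k,
                 lambda = lam, populations = pops),
            class = "lineage_schedule")
}

#' @export
print.lineage_schedule <- function(x, ...) {
  cat("Lineage schedule, interval tau_", x$i, " (", x$l_in, " -> ", x$l_out,
      " lineages, m = ", x$m, "):\n", sep = "")
  cn <- vapply(x$populations, function(d) paste(d, collapse = ""), character(1))
  k <- x$k; colnames(k) <- cn
  print(k)
  cat("lambda:", x$lambda, "\n")
  invisible(x)
}

#' Number of labelled histories (coalescence orders) of k lineages
#'
#' `H_k = k! (k-1)! / 2^(k-1)` counts the sequences of pairwise coalescences
#' of k lineages; each is equally likely under the coalescent, so `1/H_k` is
#' the probability that the coalescences above the species-tree root occur in
#' the order required by the ranked gene tree. Evaluated as
#' `prod(choose(2:k, 2))`, which is exact in double precision far beyond any
#' practical k.
#'
#' @param k integer `>= 1`.
#' @return `H_k` (numeric).
#' @examples
#' labeled_histories(4)   # 18
#' @export
labeled_histories <- function(k) {
  stopifnot(length(k) == 1L, is.finite(k), k == round(k))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k == 1L) return(1)
  prod(choose(2:k, 2))
}

# ---------------------------------------------------------------------------
# Hypoexponential interval probability (distinct rates).

#' Probability of an interval's coalescence events
#'
#' Evaluates the probability that exactly `m` prescribed coalescences happen
#' within an interval of length `delta`, when the total coalescence rate
#' immediately before (backwards in time) the j-th event is `lambda[j]`
#' (strictly increasing, `j = 0..m`):
#' `sum_j exp(-lambda_j * delta) / prod_{k != j} (lambda_k - lambda_j)`.
#' This is the hypoexponential (sum of independent exponentials with distinct
#' rates) cumulative distribution when `lambda[1] == 0` and its density
#' integral otherwise.
#'
#' Direct evaluation of the alternating sum loses all precision as
#' `delta -> 0`, so the sum is computed as `delta^m` times the divided
#' difference of `exp` over the nodes `-lambda * delta`, via the Taylor
#' recursion on the bidiagonal divided-difference matrix after shifting the
#' nodes to be nonnegative -- every term is then nonnegative and no
#' cancellation occurs. The direct formula is used only in the widely
#' separated regime where it is stable.
#'
#' @param lambda numeric vector of strictly increasing rates,
#'   `lambda_0 < ... < lambda_m`.
#' @param delta interval length, `> 0`; `Inf` is allowed and returns the
#'   limit (`1 / prod(lambda[-1])` when `lambda_0 = 0`, else 0).
#' @return a probability in `[0, 1]`. For `m = 0` this is
#'   `exp(-lambda_0 * delta)`.
#' @examples
#' interval_probability(c(0, 1, 2), 1.3)     # (1 - exp(-1.3))^2 / 2
#' @export
interval_probability <- function(lambda, delta) {
  lambda <- as.numeric(lambda)
  m <- length(lambda) - 1L
  if (m < 0L) stop("lambda must be nonempty", call. = FALSE)
  if (anyDuplicated(lambda) || any(diff(lambda) <= 0))
    stop("rates must be strictly increasing (repeated rates cannot arise ",
         "from a valid lineage schedule)", call. = FALSE)
  if (length(delta) != 1L || is.na(delta) || delta <= 0)
    stop("delta must be a single positive interval length", call. = FALSE)
  if (!is.finite(delta)) {
    if (m == 0L) return(if (lambda == 0) 1 else 0)
    return(if (lambda[1L] == 0) 1 / prod(lambda[-1L]) else 0)
  }
  if (m == 0L) return(exp(-lambda * delta))
  x <- delta * (lambda[m + 1L] - lambda[1L])
  if (x <= 600) {
    # P = delta^m * e^{-lambda_m delta} * dd(exp; u), u_j = delta*(l_m - l_j)
    u <- delta * (lambda[m + 1L] - lambda)
    dd <- exp_divided_diff_nonneg(u)
    out <- exp(m * log(delta) - lambda[m + 1L] * delta + log(dd))
  } else {
    # widely separated rates: partial-fraction formula is stable
    terms <- vapply(seq_len(m + 1L), function(jj) {
      d <- lambda[-jj] - lambda[jj]
      exp(-lambda[jj] * delta) / prod(d)
    }, numeric(1))
    out <- max(sum(terms), 0)
  }
  min(out, 1)
}

# Divided difference of exp over nonnegative nodes u (any order), computed as
# the (1, m+1) entry of expm of the bidiagonal matrix diag(u) + superdiag(1)
# by direct Taylor summation of the first row. All quantities are
# nonnegative, so the summation is cancellation-free; terms decay once the
# Taylor index passes max(u).
exp_divided_diff_nonneg <- function(u) {
  m <- length(u) - 1L
  if (m == 0L) return(exp(u))
  v <- c(1, numeric(m))
  acc <- v
  umax <- max(u)
  k <- 1
  repeat {
    v <- (v * u + c(0, v[-(m + 1L)])) / k
    acc <- acc + v
    if (k > umax + 10 && v[m + 1L] <= acc[m + 1L] * 1e-18) break
    if (k > umax + 4000) break
    k <- k + 1
  }
  acc[m + 1L]
}

# ---------------------------------------------------------------------------

#' Probability of a ranked gene tree given a species tree
#'
#' Computes `P[G | T]` under the multispecies coalescent with constant
#' population size (times in coalescent units), in `O(n^5)` time: minimum
#' lineage counts `g_i`, per-interval rate schedules, hypoexponential
#' interval probabilities, a dynamic program over intervals conditioning only
#' on the number of lineages entering each speciation time, and a final
#' summation over the number of lineages reaching the root, each weighted by
#' the probability `1/H_l` that the coalescences above the root occur in the
#' required order.
#'
#' @param G a `"ranked_tree"` gene tree (or rank-annotated Newick string).
#' @param T_ a `"species_tree"`.
#' @param log return the log probability.
#' @param detail also return the DP table `P[G_{i,l} | T]`.
#' @return the probability (or log probability); with `detail = TRUE`, a list
#'   with elements `prob`, `log_prob`, `table`, `profile`.
#' @examples
#' st <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(2, 1))
#' ranked_prob(read_ranked_newick("((A,B)2,C)1;"), st)   # 1 - (2/3) e^{-1}
#' @export
ranked_prob <- function(G, T_, log = FALSE, detail = FALSE) {
  if (is.character(G)) G <- read_ranked_newick(G)
  stopifnot(inherits(G, "ranked_tree"), inherits(T_, "species_tree"))
  prep <- rgt_prep(G, T_)
  res <- rgt_eval(prep, T_$times)
  if (detail)
    return(list(prob = res$prob, log_prob = log(res$prob), table = res$table,
                profile = prep$profile))
  if (log) log(res$prob) else res$prob
}

#' Probability of an unranked gene tree topology
#'
#' Sums [ranked_prob()] over every ranking of the unranked topology (all
#' linear extensions of its ancestry order). Shapes whose ranking count
#' exceeds `max_rankings` are refused outright rather than truncated, since a
#' partial sum is not a probability.
#'
#' @param G unranked gene tree: Newick string, `"phylo"`, `"tree_topology"`,
#'   or a `"ranked_tree"` whose ranks are ignored.
#' @param T_ a `"species_tree"`.
#' @param max_rankings cap on the number of rankings summed.
#' @return the probability, with attribute `"n_rankings"` giving the number
#'   of rankings summed.
#' @examples
#' st <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(2, 1))
#' unranked_prob("((A,C),B);", st)   # (1/3) e^{-1}
#' @export
unranked_prob <- function(G, T_, max_rankings = 1e6) {
  stopifnot(inherits(T_, "species_tree"))
  rankings <- enumerate_rankings(G, max_rankings = max_rankings)
  p <- sum(vapply(rankings, ranked_prob, numeric(1), T_ = T_))
  structure(p, n_rankings = length(rankings))
}
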