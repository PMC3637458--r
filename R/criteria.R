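# Parsimony criteria: Minimize Ancient Coalescence (MAC, rank-aware) and
# Minimize Deep Coalescence (MDC, topology-only baseline).

#' Minimize Ancient Coalescence (MAC) cost
#'
#' Counts the minimum number of "ancient" coalescences a ranked gene tree
#' forces on a ranked species tree: `sum_i (g_i - (i + 1))`, the total number
#' of extra lineages across the beaded species tree's interval rows beyond
#' the `i + 1` that a perfectly matching ranked topology would need. The cost
#' is 0 exactly when `G` and `T` share the same ranked topology; it uses only
#' the ranked topology of `T`, never its times.
#'
#' @param G a `"ranked_tree"` (or rank-annotated Newick string).
#' @param T_ a `"ranked_tree"` or `"species_tree"` (times ignored).
#' @return a nonnegative integer.
#' @examples
#' T_ <- read_ranked_newick("(((A,B)4,C)2,(D,E)3)1;")
#' mac_cost(read_ranked_newick("(((A,B)3,C)2,(D,E)4)1;"), T_)   # 1
#' mac_cost(read_ranked_newick("((A,(B,C)3)2,(D,E)4)1;"), T_)   # 2
#' @export
mac_cost <- function(G, T_) {
  if (is.character(G)) G <- read_ranked_newick(G)
  prof <- min_lineages(G, T_)
  n <- G$n
  sum(prof$g - (seq_len(n - 1L) + 1L))
}

#' Minimize Deep Coalescence (MDC) cost
#'
#' The classical topology-only deep-coalescence score, implemented as the
#' comparison baseline for MAC: for every internal edge of the (unranked)
#' species tree, the minimal number of gene lineages exiting the clade below
#' it is the number of maximal subtrees of `G` whose leaves all lie within
#' that clade; each lineage beyond the first is an extra (deep-coalescing)
#' lineage.
#'
#' @param G,T_ unranked topologies (Newick, `"phylo"`, `"tree_topology"`, or
#'   ranked objects whose ranks are ignored).
#' @return a nonnegative integer; 0 when the unranked topologies match.
#' @examples
#' mdc_cost("((A,(B,C)),(D,E));", "(((A,B),C),(D,E));")   # 1
#' mdc_cost("(((A,B),C),(D,E));", "(((A,B),C),(D,E));")   # 0
#' @export
mdc_cost <- function(G, T_) {
  G <- as_topology(G)
  S <- as_topology(T_)
  if (!identical(G$labels, S$labels))
    stop("gene tree and species tree must share the same leaf set",
         call. = FALSE)
  n <- G$n
  total <- 0L
  if (n < 3L) return(total)
  for (v in seq(2L, n - 1L)) {               # internal edges: non-root nodes
    C <- S$clade[[v]]
    inside <- c(vapply(seq_len(n - 1L), function(u) all(G$clade[[u]] %in% C),
                       logical(1)),
                seq_len(n) %in% C)           # gene nodes 1..n-1, then leaves
    maximal <- 0L
    for (u in seq_len(n - 1L))               # maximal internal subtrees
      if (inside[u] && (u == 1L || !inside[G$parent[u]])) maximal <- maximal + 1L
    for (l in seq_len(n))                    # maximal single-leaf subtrees
      if (l %in% C && !inside[G$leaf_parent[l]]) maximal <- maximal + 1L
    total <- total + (maximal - 1L)
  }
  total
}

#' Rank candidate species trees by total MAC cost
#'
#' Scores each candidate ranked species topology by the weighted sum of MAC
#' costs over a collection of observed ranked gene trees (weights default to
#' 1 per tree; fractional weights, e.g. posterior probabilities per locus,
#' are allowed). Candidates are returned sorted by score; ties are reported,
#' not broken.
#'
#' @param observed list of `"ranked_tree"` (or Newick strings), or a
#'   `"ranked_sample"`.
#' @param candidates list of candidate ranked species topologies; by default
#'   all ranked topologies on the leaf set (guarded to `n <= 7`).
#' @param weights nonnegative weights, one per observed tree (ignored when
#'   `observed` is a `"ranked_sample"`, which carries its own counts).
#' @return a data frame with columns `topology` (canonical ranked Newick),
#'   `score`, and `tied` (TRUE for rows sharing the minimum score), sorted by
#'   score.
#' @examples
#' T_ <- "(((A,B)4,C)2,(D,E)3)1;"
#' G  <- "(((A,B)3,C)2,(D,E)4)1;"
#' head(mac_rank_species_trees(list(G), candidates = list(T_, G)))
#' @export
mac_rank_species_trees <- function(observed, candidates = NULL, weights = NULL) {
  if (inherits(observed, "ranked_sample")) {
    weights <- observed$counts
    observed <- observed$trees
  }
  if (!length(observed)) stop("no observed gene trees", call. = FALSE)
  observed <- lapply(observed, function(g)
    if (is.character(g)) read_ranked_newick(g) else g)
  if (is.null(weights)) weights <- rep(1, length(observed))
  if (length(weights) != length(observed) || any(weights < 0))
    stop("weights must be nonnegative, one per observed tree", call. = FALSE)
  if (is.null(candidates))
    candidates <- enumerate_ranked_topologies(observed[[1L]]$labels)
  if (!length(candidates)) stop("no candidate species trees", call. = FALSE)
  candidates <- lapply(candidates, function(t)
    if (is.character(t)) read_ranked_newick(t) else
      if (inherits(t, "species_tree")) t$tree else t)
  score <- vapply(candidates, function(cand)
    sum(weights * vapply(observed, mac_cost, numeric(1), T_ = cand)),
    numeric(1))
  ord <- order(score)
  out <- data.frame(
    topology = vapply(candidates, write_ranked_newick, character(1))[ord],
    score = score[ord])
  out$tied <- out$score == out$score[1L]
  out
}
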