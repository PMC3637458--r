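# Counting and enumerating rankings (linear extensions of the ancestry order)
# and enumerating all ranked topologies on a label set.

#' Number of rankings of an unranked tree topology
#'
#' A binary topology on n leaves has `(n-1)! / prod(c_i - 1)` rankings, where
#' `c_i` is the number of descendant leaves of internal node i. A caterpillar
#' has a single ranking; balanced shapes have super-polynomially many.
#'
#' Computed by the interleaving recursion
#' `R(v) = choose(iL + iR, iL) * R(left) * R(right)` (with `iL`, `iR` the
#' internal node counts of the child subtrees), which keeps every intermediate
#' value integral. Values are exact up to 2^53; beyond that they are correctly
#' rounded doubles.
#'
#' @param x an unranked topology: Newick string, `"phylo"`, `"ranked_tree"`
#'   (ranks ignored) or `"tree_topology"`.
#' @return the number of rankings (numeric).
#' @examples
#' count_rankings("(((A,B),C),D);")        # caterpillar: 1
#' count_rankings("((A,B),(C,D));")        # balanced 4-leaf: 2
#' @export
count_rankings <- function(x) {
  t <- as_topology(x)
  rec <- function(code) {
    if (code < 0L) return(c(count = 1, internals = 0))
    kids <- t$children[[code]]
    a <- rec(kids[1L]); b <- rec(kids[2L])
    c(count = choose(a[["internals"]] + b[["internals"]], a[["internals"]]) *
        a[["count"]] * b[["count"]],
      internals = a[["internals"]] + b[["internals"]] + 1)
  }
  unname(rec(1L)[["count"]])
}

#' Enumerate the rankings of an unranked tree topology
#'
#' Generates every linear extension of the ancestry partial order on the
#' internal nodes, each returned as a `"ranked_tree"`. The number of results
#' equals [count_rankings()]; the enumeration refuses to run when that count
#' exceeds `max_rankings` (balanced shapes grow super-polynomially).
#'
#' @inheritParams count_rankings
#' @param max_rankings refuse when the ranking count exceeds this cap.
#' @return a list of `"ranked_tree"` objects.
#' @examples
#' enumerate_rankings("((A,B),(C,D));")
#' @export
enumerate_rankings <- function(x, max_rankings = 1e6) {
  t <- as_topology(x)
  cnt <- count_rankings(t)
  if (cnt > max_rankings)
    stop("topology has ", format(cnt, big.mark = ","),
         " rankings, exceeding the cap of ", format(max_rankings, big.mark = ","),
         call. = FALSE)
  n <- t$n
  out <- vector("list", cnt)
  pos <- 0L
  rank_of <- integer(n - 1L)
  # available = internal nodes whose parent is already ranked
  step <- function(available, nextrank) {
    if (!length(available)) {
      pos <<- pos + 1L
      children <- lapply(t$children, function(kids)
        ifelse(kids < 0L, kids, rank_of[pmax(kids, 1L)]))
      out[[pos]] <<- new_ranked_tree(t$labels, `[<-`(vector("list", n - 1L),
        rank_of, children))
      return(invisible())
    }
    for (v in available) {
      rank_of[v] <<- nextrank
      kids <- t$children[[v]]
      step(c(setdiff(available, v), kids[kids > 0L]), nextrank + 1L)
    }
  }
  step(1L, 1L)
  out
}

#' Enumerate all ranked topologies on a label set
#'
#' Generates every distinct leaf-labelled ranked binary topology on the given
#' labels. There are `n! (n-1)! / 2^(n-1)` of them (the number of labelled
#' histories of n lineages), so the enumeration is guarded to `n <= 7`.
#'
#' @param labels character vector of distinct leaf labels, `2 <= n <= 7`.
#' @return a list of `"ranked_tree"` objects.
#' @examples
#' length(enumerate_ranked_topologies(c("A", "B", "C")))   # 3
#' length(enumerate_ranked_topologies(LETTERS[1:4]))       # 18
#' @export
enumerate_ranked_topologies <- function(labels) {
  labels <- sort(as.character(labels))
  n <- length(labels)
  if (anyDuplicated(labels)) stop("labels must be distinct", call. = FALSE)
  if (n < 2L || n > 7L)
    stop("enumeration is guarded to 2 <= n <= 7 leaves (got ", n, ")",
         call. = FALSE)
  out <- list()
  children <- vector("list", n - 1L)
  # merge sequences: the k-th merge (k = 1 first) is the k-th most recent
  # coalescence, so it gets rank n - k; temp id k stands for that node
  recurse <- function(active, k) {
    if (length(active) == 1L) {
      ch <- lapply(seq_len(n - 1L), function(r) children[[n - r]])
      out[[length(out) + 1L]] <<- new_ranked_tree(labels, ch)
      return(invisible())
    }
    m <- length(active)
    for (a in seq_len(m - 1L)) for (b in seq((a + 1L), m)) {
      kids <- c(active[a], active[b])
      children[[k]] <<- vapply(kids, function(v)
        if (v <= n) -v else n - (v - n), integer(1))
      recurse(c(active[-c(a, b)], n + k), k + 1L)
    }
  }
  recurse(seq_len(n), 1L)
  out
}
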