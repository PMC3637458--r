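# Ranked tree topologies.
#
# Internal representation ("ranked_tree"):
#   labels   character, sorted; leaf i is labels[i]
#   n        number of leaves
#   children list of length n-1, indexed by rank r = 1..n-1; each element is an
#            integer vector of length 2 in canonical order, where a positive
#            entry is the rank of an internal child and a negative entry -i is
#            leaf i
#   clade    list of length n-1; clade[[r]] = sorted leaf indices below u_r
#   parent   integer of length n-1; parent[r] = rank of the parent of u_r
#            (0 for the root, which always has rank 1)
#   leaf_parent integer of length n; rank of the parent of each leaf
#
# Rank 1 is the most ancient internal node (the root), rank n-1 the most
# recent; every internal node's rank is strictly smaller than the ranks of its
# internal children.

new_ranked_tree <- function(labels, children) {
  n <- length(labels)
  clade <- vector("list", n - 1L)
  parent <- integer(n - 1L)
  leaf_parent <- integer(n)
  # ranks increase from root to tips, so fill clades bottom-up
  for (r in seq(n - 1L, 1L)) {
    kids <- children[[r]]
    cl <- integer(0)
    for (k in kids) {
      if (k < 0L) {
        cl <- c(cl, -k)
        leaf_parent[-k] <- r
      } else {
        cl <- c(cl, clade[[k]])
        parent[k] <- r
      }
    }
    clade[[r]] <- sort(cl)
  }
  # canonical child order: by smallest descendant label (labels are sorted,
  # so smallest leaf index == lexicographically smallest label)
  minleaf <- function(k) if (k < 0L) -k else min(clade[[k]])
  for (r in seq_len(n - 1L)) {
    kids <- children[[r]]
    if (minleaf(kids[1L]) > minleaf(kids[2L])) children[[r]] <- kids[c(2L, 1L)]
  }
  structure(
    list(labels = labels, n = n, children = children, clade = clade,
         parent = parent, leaf_parent = leaf_parent),
    class = "ranked_tree")
}

validate_ranked_tree <- function(x) {
  n <- x$n
  if (n < 2L) stop("a ranked tree needs at least 2 leaves", call. = FALSE)
  if (anyDuplicated(x$labels))
    stop("duplicate leaf labels: ",
         paste(unique(x$labels[duplicated(x$labels)]), collapse = ", "),
         call. = FALSE)
  if (length(x$children) != n - 1L)
    stop("tree is not binary: expected ", n - 1L, " internal nodes",
         call. = FALSE)
  for (r in seq_len(n - 1L)) {
    kids <- x$children[[r]]
    if (length(kids) != 2L)
      stop("non-binary node of rank ", r, call. = FALSE)
    bad <- kids[kids > 0L & kids <= r]
    if (length(bad))
      stop("rank order violates ancestry: node of rank ", r,
           " has internal child of rank ", bad[1L], call. = FALSE)
  }
  if (length(x$clade[[1L]]) != n)
    stop("root (rank 1) is not ancestral to all leaves", call. = FALSE)
  invisible(x)
}

#' Parse a rank-annotated Newick string
#'
#' Reads a ranked tree topology from Newick in which every internal node is
#' labelled with its rank, e.g. `"(((A,B)4,C)2,(D,E)3)1;"`. Rank 1 is the most
#' ancient node (the root), rank n-1 the most recent; the ranks must form a
#' permutation of 1..n-1 consistent with ancestry (a parent is always more
#' ancient than its children). Branch lengths, if present, are ignored. The
#' terminating semicolon is optional.
#'
#' @param text a single Newick string.
#' @return an object of class `"ranked_tree"`.
#' @examples
#' g <- read_ranked_newick("(((A,B)4,C)2,(D,E)3)1;")
#' g
#' @seealso [write_ranked_newick()], [ranks_from_ultrametric()]
#' @export
read_ranked_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || is.null(phy$tip.label))
    stop("malformed Newick string: ", text, call. = FALSE)
  ranked_from_phylo(phy)
}

# phylo (with integer node labels as ranks) -> ranked_tree
ranked_from_phylo <- function(phy) {
  n <- length(phy$tip.label)
  if (n < 2L) stop("a ranked tree needs at least 2 leaves", call. = FALSE)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (phy$Nnode != n - 1L)
    stop("tree is not binary: ", n, " leaves but ", phy$Nnode,
         " internal nodes", call. = FALSE)
  deg <- tabulate(phy$edge[, 1L], nbins = n + phy$Nnode)
  if (any(deg[(n + 1L):(n + phy$Nnode)] != 2L))
    stop("tree is not binary: node with outdegree != 2", call. = FALSE)
  labs <- phy$node.label
  if (is.null(labs) || any(is.na(labs)) || any(labs == ""))
    stop("every internal node must carry an integer rank label", call. = FALSE)
  ranks <- suppressWarnings(as.integer(labs))
  if (any(is.na(ranks)) || any(as.character(ranks) != sub("^\\+", "", labs)))
    stop("internal node labels must be integer ranks, got: ",
         paste(labs, collapse = ", "), call. = FALSE)
  if (!setequal(ranks, seq_len(n - 1L)) || anyDuplicated(ranks))
    stop("ranks must be a permutation of 1..", n - 1L, ", got: ",
         paste(sort(ranks), collapse = ", "), call. = FALSE)

  labels <- sort(phy$tip.label)
  leaf_of_tip <- match(phy$tip.label, labels)
  rank_of_node <- ranks                      # indexed by node - n
  children <- vector("list", n - 1L)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
    r <- rank_of_node[a - n]
    code <- if (b <= n) -leaf_of_tip[b] else rank_of_node[b - n]
    children[[r]] <- c(children[[r]], code)
  }
  root <- phy$edge[1L, 1L]   # cladewise order: first edge starts at the root
  if (rank_of_node[root - n] != 1L)
    stop("the root must have rank 1, got rank ", rank_of_node[root - n],
         call. = FALSE)
  tr <- new_ranked_tree(labels, children)
  validate_ranked_tree(tr)
  tr
}

quote_label <- function(x) {
  bad <- grepl("[][(),:;'\" \t]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Write a ranked tree as Newick
#'
#' Produces the canonical rank-annotated Newick string for a ranked topology:
#' children are ordered by their smallest descendant leaf label, so two equal
#' ranked topologies always serialise to the same string, and
#' `read_ranked_newick(write_ranked_newick(t))` reproduces `t` exactly.
#'
#' @param x a `"ranked_tree"`.
#' @return a single Newick string with integer internal labels and a
#'   terminating semicolon.
#' @examples
#' write_ranked_newick(read_ranked_newick("((D,E)3,((B,A)4,C)2)1"))
#' @export
write_ranked_newick <- function(x) {
  stopifnot(inherits(x, "ranked_tree"))
  labs <- quote_label(x$labels)
  rec <- function(code) {
    if (code < 0L) return(labs[-code])
    kids <- x$children[[code]]
    paste0("(", rec(kids[1L]), ",", rec(kids[2L]), ")", code)
  }
  paste0(rec(1L), ";")
}

#' @export
print.ranked_tree <- function(x, ...) {
  cat("Ranked tree topology (", x$n, " leaves):\n  ",
      write_ranked_newick(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.ranked_tree <- function(x, ...) write_ranked_newick(x)

# equality of ranked topologies via canonical form
same_ranked_topology <- function(a, b) {
  identical(write_ranked_newick(a), write_ranked_newick(b))
}

# ultrametric phylo -> node ages (named by ape node number), checking the
# clock within relative tolerance
node_ages_ultrametric <- function(phy, tol = 1e-6) {
  if (is.null(phy$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  h <- max(depth[seq_len(n)])
  if (h <= 0) stop("tree has zero height", call. = FALSE)
  if (any(abs(depth[seq_len(n)] - h) > tol * h))
    stop("tree is not ultrametric: root-to-leaf path lengths differ by more ",
         "than relative tolerance ", tol, call. = FALSE)
  ages <- h - depth[(n + 1L):(n + phy$Nnode)]
  names(ages) <- as.character((n + 1L):(n + phy$Nnode))
  ages
}

#' Derive ranks from an ultrametric tree
#'
#' Converts an ultrametric tree (Newick with branch lengths, or an ape
#' `"phylo"`) into a ranked topology by ordering internal nodes by decreasing
#' age: the oldest node (the root) gets rank 1. Two internal nodes with equal
#' age are an error rather than being broken arbitrarily -- under the
#' coalescent, simultaneous event times have probability zero, and a silent
#' tie-break would corrupt downstream probabilities.
#'
#' @param x ultrametric Newick string or `"phylo"` object.
#' @param tol relative tolerance for the ultrametricity check, and below which
#'   two node ages count as tied (relative to tree height).
#' @return a `"ranked_tree"`.
#' @examples
#' ranks_from_ultrametric("((A:1,B:1):2,C:3);")
#' @export
ranks_from_ultrametric <- function(x, tol = 1e-6) {
  phy <- as_phylo_input(x)
  ages <- node_ages_ultrametric(phy, tol = tol)
  h <- max(ages)
  if (any(abs(diff(sort(ages))) <= 1e-9 * h))
    stop("two internal nodes have equal age; ranked topologies require ",
         "strictly distinct event times", call. = FALSE)
  phy$node.label <- as.character(rank(-ages, ties.method = "first"))
  ranked_from_phylo(phy)
}

as_phylo_input <- function(x) {
  if (inherits(x, "phylo")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (!grepl(";\\s*$", x)) x <- paste0(x, ";")
  phy <- tryCatch(ape::read.tree(text = x),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || is.null(phy$tip.label))
    stop("malformed Newick string: ", x, call. = FALSE)
  phy
}

# ---------------------------------------------------------------------------
# Unranked topologies ("tree_topology"): same layout as ranked_tree but nodes
# are indexed in preorder (node 1 = root) and carry no temporal meaning.

as_topology <- function(x) {
  if (inherits(x, "tree_topology")) return(x)
  if (inherits(x, "species_tree")) x <- x$tree
  if (inherits(x, "ranked_tree")) {
    # ranks are already a valid preorder-compatible indexing (parent < child)
    out <- unclass(x)
    class(out) <- "tree_topology"
    return(out)
  }
  phy <- as_phylo_input(x)
  n <- length(phy$tip.label)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels", call. = FALSE)
  if (phy$Nnode != n - 1L)
    stop("tree is not binary", call. = FALSE)
  labels <- sort(phy$tip.label)
  leaf_of_tip <- match(phy$tip.label, labels)
  # index internal nodes so that parents precede children (ape's cladewise
  # edge order visits parents first)
  idx <- integer(phy$Nnode)
  nxt <- 1L
  root <- phy$edge[1L, 1L]
  idx[root - n] <- nxt
  children <- vector("list", n - 1L)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1L]; b <- phy$edge[e, 2L]
    if (b > n) { nxt <- nxt + 1L; idx[b - n] <- nxt }
    code <- if (b <= n) -leaf_of_tip[b] else NA_integer_
    children[[idx[a - n]]] <- c(children[[idx[a - n]]], if (is.na(code)) idx[b - n] else code)
  }
  tr <- new_ranked_tree(labels, children)
  out <- unclass(tr)
  class(out) <- "tree_topology"
  out
}

# drop ranks: ranked_tree -> canonical unranked newick (no internal labels)
unranked_newick <- function(x) {
  x <- as_topology(x)
  labs <- quote_label(x$labels)
  rec <- function(code) {
    if (code < 0L) return(labs[-code])
    kids <- x$children[[code]]
    a <- rec(kids[1L]); b <- rec(kids[2L])
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    paste0("(", a, ",", b, ")")
  }
  paste0(rec(1L), ";")
}

#' @export
print.tree_topology <- function(x, ...) {
  cat("Unranked tree topology (", x$n, " leaves):\n  ",
      unranked_newick(x), "\n", sep = "")
  invisible(x)
}
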