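# Species tree with divergence times and the beaded population grid.
#
# A "species_tree" holds a ranked topology plus strictly decreasing
# divergence times s_1 > ... > s_{n-1} > 0 in coalescent units (time 0 today,
# increasing into the past; s_0 = +Inf). Interval tau_i = [s_i, s_{i-1}).
#
# Species nodes are coded as integers: rank r for internal nodes, n-1+l for
# leaf l (codes 1..2n-1), so parent/ancestor arrays can be plain vectors.


# parent code for every species node code (0 for the root)
sp_parents <- function(tree) {
  n <- tree$n
  par <- integer(2L * n - 1L)
  par[seq_len(n - 1L)] <- tree$parent
  par[(n:(2L * n - 1L))] <- tree$leaf_parent
  par
}

#' Build a species tree with divergence times
#'
#' Constructs a `"species_tree"` either from an ultrametric Newick string /
#' `"phylo"` (branch lengths in coalescent units; internal node ages become
#' the divergence times, ranks follow decreasing age) or from a ranked
#' topology plus an explicit vector of times.
#'
#' @param x ultrametric Newick / `"phylo"`, or a `"ranked_tree"`.
#' @param times when `x` is a `"ranked_tree"`: numeric vector of divergence
#'   times `s_1 > ... > s_{n-1} > 0`, indexed by rank.
#' @param tol relative tolerance for the ultrametricity / tie checks.
#' @return an object of class `"species_tree"` with elements `tree`
#'   (`"ranked_tree"`), `times`, `n`, `labels`.
#' @examples
#' st <- species_tree("(((A:1,B:1):1.3,C:2.3):1.7,(D:1.7,E:1.7):2.3):0;")
#' st
#' @export
species_tree <- function(x, times = NULL, tol = 1e-6) {
  if (inherits(x, "species_tree")) return(x)
  if (inherits(x, "ranked_tree")) {
    if (is.null(times))
      stop("supply divergence times when building from a ranked topology",
           call. = FALSE)
    tree <- x
  } else {
    phy <- as_phylo_input(x)
    tree <- ranks_from_ultrametric(phy, tol = tol)
    ages <- node_ages_ultrametric(phy, tol = tol)
    times <- sort(unname(ages), decreasing = TRUE)
  }
  times <- as.numeric(times)
  n <- tree$n
  if (length(times) != n - 1L)
    stop("need ", n - 1L, " divergence times, got ", length(times),
         call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("divergence times must be finite and positive", call. = FALSE)
  if (any(diff(times) >= 0))
    stop("divergence times must be strictly decreasing with rank ",
         "(s_1 > ... > s_{n-1})", call. = FALSE)
  structure(list(tree = tree, times = times, n = n, labels = tree$labels),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, digits = 4, ...) {
  cat("Species tree (", x$n, " species), coalescent units:\n  ",
      write_ranked_newick(x$tree), "\n", sep = "")
  cat("  divergence times s_1..s_", x$n - 1L, ": ",
      paste(signif(x$times, digits), collapse = " > "), "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Beaded tree: one population per branch crossing each interval.
#
# Row i (interval tau_i) has exactly i populations: the species nodes y with
# parent older than s_{i-1} that already exist at s_i (internal rank >= i, or
# leaves). Exactly one population per row has outdegree 2: the node of rank i
# itself, which splits at the bottom of the row.

#' Beaded population grid of a species tree
#'
#' Inserts degree-one "bead" nodes at every divergence time so that interval
#' row i has exactly one population per species-tree branch crossing it
#' (i populations in row i, `n(n-1)/2` beads in total). Each population is
#' identified by its set of descendant species; within each row exactly one
#' population has two daughters (the branch that splits at the bottom of the
#' row), all others continue as themselves.
#'
#' @param x a `"species_tree"` (or anything [species_tree()] accepts with
#'   `times`).
#' @return an object of class `"beaded_tree"`: a list with one element per
#'   row `i = 1..n-1`, each containing `codes` (species node codes), `delta`
#'   (list of species-label sets), `split` (index z of the outdegree-2
#'   population), and `daughters` (list mapping each z to the indices of its
#'   daughter populations in row i+1; `NULL` list for the last row, whose
#'   daughters are the sampled leaves).
#' @examples
#' st <- species_tree("(((A:1,B:1):1.3,C:2.3):1.7,(D:1.7,E:1.7):2.3):0;")
#' bead(st)
#' @export
bead <- function(x) {
  st <- x
  stopifnot(inherits(st, "species_tree"))
  tree <- st$tree
  n <- st$n
  rows <- vector("list", n - 1L)
  par <- sp_parents(tree)
  code_clade <- function(code)
    if (code >= n) code - (n - 1L) else tree$clade[[code]]
  for (i in seq_len(n - 1L)) {
    codes <- integer(0)
    for (code in seq_len(2L * n - 1L)) {
      is_internal <- code <= n - 1L
      exists_at_si <- !is_internal || code >= i
      par_rank <- if (par[code] == 0L) 0L else par[code]
      if (exists_at_si && par_rank < i) codes <- c(codes, code)
    }
    minleaf <- vapply(codes, function(cd) min(code_clade(cd)), integer(1))
    codes <- codes[order(minleaf)]
    delta <- lapply(codes, function(cd) tree$labels[code_clade(cd)])
    rows[[i]] <- list(codes = codes, delta = delta,
                      split = match(i, codes), daughters = NULL)
  }
  for (i in seq_len(n - 2L)) {
    nxt <- rows[[i + 1L]]$codes
    rows[[i]]$daughters <- lapply(rows[[i]]$codes, function(cd) {
      if (cd == i) match(which(par == i) , nxt)
      else match(cd, nxt)
    })
  }
  structure(rows, class = "beaded_tree", n = n)
}

#' @export
print.beaded_tree <- function(x, ...) {
  cat("Beaded species tree, ", attr(x, "n"), " species:\n", sep = "")
  for (i in seq_along(x)) {
    sets <- vapply(x[[i]]$delta, function(d) paste0("{", paste(d, collapse = ","), "}"),
                   character(1))
    cat("  row ", i, ": ", paste(sets, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

#' Population containing a species set in an interval row
#'
#' Finds the population z of beaded row i whose species set contains `d`, or
#' reports that `d` spans multiple populations of that row (returned as
#' `NA_integer_`, not an error: a spanning set is a legitimate outcome used to
#' detect infeasible lineage placements).
#'
#' @param x a `"species_tree"`.
#' @param i interval row index, 1..n-1.
#' @param d character vector of species labels (nonempty subset of the leaves).
#' @return the population index z within row i, or `NA_integer_` when `d`
#'   spans multiple populations.
#' @examples
#' st <- species_tree("(((A:1,B:1):1.3,C:2.3):1.7,(D:1.7,E:1.7):2.3):0;")
#' population_of(st, 3, c("D", "E"))   # the DE population
#' population_of(st, 3, c("C", "D"))   # NA: spans two populations
#' @export
population_of <- function(x, i, d) {
  stopifnot(inherits(x, "species_tree"))
  if (!length(d) || !all(d %in% x$labels))
    stop("d must be a nonempty subset of the species labels", call. = FALSE)
  if (i < 1L || i > x$n - 1L) stop("row index i must be in 1..n-1", call. = FALSE)
  row <- bead(x)[[i]]
  hit <- which(vapply(row$delta, function(s) all(d %in% s), logical(1)))
  if (length(hit) == 1L) hit else NA_integer_
}

# ---------------------------------------------------------------------------
# Fast row/population lookup tables used by the DP and the simulator.
#
# pop_of_node[code, i]: index z of the row-i population whose species set
# contains delta(code) entirely, or 0 when it spans several populations.
species_pop_tables <- function(tree) {
  n <- tree$n
  par <- sp_parents(tree)
  # row membership: rowz[code, i] = z when species node `code` crosses row i
  rowz <- matrix(0L, nrow = 2L * n - 1L, ncol = n - 1L)
  rowsize <- integer(n - 1L)
  row_codes <- vector("list", n - 1L)
  clmin <- c(vapply(seq_len(n - 1L), function(r) min(tree$clade[[r]]), integer(1)),
             seq_len(n))
  for (i in seq_len(n - 1L)) {
    codes <- which(c(seq_len(n - 1L) >= i, rep(TRUE, n)) & par < i)
    codes <- codes[order(clmin[codes])]
    row_codes[[i]] <- codes
    rowz[codes, i] <- seq_along(codes)
  }
  # crossing ancestor: anc[code, i] = z of the row-i population whose branch
  # contains delta(code); 0 when `code` is an internal node more recent than
  # the row (its clade then spans several populations of the row)
  anc <- matrix(0L, nrow = 2L * n - 1L, ncol = n - 1L)
  for (code in seq_len(2L * n - 1L)) {
    for (i in seq_len(n - 1L)) {
      if (code <= n - 1L && code < i) next      # spans: stays 0
      a <- code
      while (par[a] >= i) a <- par[a]
      anc[code, i] <- rowz[a, i]
    }
  }
  list(row_codes = row_codes, rowz = rowz, anc = anc, par = par)
}
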