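# Maximum-likelihood inference of a ranked species tree (with internal
# branch lengths) from a collection of ranked gene tree topologies: the
# multinomial likelihood prod_i P[G^(i) | T]^{n_i}.

#' Collection of observed ranked gene trees
#'
#' Bundles observed ranked gene tree topologies with observation counts.
#' Duplicate topologies (under canonical form) are merged by summing their
#' counts; counts may be fractional, e.g. per-locus posterior weights.
#'
#' @param x a list of `"ranked_tree"` objects and/or rank-annotated Newick
#'   strings (a character vector also works), or an existing
#'   `"ranked_sample"`.
#' @param counts nonnegative numeric, one per tree (default 1 each).
#' @return an object of class `"ranked_sample"`: list with `trees` (distinct
#'   `"ranked_tree"`s), `counts`, `N = sum(counts)`, `labels`.
#' @examples
#' ranked_sample(c("((A,B)2,C)1;", "((A,B)2,C)1;", "((A,C)2,B)1;"))
#' @export
ranked_sample <- function(x, counts = NULL) {
  if (inherits(x, "ranked_sample")) return(x)
  if (inherits(x, "ranked_tree")) x <- list(x)
  if (is.character(x)) x <- as.list(x)
  if (!length(x)) stop("empty gene tree collection", call. = FALSE)
  trees <- lapply(x, function(g) if (is.character(g)) read_ranked_newick(g) else g)
  if (is.null(counts)) counts <- rep(1, length(trees))
  if (length(counts) != length(trees) || any(counts < 0) || !all(is.finite(counts)))
    stop("counts must be finite and nonnegative, one per tree", call. = FALSE)
  labels <- trees[[1L]]$labels
  ok <- vapply(trees, function(t) identical(t$labels, labels), logical(1))
  if (!all(ok)) stop("all gene trees must share the same leaf set", call. = FALSE)
  key <- vapply(trees, write_ranked_newick, character(1))
  agg <- tapply(counts, key, sum)
  keep <- match(names(agg), key)
  structure(list(trees = trees[keep], counts = as.numeric(agg),
                 N = sum(counts), labels = labels),
            class = "ranked_sample")
}

#' @export
print.ranked_sample <- function(x, ...) {
  cat("Ranked gene tree sample: N = ", format(x$N), ", ",
      length(x$trees), " distinct topologies, ", length(x$labels),
      " taxa\n", sep = "")
  invisible(x)
}

#' Read a ranked gene tree sample from a file
#'
#' One rank-annotated Newick per line, with an optional tab-separated weight
#' column (defaults to 1). Blank lines and `#` comments are skipped.
#'
#' @param file path.
#' @return a `"ranked_sample"`.
#' @export
read_ranked_sample <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no gene trees in ", file, call. = FALSE)
  parts <- strsplit(lines, "\t")
  trees <- vapply(parts, `[[`, character(1), 1L)
  w <- vapply(parts, function(p) if (length(p) > 1L) as.numeric(p[[2L]]) else 1,
              numeric(1))
  ranked_sample(as.list(trees), counts = w)
}

#' Log-likelihood of a species tree for a ranked gene tree sample
#'
#' `sum_i n_i log P[G^(i) | T]`: the log of the multinomial likelihood of
#' the observed ranked topologies (the multinomial coefficient, constant in
#' `T`, is omitted).
#'
#' @param sample a `"ranked_sample"` (or anything [ranked_sample()] accepts).
#' @param T_ a `"species_tree"`.
#' @return the log-likelihood (numeric scalar).
#' @export
ranked_loglik <- function(sample, T_) {
  sample <- ranked_sample(sample)
  stopifnot(inherits(T_, "species_tree"))
  if (!identical(sample$labels, T_$labels))
    stop("sample and species tree must share the same leaf set", call. = FALSE)
  lp <- vapply(sample$trees, ranked_prob, numeric(1), T_ = T_, log = TRUE)
  sum(sample$counts * lp)
}

# times from internal gaps d_i = s_{i-1} - s_i (i = 2..n-1), anchored at
# s_{n-1} = anchor; the likelihood is invariant to the anchor and to shifting
# all times, so only the n-2 gaps are free parameters
times_from_gaps <- function(gaps, anchor = 1) {
  anchor + c(rev(cumsum(rev(gaps))), 0)
}

#' Fit divergence times for a fixed ranked species topology
#'
#' Maximises the ranked gene tree log-likelihood over the `n - 2` internal
#' interval lengths `d_i = s_{i-1} - s_i` (log-parametrised, multi-start
#' quasi-Newton; Brent line search when there is a single gap). The most
#' recent divergence is anchored at `s_{n-1} = anchor`: with one gene copy
#' sampled per species no coalescence can predate it, so the likelihood does
#' not depend on it.
#'
#' @param sample a `"ranked_sample"` (or anything [ranked_sample()] accepts).
#' @param topology candidate ranked species topology (`"ranked_tree"`,
#'   Newick, or `"species_tree"` whose times are ignored).
#' @param starts number of optimisation starts.
#' @param seed integer seed for the start points.
#' @param anchor value of `s_{n-1}`.
#' @param reltol convergence tolerance passed to the optimiser.
#' @return a list: `tree` (fitted `"species_tree"`), `gaps`, `logLik`,
#'   `convergence` (0 = converged; with a warning and the best value found
#'   otherwise).
#' @examples
#' st <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(2, 1))
#' g <- simulate(st, 200, seed = 7)
#' fit_times(ranked_sample(g), st$tree)$gaps   # close to 1
#' @export
fit_times <- function(sample, topology, starts = 3, seed = 1, anchor = 1,
                      reltol = 1e-8) {
  sample <- ranked_sample(sample)
  if (sample$N <= 0) stop("sample has zero total weight", call. = FALSE)
  tree <- if (is.character(topology)) read_ranked_newick(topology) else
    if (inherits(topology, "species_tree")) topology$tree else topology
  stopifnot(inherits(tree, "ranked_tree"))
  if (!identical(sample$labels, tree$labels))
    stop("sample and species topology must share the same leaf set",
         call. = FALSE)
  n <- tree$n
  if (n < 3L)
    stop("the likelihood is flat for n = 2 (P = 1 for the single ranked ",
         "topology); nothing to fit", call. = FALSE)
  preps <- lapply(sample$trees, rgt_prep, T_ = tree)
  negll <- function(loggaps) {
    gaps <- pmin(pmax(exp(loggaps), 1e-10), 1e10)   # keep the DP in range
    times <- times_from_gaps(gaps, anchor)
    lp <- vapply(preps, function(pr) log(rgt_eval(pr, times)$prob), numeric(1))
    v <- -sum(sample$counts * lp)
    if (!is.finite(v)) 1e10 else v
  }
  npar <- n - 2L
  set.seed(seed)
  inits <- matrix(log(0.75), nrow = starts, ncol = npar)
  if (starts > 1L)
    inits[-1L, ] <- matrix(rnorm((starts - 1L) * npar, mean = 0, sd = 1.2),
                           nrow = starts - 1L)
  best <- NULL
  for (s in seq_len(starts)) {
    fit <- if (npar == 1L) {
      o <- optimize(negll, interval = c(-18, 12), tol = reltol)
      list(par = o$minimum, value = o$objective, convergence = 0L)
    } else {
      o <- optim(inits[s, ], negll, method = "Nelder-Mead",
                 control = list(reltol = reltol, maxit = 2000))
      o2 <- optim(o$par, negll, method = "BFGS",
                  control = list(reltol = reltol, maxit = 200))
      if (o2$value <= o$value) o2 else o
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.null(best$convergence) && best$convergence != 0L)
    warning("optimiser did not report convergence; returning best value found")
  gaps <- pmin(pmax(exp(best$par), 1e-10), 1e10)
  names(gaps) <- paste0("d", seq(2L, n - 1L))
  list(tree = species_tree(tree, times = times_from_gaps(gaps, anchor)),
       gaps = gaps, logLik = -best$value,
       convergence = if (is.null(best$convergence)) 0L else best$convergence)
}

#' Exhaustive maximum-likelihood ranked species tree
#'
#' Fits divergence times for every ranked species topology on the leaf set
#' (exhaustive enumeration, guarded to `n <= 6`) and returns the
#' maximum-likelihood candidate with the full score table. Note the ML ranked
#' topology can differ from the most frequent observed ranked gene tree.
#'
#' @inheritParams fit_times
#' @param n_max refuse leaf sets larger than this (hard cap 6).
#' @return a list: `tree` (the ML `"species_tree"`), `logLik`, `gaps`, and
#'   `score_table` (data frame of all candidates sorted by log-likelihood).
#' @export
ml_species_tree <- function(sample, n_max = 6, starts = 3, seed = 1,
                            anchor = 1, reltol = 1e-8) {
  sample <- ranked_sample(sample)
  n <- length(sample$labels)
  if (n > min(n_max, 6))
    stop("exhaustive search is guarded to n <= ", min(n_max, 6),
         " species (got ", n, ")", call. = FALSE)
  cands <- enumerate_ranked_topologies(sample$labels)
  fits <- lapply(cands, function(cand)
    fit_times(sample, cand, starts = starts, seed = seed, anchor = anchor,
              reltol = reltol))
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  ord <- order(ll, decreasing = TRUE)
  tab <- data.frame(
    topology = vapply(cands, write_ranked_newick, character(1))[ord],
    logLik = ll[ord],
    gaps = I(lapply(fits[ord], `[[`, "gaps")))
  best <- fits[[ord[1L]]]
  list(tree = best$tree, logLik = best$logLik, gaps = best$gaps,
       score_table = tab)
}
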