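# Model-fitting front end: maximum-likelihood ranked species tree from a
# collection of ranked gene tree topologies, with the usual fitted-model
# methods.

#' Maximum-likelihood species tree from ranked gene trees
#'
#' Fits the multispecies-coalescent multinomial model
#' `P[G_1, ..., G_N | T] = prod_i P[G^(i) | T]^{n_i}` to a collection of
#' ranked gene tree topologies. With `topology` supplied, only the internal
#' divergence-time gaps of that ranked species topology are estimated
#' ([fit_times()]); otherwise every ranked species topology on the leaf set
#' is scored exhaustively ([ml_species_tree()], guarded to `n <= 6`).
#'
#' @param x observed gene trees: a `"ranked_sample"`, a list of
#'   `"ranked_tree"`s, or a character vector of rank-annotated Newick strings.
#' @param counts optional observation counts (may be fractional posterior
#'   weights); default 1 per tree.
#' @param topology optional fixed ranked species topology.
#' @param n_max guard for the exhaustive search.
#' @param starts,seed,anchor,reltol optimisation settings, see [fit_times()].
#' @return an object of class `"mscml"` with methods `print`, `summary`,
#'   `coef` (fitted gaps), `logLik`, `predict` (topology probabilities under
#'   the fitted tree), `fitted`, `residuals` (Pearson), `simulate`
#'   (replicate samples from the fitted tree) and `plot` (observed vs fitted
#'   frequencies).
#' @examples
#' st <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(2, 1))
#' fit <- mscml(simulate(st, 300, seed = 11), topology = st$tree)
#' coef(fit)
#' @export
mscml <- function(x, counts = NULL, topology = NULL, n_max = 6, starts = 3,
                  seed = 1, anchor = 1, reltol = 1e-8) {
  cl <- match.call()
  sample <- ranked_sample(x, counts = counts)
  if (is.null(topology)) {
    res <- ml_species_tree(sample, n_max = n_max, starts = starts,
                           seed = seed, anchor = anchor, reltol = reltol)
    score_table <- res$score_table
  } else {
    res <- fit_times(sample, topology, starts = starts, seed = seed,
                     anchor = anchor, reltol = reltol)
    score_table <- NULL
  }
  structure(list(call = cl, sample = sample, tree = res$tree,
                 gaps = res$gaps, logLik = res$logLik,
                 score_table = score_table,
                 searched = is.null(topology)),
            class = "mscml")
}

#' @export
print.mscml <- function(x, digits = 4, ...) {
  cat("Maximum-likelihood ranked species tree",
      if (x$searched) " (exhaustive search)" else " (fixed topology)",
      "\n", sep = "")
  cat("  ", write_ranked_newick(x$tree$tree), "\n", sep = "")
  cat("  internal gaps (coalescent units): ",
      paste(names(x$gaps), "=", signif(x$gaps, digits), collapse = ", "),
      "\n", sep = "")
  cat("  log-likelihood: ", format(x$logLik, digits = digits + 2),
      "  (N = ", format(x$sample$N), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.mscml <- function(object, ...) object$gaps

#' @export
logLik.mscml <- function(object, ...) {
  structure(object$logLik, df = length(object$gaps), nobs = object$sample$N,
            class = "logLik")
}

#' @rdname mscml
#' @param object an `"mscml"` fit.
#' @param newdata ranked gene trees to score under the fitted species tree
#'   (defaults to the observed topologies).
#' @param ... unused.
#' @export
predict.mscml <- function(object, newdata = NULL, ...) {
  trees <- if (is.null(newdata)) object$sample$trees else
    ranked_sample(newdata)$trees
  p <- vapply(trees, ranked_prob, numeric(1), T_ = object$tree)
  setNames(p, vapply(trees, write_ranked_newick, character(1)))
}

#' @export
fitted.mscml <- function(object, ...) predict(object)

#' @export
residuals.mscml <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  p <- fitted(object)
  obs <- object$sample$counts / object$sample$N
  r <- obs - p
  if (type == "pearson") r <- r / sqrt(p * (1 - p) / object$sample$N)
  setNames(r, names(p))
}

#' @export
summary.mscml <- function(object, ...) {
  p <- fitted(object)
  tab <- data.frame(
    topology = names(p),
    observed = object$sample$counts / object$sample$N,
    fitted = unname(p),
    pearson = unname(residuals(object)))
  out <- list(fit = object, table = tab[order(-tab$observed), ])
  class(out) <- "summary.mscml"
  out
}

#' @export
print.summary.mscml <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nObserved vs fitted ranked topology frequencies:\n")
  tab <- x$table
  tab$observed <- signif(tab$observed, digits)
  tab$fitted <- signif(tab$fitted, digits)
  tab$pearson <- signif(tab$pearson, 3)
  print(tab, row.names = FALSE)
  if (!is.null(x$fit$score_table)) {
    cat("\nTop candidate ranked species topologies:\n")
    st <- utils::head(x$fit$score_table[, c("topology", "logLik")], 5)
    print(st, row.names = FALSE)
  }
  invisible(x)
}

#' @export
simulate.mscml <- function(object, nsim = 1, seed = NULL, N = NULL, ...) {
  N <- if (is.null(N)) round(object$sample$N) else N
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seq_len(nsim), function(i)
    ranked_sample(simulate(object$tree, nsim = N, seed = seeds[i])))
}

#' @export
plot.mscml <- function(x, ...) {
  s <- summary(x)$table
  m <- rbind(observed = s$observed, fitted = s$fitted)
  colnames(m) <- abbreviate(gsub("[;]", "", s$topology), 14)
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = c("observed", "fitted"),
                    ylab = "frequency", cex.names = 0.7, ...)
  invisible(x)
}
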