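# Maximum-likelihood inference of the ranked species tree.

test_that("ranked samples merge duplicates and accept fractional weights", {
  s <- ranked_sample(c("((A,B)2,C)1;", "((B,A)2,C)1;", "((A,C)2,B)1;"))
  expect_equal(length(s$trees), 2)
  expect_equal(s$N, 3)
  expect_equal(sort(s$counts), c(1, 2))

  sw <- ranked_sample(c("((A,B)2,C)1;", "((A,C)2,B)1;"), counts = c(0.25, 0.75))
  expect_equal(sw$N, 1)
  expect_error(ranked_sample(c("((A,B)2,C)1;"), counts = -1), "nonnegative")
  expect_error(ranked_sample(list()), "empty")
  expect_error(ranked_sample(c("((A,B)2,C)1;", "((A,B)2,D)1;")), "leaf set")
})

test_that("log-likelihood is invariant to ordering and duplicate merging", {
  st <- rspecies_tree(4, seed = 51)
  g <- simulate(st, 40, seed = 52)
  l1 <- ranked_loglik(ranked_sample(g), st)
  l2 <- ranked_loglik(ranked_sample(rev(g)), st)
  expect_equal(l1, l2, tolerance = 1e-12)
  # single topology observed N times: N * log P
  g1 <- g[[1]]
  lN <- ranked_loglik(ranked_sample(rep(list(g1), 7)), st)
  expect_equal(lN, 7 * ranked_prob(g1, st, log = TRUE), tolerance = 1e-12)
})

test_that("the three-taxon ML gap matches its closed form", {
  # matching fraction p-hat > 1/3 gives ML gap solving 1 - (2/3) e^{-t} = p-hat
  counts <- c(160, 25, 15)                     # match, mismatch, mismatch
  s <- ranked_sample(c("((A,B)2,C)1;", "((A,C)2,B)1;", "(A,(B,C)2)1;"),
                     counts = counts)
  fit <- fit_times(s, "((A,B)2,C)1;")
  phat <- counts[1] / sum(counts)
  t_analytic <- -log(1.5 * (1 - phat))
  expect_equal(unname(fit$gaps), t_analytic, tolerance = 1e-5)
  expect_equal(fit$tree$times, c(1 + t_analytic, 1), tolerance = 1e-5)
  # and the log-likelihood at the optimum beats nearby gaps
  for (d in c(0.8, 1.25) * t_analytic) {
    alt <- species_tree(fit$tree$tree, times = c(1 + d, 1))
    expect_gt(fit$logLik, ranked_loglik(s, alt))
  }
})

test_that("likelihood at the generating tree beats a perturbed tree", {
  # seeded simulation experiment: n = 5, N = 120 per dataset
  st <- rspecies_tree(5, seed = 61)
  perturbed <- species_tree(st$tree, times = st$times + c(1.5, 0.9, 0.4, 0))
  wins <- 0L
  ndata <- 20L
  for (r in seq_len(ndata)) {
    s <- ranked_sample(simulate(st, 120, seed = 6100 + r))
    if (ranked_loglik(s, st) > ranked_loglik(s, perturbed)) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * ndata))
})

test_that("interval gaps are recovered from simulated data", {
  Ttop <- read_ranked_newick("(((A,B)3,C)2,D)1;")
  truth <- species_tree(Ttop, times = rankedcoal:::times_from_gaps(c(1, 0.5)))
  s <- ranked_sample(simulate(truth, 800, seed = 71))
  fit <- fit_times(s, Ttop, starts = 2)
  expect_lt(max(abs(fit$gaps - c(1, 0.5))), 0.2)
  expect_equal(fit$convergence, 0)
  # n = 2 is flat: nothing to fit
  expect_error(fit_times(ranked_sample("(A,B)1;"), "(A,B)1;"), "flat")
})

test_that("exhaustive search recovers the generating ranked topology", {
  truth <- species_tree(read_ranked_newick("((A,B)3,(C,D)2)1;"),
                        times = rankedcoal:::times_from_gaps(c(1, 1)))
  hits <- 0L
  nrep <- 10L
  for (r in seq_len(nrep)) {
    s <- ranked_sample(simulate(truth, 300, seed = 8100 + r))
    fit <- ml_species_tree(s, starts = 1, reltol = 1e-6)
    if (write_ranked_newick(fit$tree$tree) ==
        write_ranked_newick(truth$tree)) hits <- hits + 1L
    expect_equal(nrow(fit$score_table), 18)
    expect_equal(fit$score_table$logLik[1], fit$logLik)
  }
  expect_gte(hits, ceiling(0.9 * nrep))

  # a single observed 3-taxon topology: the matching species topology wins
  s3 <- ranked_sample(rep(c("((A,B)2,C)1;"), 5))
  fit3 <- ml_species_tree(s3)
  expect_equal(write_ranked_newick(fit3$tree$tree), "((A,B)2,C)1;")
  expect_error(ml_species_tree(ranked_sample(character(0))), "empty")
})

test_that("mscml objects expose the standard fitted-model methods", {
  truth <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(2, 1))
  fit <- mscml(simulate(truth, 400, seed = 91), topology = truth$tree)
  expect_s3_class(fit, "mscml")
  expect_named(coef(fit), "d2")
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 1)
  expect_equal(attr(ll, "nobs"), 400)
  expect_equal(as.numeric(ll), ranked_loglik(fit$sample, fit$tree),
               tolerance = 1e-9)

  p <- predict(fit)
  expect_true(all(p > 0 & p < 1))
  expect_equal(names(p), vapply(fit$sample$trees, write_ranked_newick,
                                character(1)))
  r <- residuals(fit)
  expect_equal(length(r), length(p))
  # fitted probabilities should track observed frequencies
  expect_lt(max(abs(residuals(fit, type = "response"))), 0.1)

  s <- summary(fit)
  expect_s3_class(s, "summary.mscml")
  expect_true(all(c("observed", "fitted", "pearson") %in% names(s$table)))

  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "ranked_sample")
  expect_equal(sims[[1]]$N, 400)

  out <- capture.output(print(fit))
  expect_true(any(grepl("log-likelihood", out)))
})
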