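# The core algorithm: minimum lineage counts, lineage schedules, rates, the
# hypoexponential interval probability, and the full DP.

test_that("minimum lineage counts match the worked examples and brute force", {
  T_ <- fig_species()
  expect_equal(min_lineages(fig_gene_c(), T_)$g, c(2, 3, 5, 5))
  expect_equal(min_lineages(fig_gene_b(), T_)$g, c(2, 4, 5, 5))
  # identical ranked topologies: g_i = i + 1
  expect_equal(min_lineages(fig_gene_match(), T_)$g, c(2, 3, 4, 5))

  # brute-force oracle over random pairs of ranked topologies
  set.seed(42)
  for (n in 3:5) {
    all_t <- enumerate_ranked_topologies(LETTERS[seq_len(n)])
    for (rep in 1:6) {
      G <- all_t[[sample.int(length(all_t), 1)]]
      S <- all_t[[sample.int(length(all_t), 1)]]
      prof <- min_lineages(G, S)
      expect_equal(prof$g, brute_min_lineages(G, S),
                   info = paste(write_ranked_newick(G), write_ranked_newick(S)))
      expect_true(all(prof$g > seq_len(n - 1) & prof$g <= n))
    }
  }
  expect_error(min_lineages(read_ranked_newick("(A,B)1;"), fig_species()),
               "leaf set")
})

test_that("lineage schedules reproduce the printed k tables", {
  st <- fig_species_timed()
  # deep-coalescence gene tree, l = (2,4,5,5): ABC branch counts 1,2,3,
  # DE branch 1,1,1
  sch <- coalescence_schedule(fig_gene_b(), st, i = 2, l_in = 4, l_out = 2)
  expect_equal(unname(sch$k[, 1]), c(1, 2, 3))
  expect_equal(unname(sch$k[, 2]), c(1, 1, 1))
  # rank-mismatch gene tree with all coalescences as recent as possible,
  # l = (2,3,5,5): ABC branch exits 1, holds 2 after the first coalescence
  schc <- coalescence_schedule(fig_gene_c(), st, i = 2, l_in = 3, l_out = 2)
  expect_equal(unname(schc$k[1:2, 1]), c(1, 2))
  # same ranked gene tree, one coalescence shifted into tau_2: counts 2, 3
  schd <- coalescence_schedule(fig_gene_c(), st, i = 2, l_in = 4, l_out = 3)
  expect_equal(unname(schd$k[1:2, 1]), c(2, 3))
  # m = 0: exiting equals entering configuration
  sch0 <- coalescence_schedule(fig_gene_c(), st, i = 3, l_in = 5, l_out = 5)
  expect_equal(sch0$m, 0)
  expect_equal(nrow(sch0$k), 1)

  expect_error(coalescence_schedule(fig_gene_c(), st, i = 2, l_in = 2, l_out = 2),
               "l_in")
})

test_that("schedule bottom counts agree with the daughter-sum recursion", {
  set.seed(11)
  for (n in 4:5) {
    st <- rspecies_tree(n, seed = n + 100)
    all_t <- enumerate_ranked_topologies(st$labels)
    for (rep in 1:4) {
      G <- all_t[[sample.int(length(all_t), 1)]]
      g <- min_lineages(G, st)$g
      for (i in seq(2, n - 2)) {
        l_in <- pick(seq(g[i], n))
        sch <- coalescence_schedule(G, st, i, l_in = l_in, l_out = max(g[i - 1], i))
        alt <- daughter_sum_bottom_counts(G, st, i, l_in = n,
                                          l_out_next = l_in)
        expect_equal(unname(sch$k[nrow(sch$k), ]), unname(alt))
      }
    }
  }
})

test_that("rates are strictly increasing sums of per-population pair counts", {
  st <- fig_species_timed()
  sch <- coalescence_schedule(fig_gene_c(), st, i = 3, l_in = 5, l_out = 3)
  expect_equal(unname(sch$lambda), c(0, 1, 2))
  # m = 0: a single rate, the sum of pair counts of the standing populations
  st3 <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(2, 1))
  sch1 <- coalescence_schedule(read_ranked_newick("((A,B)2,C)1;"), st3,
                               i = 2, l_in = 3, l_out = 3)
  expect_equal(unname(sch1$lambda), choose(2, 2))   # AB holds 2, C holds 1

  # property: random schedules always strictly increasing
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    st <- rspecies_tree(n, seed = rep)
    G <- simulate(st, 1, seed = rep + 50)[[1]]
    g <- min_lineages(G, st)$g
    i <- pick(seq(2, n - 1))
    l_in <- pick(seq(g[i], n))
    l_out <- pick(seq(g[i - 1], l_in))
    sch <- coalescence_schedule(G, st, i, l_in = l_in, l_out = l_out)
    if (sch$m > 0) expect_true(all(diff(sch$lambda) > 0))
    expect_equal(sum(sch$k[nrow(sch$k), ]), l_in)
    expect_equal(sum(sch$k[1, ]), l_out)
  }
})

test_that("interval probability matches closed forms, quadrature, and a
           high-precision oracle", {
  # Worked example: lambda = (0,1,2) gives (1 - e^-D)^2 / 2
  for (d in c(1e-6, 1e-3, 0.1, 1, 5, 50))
    expect_equal(interval_probability(c(0, 1, 2), d),
                 expm1(-d)^2 / 2, tolerance = 1e-12)
  expect_equal(interval_probability(3, 1), exp(-3))
  expect_equal(interval_probability(c(0, 1, 2), Inf), 1 / 2)
  expect_equal(interval_probability(c(2, 5), Inf), 0)

  # frozen 50-digit oracle values (mpmath), covering the cancellation-prone
  # small-Delta regime and the widely separated direct regime
  oracle <- list(
    list(l = c(0, 1, 3),        d = 1e-6, p = 4.99999333333875e-13),
    list(l = c(2, 5, 9, 14),    d = 0.37, p = 6.82652302583178287e-4),
    list(l = c(1, 2, 3, 4, 5),  d = 1e-4, p = 4.1654168610902795e-18),
    list(l = c(0, 3, 4, 10),    d = 25,   p = 8.33333333333333333e-3),
    list(l = 0:10,              d = 0.01, p = 2.62144251502637108e-27),
    list(l = c(1, 45, 66),      d = 50,   p = 6.74388058728642581e-26),
    list(l = c(0, 10, 55, 66),  d = 12,   p = 2.75482093663911846e-5),
    list(l = c(0, 1, 2),        d = 1e-6, p = 4.99999500000291667e-13))
  for (cs in oracle)
    expect_equal(interval_probability(cs$l, cs$d), cs$p, tolerance = 1e-9)

  # random integer rates vs nested quadrature of the joint density
  set.seed(3)
  for (rep in 1:8) {
    m <- sample(1:2, 1)
    lam <- sort(sample(0:12, m + 1))
    d <- runif(1, 0.05, 3)
    expect_equal(interval_probability(lam, d), quad_interval_prob(lam, d),
                 tolerance = 1e-8)
  }

  # monotonicity in Delta: -> 0 when m >= 1, -> 1 when m = 0 with zero rate
  ds <- 10^seq(-4, 1, length.out = 12)
  ps <- vapply(ds, function(d) interval_probability(c(0, 2, 3), d), 1)
  expect_true(all(diff(ps) > 0))
  expect_lt(ps[1], 1e-7)

  expect_error(interval_probability(c(1, 1, 2), 1), "strictly increasing")
  expect_error(interval_probability(c(0, 1), 0), "positive")
})

test_that("labelled history counts match enumeration", {
  expect_equal(labeled_histories(1), 1)
  expect_equal(labeled_histories(2), 1)
  for (k in 3:5)
    expect_equal(labeled_histories(k), brute_labeled_histories(k))
  expect_equal(labeled_histories(4), 18)
  expect_error(labeled_histories(0), ">= 1")
})

test_that("ranked probabilities: closed forms, totals, and invariances", {
  # n = 2: the unique ranked tree has probability 1
  st2 <- species_tree(read_ranked_newick("(A,B)1;"), times = 1)
  expect_equal(ranked_prob("(A,B)1;", st2), 1)

  # three-taxon closed forms
  t <- 1.7
  st3 <- species_tree(read_ranked_newick("((A,B)2,C)1;"), times = c(1 + t, 1))
  expect_equal(ranked_prob("((A,B)2,C)1;", st3), 1 - (2 / 3) * exp(-t),
               tolerance = 1e-12)
  expect_equal(ranked_prob("((A,C)2,B)1;", st3), (1 / 3) * exp(-t),
               tolerance = 1e-12)
  expect_equal(ranked_prob("(A,(B,C)2)1;", st3), (1 / 3) * exp(-t),
               tolerance = 1e-12)

  # DP boundary and the Fig-1c conditional P[G_{2,3} | G_{3,5}, T]
  st <- fig_species_timed(times = c(4, 2.6, 1.9, 1))
  det <- ranked_prob(fig_gene_c(), st, detail = TRUE)
  expect_equal(unname(det$table["i=4", "l=5"]), 1)
  d23 <- st$times[2] - st$times[3]
  sch <- coalescence_schedule(fig_gene_c(), st, i = 3, l_in = 5, l_out = 3)
  expect_equal(interval_probability(sch$lambda, d23),
               (1 - exp(-d23))^2 / 2, tolerance = 1e-12)

  # total probability over all ranked topologies is 1 (n = 3, 4, 5)
  for (n in 3:5) {
    st <- rspecies_tree(n, seed = 20 + n)
    tot <- sum(vapply(enumerate_ranked_topologies(st$labels), ranked_prob,
                      numeric(1), T_ = st))
    expect_equal(tot, 1, tolerance = 1e-10)
  }

  # positivity: every ranked topology has positive probability
  st4 <- rspecies_tree(4, seed = 9)
  ps <- vapply(enumerate_ranked_topologies(st4$labels), ranked_prob,
               numeric(1), T_ = st4)
  expect_true(all(ps > 0))

  # translation invariance: only internal gaps matter
  G <- random_ranked_topology(LETTERS[1:4])
  Ttop <- rspecies_tree(4, seed = 31)$tree
  p1 <- ranked_prob(G, species_tree(Ttop, times = c(3.2, 1.9, 0.8)))
  p2 <- ranked_prob(G, species_tree(Ttop, times = c(3.2, 1.9, 0.8) + 2.5))
  p3 <- ranked_prob(G, species_tree(Ttop, times = c(3.2, 1.9, 0.8) - 0.7))
  expect_equal(p1, p2, tolerance = 1e-13)
  expect_equal(p1, p3, tolerance = 1e-13)

  expect_error(ranked_prob("(A,B)1;", st4), "leaf set")
})

test_that("single-population intervals reduce to the product of g_{i,j} terms", {
  # probability that i lineages coalesce to j within time t in one
  # population: classical Tavare coefficients, independent of the
  # hypoexponential route used by the package
  gij <- function(i, j, t) {
    sum(vapply(j:i, function(k) {
      rising <- function(x, m) if (m == 0) 1 else prod(x + 0:(m - 1))
      falling <- function(x, m) if (m == 0) 1 else prod(x - 0:(m - 1))
      exp(-k * (k - 1) / 2 * t) * (2 * k - 1) * (-1)^(k - j) /
        (factorial(j) * factorial(k - j) * (j + k - 1)) *
        rising(j, k) * falling(i, k) / rising(i, k)
    }, numeric(1)))
  }
  expect_equal(gij(3, 3, 0.9), exp(-3 * 0.9))     # self-consistency spot check

  # when all m coalescences of an interval fall in one population z*, the
  # conditional equals g_{a,b}(t) for that population (a entering, b exiting)
  # times exp(-choose(k_z,2) t) for every other branch, divided by the number
  # of coalescence orders prod_{k=1}^{m} choose(a - k + 1, 2)
  single_pop_identity <- function(sch, d) {
    bot <- sch$k[nrow(sch$k), ]
    top <- sch$k[1, ]
    zstar <- which(bot != top)
    stopifnot(length(zstar) == 1)
    a <- bot[zstar]; b <- top[zstar]
    orders <- prod(choose(a - seq_len(a - b) + 1, 2))
    gij(a, b, d) * prod(exp(-choose(bot[-zstar], 2) * d)) / orders
  }

  st <- species_tree(read_ranked_newick("(((A,B)3,C)2,D)1;"),
                     times = c(3, 2.2, 1))
  G <- read_ranked_newick("(((A,B)3,C)2,D)1;")
  d <- st$times[1] - st$times[2]
  sch <- coalescence_schedule(G, st, i = 2, l_in = 4, l_out = 2)
  expect_equal(interval_probability(sch$lambda, d), single_pop_identity(sch, d),
               tolerance = 1e-10)

  # and on the worked 5-taxon species tree: both tau_2 coalescences of the
  # deep-coalescing gene tree happen in the ABC population
  st5 <- fig_species_timed(times = c(3.4, 2.1, 1.6, 1))
  schb <- coalescence_schedule(fig_gene_b(), st5, i = 2, l_in = 4, l_out = 2)
  d2 <- st5$times[1] - st5$times[2]
  expect_equal(interval_probability(schb$lambda, d2),
               single_pop_identity(schb, d2), tolerance = 1e-10)
})
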