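test_that("candidate window enumeration matches the closed-form count", {
  # sum over w = 9..16 of (L - w + 1)
  cr <- candidate_regions(strrep("A", 20))
  expect_equal(nrow(cr), sum(20 - 9:16 + 1))
  expect_true(all(cr$length >= 9 & cr$length <= 16))

  one <- candidate_regions(strrep("A", 9), min_len = 9, max_len = 9)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(1, 9))

  s <- strrep("ACGU", 10)
  a <- candidate_regions(s, mode = "random", sample_size = 10, seed = 5)
  b <- candidate_regions(s, mode = "random", sample_size = 10, seed = 5)
  expect_identical(a, b)
  expect_warning(
    capped <- candidate_regions(strrep("A", 10), 9, 9,
                                mode = "random", sample_size = 99, seed = 1),
    "capped")
  expect_equal(nrow(capped), 2)
})

test_that("hybridization score composes the model terms", {
  # fully unpaired target: theta = length, dG_tf = 0, dG_asF = 0,
  # dG_asT = -2 * length  =>  nu = 2 * length^2
  ta <- strrep("A", 20)
  sc <- hybridization_score(data.frame(start = 1, end = 9), ta)
  expect_equal(sc$theta_bar, 9)
  expect_equal(sc$dG_tf, 0)
  expect_equal(sc$dG_asT, -18)
  expect_equal(sc$dG_asF, 0)
  expect_equal(sc$nu, 9 * (0 - (-18)) + 0)  # 162

  # structured target: compose the score from oracle-derived components
  ta <- "GGGAAACCC"
  sc <- hybridization_score(data.frame(start = 4, end = 6), ta)
  o <- enumerate_structures(ta)
  theta <- sum(o$unpaired_prob[4:6])
  tf <- enumerate_opening_energy(ta, c(4, 6))
  asT <- duplex_energy("UUU", "AAA")
  asF <- enumerate_structures("UUU")$mfe
  expect_equal(sc$nu, theta * (tf - asT) + asF, tolerance = 1e-9)
})

test_that("knowledge gradient matches its closed form and a Monte-Carlo estimate", {
  expect_equal(kg_value(c(0, 1), c(0, 0.5), 1)[1], 0)  # no belief variance
  v <- kg_value(c(0, 0), c(1, 1), 1)
  expect_equal(v, rep(dnorm(0) / sqrt(2), 2), tolerance = 1e-9)

  # Monte-Carlo: expected gain in posterior max from measuring alternative 1
  set.seed(99)
  y <- rnorm(2e5, 0, sqrt(1 + 1))      # predictive draw for mu = 0
  post <- y * 1 / (1 + 1)              # posterior mean of alt 1
  mc <- mean(pmax(post, 0)) - 0        # E[max(mu1', mu2)] - max(mu)
  expect_equal(v[1], mc, tolerance = 0.01)

  # non-increasing in the gap to the best competitor
  gaps <- seq(0, 3, by = 0.5)
  vals <- vapply(gaps, function(g) kg_value(c(0, g), c(1, 1), 1)[1], 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("greedy set cover reproduces the worked three-candidate instance", {
  d <- greedy_set_cover(starts = c(1, 5, 1), ends = c(6, 10, 10),
                        v = c(0.5, 0.5, 0.1), lambda = 1, L = 10)
  expect_equal(d$selected, c(1, 2))  # A then B; tie at step 1 broken to A
  expect_equal(d$trace$alpha, c(0.5 / 6, 0.5 / 4), tolerance = 1e-12)
  expect_equal(d$trace$marginal, c(6, 4))
})

test_that("greedy set cover always covers, never wastes a pick, and is near-optimal", {
  set.seed(2024)
  for (r in 1:200) {
    L <- sample(8:20, 1)
    n <- sample(3:12, 1)
    starts <- sample(L, n, replace = TRUE)
    lens <- sample(3:8, n, replace = TRUE)
    ends <- pmin(starts + lens - 1L, L)
    starts[1] <- 1L; ends[n] <- L  # nudge toward feasibility
    covered <- rep(FALSE, L)
    for (k in seq_len(n)) covered[starts[k]:ends[k]] <- TRUE
    if (!all(covered)) {
      expect_error(greedy_set_cover(starts, ends, runif(n), 1, L), "uncovered")
      next
    }
    v <- runif(n)
    d <- greedy_set_cover(starts, ends, v, lambda = 1, L = L)
    got <- rep(FALSE, L)
    for (k in d$selected) got[starts[k]:ends[k]] <- TRUE
    expect_true(all(got))
    expect_true(all(d$trace$marginal > 0))
    # greedy is an approximation: objective never exceeds the exhaustive optimum
    obj <- sum(v[d$selected]) - 1 * length(d$selected)
    expect_lte(obj, optimal_cover_objective(starts, ends, v, 1, L) + 1e-9)
  }
})

test_that("baseline designs respect their contracts", {
  ta <- strrep("A", 30)
  e1 <- design_probes(ta, mode = "explore", seed = 42)
  e2 <- design_probes(ta, mode = "explore", seed = 42)
  expect_identical(e1$panel, e2$panel)
  covered <- rep(FALSE, 30)
  for (i in seq_len(nrow(e1$panel))) covered[e1$panel$start[i]:e1$panel$end[i]] <- TRUE
  expect_true(all(covered))
  expect_true(all(e1$panel$length == 12))

  # uniform scores: exploitation degenerates to coverage minimization,
  # earliest-start tiling under the tie rule
  x <- design_probes(ta, mode = "exploit", min_len = 12, max_len = 12)
  expect_equal(sort(x$panel$start), c(1, 13, 19))

  set.seed(31)
  ta2 <- random_rna(40)
  k <- design_probes(ta2, mode = "kg")
  covered <- rep(FALSE, 40)
  for (i in seq_len(nrow(k$panel))) covered[k$panel$start[i]:k$panel$end[i]] <- TRUE
  expect_true(all(covered))
  expect_true(all(k$panel$v >= 0))
})

test_that("experimental effort and its rescaling follow the definitions", {
  truth <- c(1.0, 0.2, 0.7)
  expect_equal(experimental_effort(truth, 1), 0)       # optimum selected
  expect_equal(experimental_effort(truth, 2), 0.8)
  expect_error(experimental_effort(truth, integer(0)), "empty")
  eff <- rescale_efforts(c(0.8, 0.1, 0.4))
  expect_equal(min(eff), 0)
  expect_equal(max(eff), 1)
  expect_equal(rescale_efforts(c(0.3, 0.3)), c(0, 0))
})

test_that("top-fraction rank filter keeps the globally best regions", {
  v <- c(0.1, 0.9, 0.5, 0.8, 0.2, 0.7, 0.05, 0.3, 0.6, 0.4)
  keep <- top_fraction(v, 0.2)
  expect_equal(which(keep), c(2, 4))
  expect_equal(sum(top_fraction(runif(10), 0.015)), 1)  # at least one kept
})
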