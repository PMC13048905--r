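test_that("exchangeability constructors validate and the Poisson builtin is flat", {
  P <- poisson_exchangeabilities(20)
  expect_true(all(P[upper.tri(P)] == 1))
  expect_true(all(diag(P) == 0))
  S <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  expect_equal(unclass(exchangeability_matrix(S))[2, 3], 3)
  expect_error(exchangeability_matrix(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(exchangeability_matrix(-S), "non-negative")
})

test_that("PAML-style .dat files load as symmetric matrices", {
  p <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("1", "2 3"), p)
  S <- load_exchangeabilities(p, s = 3)
  expect_equal(unclass(S), matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3),
               ignore_attr = TRUE)
  writeLines(c("1", "2 3", "0.5 0.3 0.2"), p)
  S2 <- load_exchangeabilities(p, s = 3)
  expect_equal(attr(S2, "freq"), c(0.5, 0.3, 0.2))
  writeLines(c("1", "2"), p)
  expect_error(load_exchangeabilities(p, s = 3), "expected")
})

test_that("discrete gamma bin means match a quadrature oracle and renormalize", {
  expect_equal(discrete_gamma(2, 1)$rates, 1)
  hi <- discrete_gamma(1e6, 4)$rates
  expect_true(all(abs(hi - 1) < 0.01))
  # oracle: numerically integrate x * dgamma within each quantile bin
  for (alpha in c(0.3, 1, 5)) {
    K <- 4
    q <- qgamma(seq(0, 1, length.out = K + 1), alpha, alpha)
    oracle <- vapply(seq_len(K), function(k)
      integrate(function(x) x * dgamma(x, alpha, alpha), q[k], q[k + 1],
                rel.tol = 1e-10)$value * K, 0)
    oracle <- oracle / mean(oracle)
    expect_equal(discrete_gamma(alpha, K)$rates, oracle, tolerance = 1e-6)
  }
  # exact unit mean on a grid
  for (alpha in c(0.1, 0.5, 1, 5))
    for (K in c(1, 2, 4, 8))
      expect_equal(mean(discrete_gamma(alpha, K)$rates), 1, tolerance = 1e-12)
  expect_error(discrete_gamma(0, 4), "positive")
  # rates strictly increasing
  expect_true(all(diff(discrete_gamma(0.5, 8)$rates) > 0))
})

test_that("rate matrices are normalized, reversible GTR constructions", {
  pi <- rep(1 / 20, 20)
  Q <- rate_matrix(poisson_exchangeabilities(20), pi)
  expect_equal(unique(round(Q[row(Q) != col(Q)], 12)), 1 / 19)
  expect_equal(unname(diag(Q)), rep(-1, 20))
  set.seed(1)
  S <- matrix(rgamma(400, 1), 20); S <- S + t(S); diag(S) <- 0
  S <- exchangeability_matrix(S)
  pi <- random_profile(20)
  Q <- rate_matrix(S, pi)
  expect_equal(rowSums(Q), rep(0, 20), tolerance = 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  expect_equal(pi * Q, t(pi * Q), tolerance = 1e-12)  # detailed balance
})

test_that("transition matrices behave at both time limits and compose", {
  set.seed(2)
  S <- poisson_exchangeabilities(20)
  pi <- rep(1 / 20, 20)
  expect_equal(transition_matrix(S, pi, 0), diag(20), tolerance = 1e-12)
  Pinf <- transition_matrix(S, pi, 100)
  expect_true(all(abs(t(Pinf) - pi) < 1e-6))
  # closed form for the Poisson/uniform case
  for (t in c(0.01, 0.3, 2)) {
    P <- transition_matrix(S, pi, t)
    expect_equal(P[1, 1], 1 / 20 + (19 / 20) * exp(-20 * t / 19),
                 tolerance = 1e-10)
  }
  # Chapman-Kolmogorov on random GTR models
  for (i in 1:3) {
    Sr <- matrix(rgamma(36, 1), 6); Sr <- Sr + t(Sr); diag(Sr) <- 0
    Sr <- exchangeability_matrix(Sr)
    pir <- random_profile(6)
    s1 <- runif(1, 0.05, 0.5); s2 <- runif(1, 0.05, 0.5)
    expect_equal(transition_matrix(Sr, pir, s1) %*% transition_matrix(Sr, pir, s2),
                 transition_matrix(Sr, pir, s1 + s2), tolerance = 1e-8)
  }
  expect_error(transition_matrix(S, pi, -1), "negative")
})

test_that("profile learning recovers separable clusters and is deterministic", {
  half <- c(rep("A", 30), rep("C", 30))
  a <- aln_from_strings(list(t1 = paste(half, collapse = ""),
                             t2 = paste(half, collapse = ""),
                             t3 = paste(half, collapse = ""),
                             t4 = paste(half, collapse = "")))
  m1 <- learn_profiles(a, 1, seed = 1, pseudocount = 0)
  expect_equal(ncol(m1$profiles), 1)
  expect_equal(sum(m1$profiles), 1)
  m2 <- learn_profiles(a, 2, seed = 1, pseudocount = 0)
  tops <- apply(m2$profiles, 2, which.max)
  expect_setequal(rootsignal:::AA_STATES[tops], c("A", "C"))
  expect_true(all(apply(m2$profiles, 2, max) > 0.99))
  expect_equal(m2$weights, c(0.5, 0.5), tolerance = 1e-9)
  m2b <- learn_profiles(a, 2, seed = 1, pseudocount = 0)
  expect_identical(m2$profiles, m2b$profiles)
  expect_error(learn_profiles(a, 5, seed = 1, pseudocount = 0), "distinct")
})

test_that("model containers enforce simplex invariants", {
  expect_error(mixture_model(poisson_exchangeabilities(3),
                             matrix(c(0.5, 0.4, 0.2), ncol = 1)), "sum to 1")
  expect_error(mixture_model(poisson_exchangeabilities(3),
                             matrix(c(0.5, 0.3, 0.2), ncol = 1),
                             weights = c(0.7, 0.7)), "one weight")
  g <- discrete_gamma(0.7, 4)
  m <- mixture_model(poisson_exchangeabilities(3),
                     cbind(c(0.5, 0.3, 0.2), c(1, 0, 0) * 0.98 + 0.02 / 3),
                     gamma = g)
  expect_equal(sum(m$weights), 1)
  expect_error(site_frequency_model(poisson_exchangeabilities(3),
                                    matrix(c(0.5, 0.6, 0.2), ncol = 1)),
               "simplex")
})

test_that("profile dictionaries load from TSV", {
  p <- withr::local_tempfile(fileext = ".tsv")
  d <- as.data.frame(t(default_profiles()))
  write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  pd <- read_profile_dictionary(p, s = 20)
  expect_equal(ncol(pd$profiles), 5)
  expect_equal(colSums(pd$profiles), rep(1, 5), ignore_attr = TRUE)
})
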