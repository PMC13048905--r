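test_that("pruning equals exhaustive enumeration on small random trees", {
  set.seed(10)
  s <- 4  # small alphabet keeps the oracle cheap; the engine is size-generic
  for (trial in 1:6) {
    n <- sample(4:5, 1)
    tree <- ape::unroot(ape::rtree(n))
    pi <- random_profile(s)
    S <- poisson_exchangeabilities(s)
    model <- mixture_model(S, matrix(pi, ncol = 1), 1, discrete_gamma(1, 1))
    states <- matrix(sample(c(-1L, 0:(s - 1L)), n * 20, replace = TRUE,
                            prob = c(0.15, rep(0.85 / s, s))), n, 20)
    chars <- c("A", "R", "N", "D")
    mat <- matrix("X", n, 20, dimnames = list(tree$tip.label, NULL))
    mat[states >= 0] <- chars[states[states >= 0] + 1]
    # restrict to a 4-letter sub-alphabet via a custom 4-state model
    aln <- new_alignment(mat)
    pi20 <- c(pi, rep(0, 16))
    model20 <- mixture_model(poisson_exchangeabilities(20),
                             matrix(pi20, ncol = 1), 1, discrete_gamma(1, 1))
    sl <- site_log_likelihoods(aln, tree, model20)
    for (j in seq_len(20)) {
      oracle <- log(brute_site_lik(tree, states[, j], pi,
                                   function(t) pois_P(pi, t)))
      expect_equal(sl$site_lnl[j], oracle, tolerance = 1e-10)
    }
  }
})

test_that("pruning under a gamma mixture equals the averaged oracle", {
  set.seed(11)
  s <- 4
  tree <- ape::unroot(ape::rtree(5))
  pi <- random_profile(s)
  g <- discrete_gamma(0.6, 3)
  states <- matrix(sample(0:(s - 1L), 5 * 10, replace = TRUE), 5, 10)
  chars <- c("A", "R", "N", "D")
  mat <- matrix(chars[states + 1], 5, 10,
                dimnames = list(tree$tip.label, NULL))
  aln <- new_alignment(mat)
  model <- mixture_model(poisson_exchangeabilities(20),
                         matrix(c(pi, rep(0, 16)), ncol = 1), 1, g)
  sl <- site_log_likelihoods(aln, tree, model)
  for (j in 1:10) {
    per_rate <- vapply(g$rates, function(r)
      brute_site_lik(tree, states[, j], pi,
                     function(t) pois_P(pi, t * r)), 0)
    expect_equal(sl$site_lnl[j], log(mean(per_rate)), tolerance = 1e-10)
  }
})

test_that("dense and closed-form paths agree; profile mixtures sum over classes", {
  set.seed(12)
  roles <- taxon_roles(1, 2, 3)
  tree <- make_hypothesis_trees(roles)$LM_SISTER
  prof <- default_profiles()[, 1:3]
  model <- mixture_model(poisson_exchangeabilities(20), prof,
                         c(0.5, 0.3, 0.2), discrete_gamma(0.9, 2))
  aln <- simulate_alignment(tree, model, 80, seed = 3)
  sl_fast <- site_log_likelihoods(aln, tree, model)
  # dense path forced by a numerically non-flat copy of the Poisson matrix
  S2 <- unclass(poisson_exchangeabilities(20))
  S2[1, 2] <- S2[2, 1] <- 1 + 1e-12
  model2 <- model
  model2$exch <- exchangeability_matrix(S2)
  sl_dense <- site_log_likelihoods(aln, tree, model2)
  expect_equal(sl_fast$site_lnl, sl_dense$site_lnl, tolerance = 1e-6)
  expect_equal(sl_fast$lnl, sum(sl_fast$site_lnl), tolerance = 1e-6)
})

test_that("two-taxon likelihood matches the closed form and missing data is neutral", {
  tree <- parse_newick("(A:0.15,B:0.25);")
  pi <- rep(1 / 20, 20)
  model <- mixture_model(poisson_exchangeabilities(20),
                         matrix(pi, ncol = 1), 1, discrete_gamma(1, 1))
  aln <- aln_from_strings(c(A = "AAX", B = "ACX"))
  sl <- site_log_likelihoods(aln, tree, model)
  t <- 0.4
  Paa <- 1 / 20 + (19 / 20) * exp(-20 * t / 19)
  expect_equal(sl$site_lnl[1], log(pi[1] * Paa), tolerance = 1e-10)
  expect_equal(sl$site_lnl[2], log(pi[1] * (1 - Paa) / 19), tolerance = 1e-10)
  expect_equal(sl$site_lnl[3], 0)  # all-missing column
})

test_that("likelihood is invariant to pattern duplication and re-rooting", {
  set.seed(13)
  roles <- taxon_roles(1, 2, 3)
  tree <- make_hypothesis_trees(roles)$L_SISTER
  model <- mixture_model(poisson_exchangeabilities(20), default_profiles(),
                         gamma = discrete_gamma(1, 4))
  aln <- simulate_alignment(tree, model, 60, seed = 4)
  dup <- new_alignment(aln$mat[, c(1:60, 1:60)])
  expect_equal(site_log_likelihoods(dup, tree, model)$lnl,
               2 * site_log_likelihoods(aln, tree, model)$lnl,
               tolerance = 1e-8)
  rr <- ape::root(ape::unroot(tree), outgroup = "L1", resolve.root = TRUE)
  expect_equal(site_log_likelihoods(aln, rr, model)$lnl,
               site_log_likelihoods(aln, tree, model)$lnl, tolerance = 1e-8)
})

test_that("branch optimization collapses identical sequences and is a fixed point", {
  tree <- parse_newick("((A:0.3,B:0.3):0.1,(C:0.3,D:0.3):0.1);")
  aln <- aln_from_strings(c(A = strrep("ARNDCQEGHI", 10),
                            B = strrep("ARNDCQEGHI", 10),
                            C = strrep("KFPSTWYVLM", 10),
                            D = strrep("KFPSTWYVLM", 10)))
  model <- mixture_model(poisson_exchangeabilities(20),
                         matrix(empirical_frequencies(aln), ncol = 1), 1,
                         discrete_gamma(1, 1))
  f <- optimize_branch_lengths(aln, tree, model)
  E <- f$tree$edge
  tiplen <- f$tree$edge.length[E[, 2] <= 4]
  expect_true(all(tiplen <= 1e-6))
  expect_true(all(diff(f$trace) >= 0))
  f2 <- optimize_branch_lengths(aln, f$tree, model)
  expect_lt(abs(f2$lnl - f$lnl), 1e-3)
})

test_that("branch lengths are recovered from simulated data", {
  set.seed(14)
  tree <- ape::unroot(ape::rtree(6))
  tree$edge.length <- runif(nrow(tree$edge), 0.1, 0.5)
  model <- mixture_model(poisson_exchangeabilities(20),
                         matrix(rep(1 / 20, 20), ncol = 1), 1,
                         discrete_gamma(1, 1))
  aln <- simulate_alignment(tree, model, 5000, seed = 15)
  start <- tree
  start$edge.length <- rep(0.1, nrow(tree$edge))
  f <- optimize_branch_lengths(aln, start, model)
  truth <- ape::reorder.phylo(tree, "postorder")  # same edge order as the fit
  rel <- abs(f$tree$edge.length - truth$edge.length) / truth$edge.length
  expect_lt(median(rel), 0.15)
})

test_that("gamma shape estimation recovers the truth and pins homogeneous data", {
  set.seed(16)
  roles <- taxon_roles(1, 2, 3)
  tree <- make_hypothesis_trees(roles)$LM_SISTER
  model <- mixture_model(poisson_exchangeabilities(20),
                         matrix(rep(1 / 20, 20), ncol = 1), 1,
                         discrete_gamma(0.8, 4))
  aln <- simulate_alignment(tree, model, 10000, seed = 17)
  m0 <- model; m0$gamma <- discrete_gamma(2, 4)
  m1 <- estimate_alpha(aln, tree, m0)
  expect_gt(attr(m1, "alpha"), 0.6)
  expect_lt(attr(m1, "alpha"), 1.0)
  # lnL can only improve over the starting shape
  l0 <- site_log_likelihoods(aln, tree, m0)$lnl
  expect_gte(attr(m1, "lnl"), l0)
  homo <- model; homo$gamma <- discrete_gamma(1, 1)
  aln2 <- simulate_alignment(tree, homo, 3000, seed = 18)
  m2 <- model; m2$gamma <- discrete_gamma(1, 4)
  m3 <- estimate_alpha(aln2, tree, m2)
  expect_equal(attr(m3, "alpha"), 100)
})

test_that("EM weight fitting finds separable clusters and never decreases lnL", {
  half <- paste(c(rep("A", 40), rep("C", 40)), collapse = "")
  aln <- aln_from_strings(c(t1 = half, t2 = half, t3 = half, t4 = half))
  tree <- parse_newick("((t1:0.05,t2:0.05):0.02,(t3:0.05,t4:0.05):0.02);")
  dA <- 0.94 * (rootsignal:::AA_STATES == "A") + 0.003
  dC <- 0.94 * (rootsignal:::AA_STATES == "C") + 0.003
  model <- mixture_model(poisson_exchangeabilities(20),
                         cbind(dA / sum(dA), dC / sum(dC)), c(0.9, 0.1),
                         discrete_gamma(1, 1))
  m <- fit_mixture_weights_em(aln, tree, model)
  expect_equal(m$weights, c(0.5, 0.5), tolerance = 0.05)
  expect_true(all(diff(attr(m, "trace")) >= -1e-9))
  one <- fit_mixture_weights_em(aln, tree,
                                mixture_model(poisson_exchangeabilities(20),
                                              matrix(dA / sum(dA), ncol = 1),
                                              1, discrete_gamma(1, 1)))
  expect_equal(one$weights, 1)
})

test_that("PMSF construction concentrates on the right profiles", {
  half <- paste(c(rep("A", 40), rep("C", 40)), collapse = "")
  aln <- aln_from_strings(c(t1 = half, t2 = half, t3 = half, t4 = half))
  tree <- parse_newick("((t1:0.05,t2:0.05):0.02,(t3:0.05,t4:0.05):0.02);")
  dA <- 0.94 * (rootsignal:::AA_STATES == "A") + 0.003
  dC <- 0.94 * (rootsignal:::AA_STATES == "C") + 0.003
  model <- mixture_model(poisson_exchangeabilities(20),
                         cbind(dA / sum(dA), dC / sum(dC)), c(0.5, 0.5),
                         discrete_gamma(1, 1))
  pm <- pmsf_site_frequencies(aln, tree, model)
  expect_true(all(pm$site_freqs[1, 1:40] > 0.9))    # 'A' sites
  expect_true(all(pm$site_freqs[5, 41:80] > 0.9))   # 'C' sites
  expect_equal(colSums(pm$site_freqs), rep(1, 80), tolerance = 1e-9)
  # K = 1 PMSF evaluation equals the plain single-profile mixture exactly
  single <- mixture_model(poisson_exchangeabilities(20),
                          matrix(dA / sum(dA), ncol = 1), 1,
                          discrete_gamma(0.7, 4))
  pm1 <- pmsf_site_frequencies(aln, tree, single)
  expect_equal(site_log_likelihoods(aln, tree, pm1)$lnl,
               site_log_likelihoods(aln, tree, single)$lnl,
               tolerance = 1e-9)
})

test_that("candidate evaluation ranks the generating topology first", {
  set.seed(19)
  roles <- taxon_roles(2, 2, 4)
  trees <- make_hypothesis_trees(roles)
  model <- mixture_model(poisson_exchangeabilities(20), default_profiles(),
                         gamma = discrete_gamma(1, 4))
  wins <- 0
  for (i in 1:8) {
    aln <- simulate_alignment(trees$M_SISTER, model, 2000, seed = 100 + i)
    ev <- evaluate_candidates(aln, model, unname(trees))
    if (ev$ranking[1] == 3) wins <- wins + 1
  }
  expect_gte(wins, 7)
  # duplicate candidates tie to within tolerance, input order breaks the tie
  aln <- simulate_alignment(trees$M_SISTER, model, 300, seed = 1)
  ev <- evaluate_candidates(aln, model, list(trees$M_SISTER, trees$M_SISTER))
  expect_lt(abs(ev$lnl[1] - ev$lnl[2]), 1e-3)
  expect_equal(ev$ranking[1], 1)
  # degenerate single-site alignment still returns a ranking
  one <- new_alignment(aln$mat[, 1, drop = FALSE])
  ev1 <- evaluate_candidates(one, model, unname(trees))
  expect_length(ev1$ranking, 3)
})

test_that("NNI search stays at the truth and improves from a wrong start", {
  set.seed(20)
  roles <- taxon_roles(1, 2, 3)
  trees <- make_hypothesis_trees(roles)
  model <- mixture_model(poisson_exchangeabilities(20),
                         matrix(rep(1 / 20, 20), ncol = 1), 1,
                         discrete_gamma(1, 1))
  aln <- simulate_alignment(trees$LM_SISTER, model, 4000, seed = 21)
  stay <- nni_search(aln, model, trees$LM_SISTER)
  expect_equal(robinson_foulds(stay$tree, trees$LM_SISTER), 0)
  expect_equal(attr(stay, "n_moves"), 0)
  hits <- 0
  for (i in 1:3) {
    a <- simulate_alignment(trees$LM_SISTER, model, 4000, seed = 30 + i)
    wrong <- ape::rtree(7, tip.label = trees$LM_SISTER$tip.label)
    f0 <- optimize_branch_lengths(a, wrong, model)
    fs <- nni_search(a, model, wrong)
    expect_gte(fs$lnl, f0$lnl)
    if (robinson_foulds(fs$tree, trees$LM_SISTER) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("BIC selection penalizes parameters and prefers the generating family", {
  set.seed(22)
  roles <- taxon_roles(1, 2, 3)
  tree <- make_hypothesis_trees(roles)$LM_SISTER
  gen <- mixture_model(poisson_exchangeabilities(20),
                       matrix(rep(1 / 20, 20), ncol = 1), 1,
                       discrete_gamma(0.5, 4))
  wins <- 0
  for (i in 1:3) {
    aln <- simulate_alignment(tree, gen, 2000, seed = 40 + i)
    sel <- select_model_bic(aln, tree, list(
      model_spec("Poisson+G", profiles = "uniform"),
      model_spec("Poisson", profiles = "uniform", gamma_categories = 1)))
    f <- sel$best
    expect_equal(f$bic, -2 * f$lnl + f$n_par * log(n_sites(aln)),
                 tolerance = 1e-9)
    if (f$spec$name == "Poisson+G") wins <- wins + 1
  }
  expect_equal(wins, 3)
})

test_that("free-parameter counts follow the documented accounting", {
  # 2n-3 branches + alpha + (s-1) frequencies
  expect_equal(rootsignal:::count_free_params(
    model_spec("m"), n_taxa = 10, s = 20, K_eff = 1, gamma_K = 4),
    17 + 1 + 19)
  # mixture with learned profiles: weights only
  expect_equal(rootsignal:::count_free_params(
    model_spec("m", K = 5, profiles = NULL), n_taxa = 10, s = 20,
    K_eff = 5, gamma_K = 4), 17 + 1 + 4)
  # dayhoff6 GTR: (36-6)/2 - 1 = 14 exchangeabilities
  expect_equal(rootsignal:::count_free_params(
    model_spec("m", exch = "gtr", profiles = "uniform"), n_taxa = 10,
    s = 6, K_eff = 1, gamma_K = 4), 17 + 1 + 14)
})

test_that("RELL bootstrap is deterministic and tracks signal strength", {
  set.seed(23)
  roles <- taxon_roles(1, 2, 3)
  trees <- make_hypothesis_trees(roles)
  model <- mixture_model(poisson_exchangeabilities(20),
                         matrix(rep(1 / 20, 20), ncol = 1), 1,
                         discrete_gamma(1, 1))
  strong <- simulate_alignment(trees$L_SISTER, model, 10000, seed = 24)
  bs <- felsenstein_bootstrap(strong, model, unname(trees), B = 50, seed = 7)
  expect_equal(bs$winner, rep(2L, 50))
  bs2 <- felsenstein_bootstrap(strong, model, unname(trees), B = 50, seed = 7)
  expect_identical(bs$winner, bs2$winner)
  # signal-free data (iid columns, no tree structure): winners spread out
  star <- trees$L_SISTER
  star$edge.length[] <- 5
  noise <- simulate_alignment(star, model, 400, seed = 25)
  bsn <- felsenstein_bootstrap(noise, model, unname(trees), B = 60, seed = 8)
  expect_gte(length(unique(bsn$winner)), 2)
  # full mode agrees with rell on overwhelming signal
  bf <- felsenstein_bootstrap(strong, model, unname(trees), B = 3, seed = 9,
                              mode = "full")
  expect_equal(bf$winner, rep(2L, 3))
})

test_that("AU test separates dominance from ties", {
  set.seed(26)
  n <- 300
  base <- rnorm(n, -3, 1)
  tied <- cbind(h1 = base, h2 = base)
  au <- au_test(tied, B = 500, seed = 1)
  expect_equal(unname(au$p_au["h1"]), 0.5, tolerance = 0.05)
  expect_equal(unname(au$p_au["h2"]), 0.5, tolerance = 0.05)
  dom <- cbind(best = base + 1, worst = base)
  expect_warning(au2 <- au_test(dom, B = 500, seed = 2), "degenerate")
  expect_gte(unname(au2$p_au["best"]), 0.99)
  expect_lte(unname(au2$p_au["worst"]), 0.01)
  expect_true(all(abs(rowSums(au2$bp) - 1) < 1e-9))
  expect_error(au_test(tied[1:5, ], B = 100, seed = 1), "10 sites")
  expect_error(au_test(tied[, 1, drop = FALSE], B = 100, seed = 1),
               "2 hypotheses")
})

test_that("per-site lnL matrices round-trip through TSV", {
  set.seed(27)
  L <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_site_lnl_tsv(L, p)
  expect_equal(read_site_lnl_tsv(p), L, tolerance = 1e-12)
})
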