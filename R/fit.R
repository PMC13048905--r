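# Model specification, fitting, BIC selection, candidate-topology
# comparison, NNI search and bootstrap.

#' Declare a substitution model to be fitted
#'
#' A lightweight recipe consumed by [fit_model()] and [select_model_bic()].
#'
#' @param name model tag used in reports.
#' @param exch `"poisson"`, `"gtr"` (exchangeabilities estimated by ML), or
#'   an [exchangeability_matrix()] (e.g. loaded from a PAML .dat file).
#' @param profiles `"empirical"` (single +F profile from the data),
#'   `"uniform"` (single flat profile), or a states x K matrix of fixed
#'   profiles (a user-supplied dictionary).
#' @param K when non-NULL, learn `K` profiles from the data by k-means
#'   ([learn_profiles()]), overriding `profiles`.
#' @param gamma_categories number of discrete Gamma categories (1 = rate
#'   homogeneous).
#' @param alpha initial Gamma shape.
#' @param estimate_alpha estimate alpha by ML (needs >= 2 categories)?
#' @param em_weights refit mixture weights by EM when K > 1?
#' @param profile_seed seed for profile learning.
#' @export
model_spec <- function(name, exch = "poisson", profiles = "empirical",
                       K = NULL, gamma_categories = 4, alpha = 1,
                       estimate_alpha = TRUE, em_weights = TRUE,
                       profile_seed = 1) {
  structure(list(name = name, exch = exch, profiles = profiles, K = K,
                 gamma_categories = gamma_categories, alpha = alpha,
                 estimate_alpha = estimate_alpha, em_weights = em_weights,
                 profile_seed = profile_seed), class = "rs_model_spec")
}

# free-parameter count for BIC; learned/fixed profile ENTRIES are not
# counted (they are treated as fixed inputs, like PMSF site frequencies)
count_free_params <- function(spec, n_taxa, s, K_eff, gamma_K) {
  p <- 2 * n_taxa - 3                       # branch lengths
  if (gamma_K >= 2 && spec$estimate_alpha) p <- p + 1
  if (identical(spec$profiles, "empirical") && is.null(spec$K))
    p <- p + (s - 1)                        # +F frequencies
  if (K_eff > 1 && spec$em_weights) p <- p + (K_eff - 1)
  if (identical(spec$exch, "gtr")) p <- p + s * (s - 1) / 2 - 1
  p
}

# ML estimation of GTR exchangeabilities at fixed tree/profiles
fit_gtr_exch <- function(pd, model, maxit = 100) {
  s <- nrow(model$profiles)
  ut <- upper.tri(matrix(0, s, s))
  nfree <- s * (s - 1) / 2 - 1              # first entry fixed at 1
  rates <- model$gamma$rates
  logw <- log(model$weights)
  obj <- function(theta) {
    v <- c(1, exp(theta))
    S <- matrix(0, s, s); S[ut] <- v; S <- S + t(S)
    m2 <- model
    m2$exch <- exchangeability_matrix(S, "GTR-free")
    cl <- class_loglik_matrix(pd, m2)
    -sum(pd$wpat * logsumexp_rows(sweep(cl, 2, logw, "+")))
  }
  opt <- optim(rep(0, nfree), obj, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-7))
  v <- c(1, exp(opt$par))
  S <- matrix(0, s, s); S[ut] <- v; S <- S + t(S)
  list(exch = exchangeability_matrix(S, "GTR-free"), lnl = -opt$value)
}

#' Fit a model specification on a fixed topology
#'
#' Builds the model from its recipe, then alternates: branch lengths, EM
#' mixture weights, Gamma shape, (for `"gtr"`) exchangeabilities, and a
#' final branch-length pass.
#'
#' @param aln an `rs_alignment`.
#' @param tree topology to fit on (lengths optimized, topology fixed).
#' @param spec an [model_spec()].
#' @param tol lnL convergence tolerance per stage.
#' @return an `rs_fit` with elements `tree`, `model`, `lnl`, `n_par`,
#'   `bic`, `spec`, `log` (per-stage lnL).
#' @export
fit_model <- function(aln, tree, spec, tol = 1e-4) {
  s <- length(alphabet_states(aln$alphabet))
  exch <- if (inherits(spec$exch, "rs_exchangeability")) spec$exch
          else poisson_exchangeabilities(s)  # "gtr" starts from Poisson
  gamma <- discrete_gamma(spec$alpha, spec$gamma_categories)
  if (!is.null(spec$K)) {
    model <- learn_profiles(aln, spec$K, seed = spec$profile_seed,
                            gamma = gamma)
    model$exch <- exch
  } else if (is.matrix(spec$profiles)) {
    model <- mixture_model(exch, spec$profiles, gamma = gamma,
                           name = spec$name)
  } else if (identical(spec$profiles, "empirical")) {
    f <- empirical_frequencies(aln, pseudocount = 0.5)
    model <- mixture_model(exch, matrix(f / sum(f), ncol = 1), 1, gamma,
                           name = spec$name)
  } else {
    model <- mixture_model(exch, matrix(1 / s, s, 1), 1, gamma,
                           name = spec$name)
  }
  model$name <- spec$name
  stage_log <- c()
  # coarse first pass; parameters are refined before the final pass
  fit <- optimize_branch_lengths(aln, tree, model, tol = max(tol, 1e-2))
  tree <- fit$tree; lnl <- fit$lnl
  stage_log <- c(blen1 = lnl)
  if (ncol(model$profiles) > 1 && spec$em_weights) {
    model <- fit_mixture_weights_em(aln, tree, model)
    lnl <- attr(model, "lnl")
    stage_log <- c(stage_log, em = lnl)
  }
  if (spec$gamma_categories >= 2 && spec$estimate_alpha) {
    model <- estimate_alpha(aln, tree, model)
    lnl <- attr(model, "lnl")
    stage_log <- c(stage_log, alpha = lnl)
  }
  if (identical(spec$exch, "gtr")) {
    pd <- prep_data(aln, tree)
    g <- fit_gtr_exch(pd, model)
    model$exch <- g$exch
    lnl <- g$lnl
    stage_log <- c(stage_log, gtr = lnl)
  }
  fit <- optimize_branch_lengths(aln, tree, model, tol = tol)
  tree <- fit$tree; lnl <- fit$lnl
  stage_log <- c(stage_log, blen2 = lnl)
  K_eff <- ncol(model$profiles)
  n_par <- count_free_params(spec, ape::Ntip(tree), s, K_eff,
                             spec$gamma_categories)
  bic <- -2 * lnl + n_par * log(n_sites(aln))
  structure(list(tree = tree, model = model, lnl = lnl, n_par = n_par,
                 bic = bic, spec = spec, log = stage_log),
            class = "rs_fit")
}

#' Select the best-fitting model by BIC
#'
#' Fits every specification on the same tree; `BIC = -2 lnL + p ln(n_sites)`;
#' the lowest BIC wins, ties going to the model with fewer parameters.
#'
#' @param aln an `rs_alignment`.
#' @param tree topology shared by all fits.
#' @param specs list of [model_spec()] recipes.
#' @return list: `best` (an `rs_fit`), `table` (name, lnl, n_par, bic).
#' @export
select_model_bic <- function(aln, tree, specs, tol = 1e-4) {
  stopifnot(length(specs) >= 1)
  fits <- lapply(specs, function(sp) fit_model(aln, tree, sp, tol = tol))
  tab <- data.frame(name = vapply(specs, function(sp) sp$name, ""),
                    lnl = vapply(fits, function(f) f$lnl, 0),
                    n_par = vapply(fits, function(f) f$n_par, 0),
                    bic = vapply(fits, function(f) f$bic, 0),
                    stringsAsFactors = FALSE)
  o <- order(tab$bic, tab$n_par)
  list(best = fits[[o[1]]], table = tab[o, ])
}

#' Compare candidate topologies under one model
#'
#' Each candidate is independently optimized (branch lengths, optionally
#' also the Gamma shape) and candidates are ranked by final lnL, ties
#' broken by input order.
#'
#' @param aln an `rs_alignment`.
#' @param model an `rs_mixture` or `rs_pmsf`.
#' @param candidate_trees list of trees on identical leaf sets.
#' @param optimize `"lengths"` or `"lengths+alpha"`.
#' @param tol lnL tolerance.
#' @param max_rounds branch-optimization round cap per candidate.
#' @return list: `fits` (per candidate, input order), `ranking` (indices,
#'   best first), `lnl` (per candidate).
#' @export
evaluate_candidates <- function(aln, model, candidate_trees,
                                optimize = c("lengths", "lengths+alpha"),
                                tol = 1e-4, max_rounds = 20) {
  optimize <- match.arg(optimize)
  stopifnot(length(candidate_trees) >= 2 || length(candidate_trees) == 1)
  base <- candidate_trees[[1]]$tip.label
  for (tr in candidate_trees)
    if (!setequal(tr$tip.label, base)) stop("leaf-set mismatch")
  fits <- lapply(candidate_trees, function(tr) {
    f <- optimize_branch_lengths(aln, tr, model, tol = tol,
                                 max_rounds = max_rounds)
    if (optimize == "lengths+alpha" && model$gamma$K >= 2) {
      m2 <- estimate_alpha(aln, f$tree, f$model)
      f2 <- optimize_branch_lengths(aln, f$tree, m2, tol = tol,
                                    max_rounds = max_rounds)
      if (f2$lnl >= f$lnl) f <- f2
    }
    f
  })
  lnl <- vapply(fits, function(f) f$lnl, 0)
  ranking <- order(-lnl)  # stable: ties keep input order
  list(fits = fits, ranking = ranking, lnl = lnl)
}

# NNI neighbours of an unrooted binary tree, preserving branch lengths.
# For each internal edge (u, v) the two swaps exchange one child subtree
# of v with one subtree on u's side.
nni_neighbors <- function(tree) {
  # a degree-2 root would generate redundant moves across the root
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  E <- tree$edge
  out <- list()
  for (i in seq_len(nrow(E))) {
    v <- E[i, 2]
    if (v <= n_tip) next
    u <- E[i, 1]
    kids_v <- which(E[, 1] == v)
    others_u <- setdiff(which(E[, 1] == u), i)
    if (!length(others_u)) next
    ci <- others_u[1]
    for (ai in kids_v) {
      E2 <- E
      E2[ai, 1] <- u
      E2[ci, 1] <- v
      t2 <- tree
      t2$edge <- E2
      attr(t2, "order") <- NULL
      t2 <- ape::reorder.phylo(t2, "postorder")
      out[[length(out) + 1]] <- t2
    }
  }
  out
}

#' Greedy NNI tree search
#'
#' Best-improvement nearest-neighbour-interchange hill climbing: neighbours
#' are scored at the current branch lengths (cheap), the best one is
#' re-optimized and accepted if it improves the lnL by more than `tol`.
#' Returns a local optimum; this is a desk-scale stand-in for a full ML
#' tree search.
#'
#' @param aln an `rs_alignment`.
#' @param model an `rs_mixture` or `rs_pmsf`.
#' @param start_tree binary starting topology.
#' @param max_rounds cap on accepted moves.
#' @param tol minimum lnL gain to accept a move.
#' @return an `rs_fit` at the local optimum, with `n_moves` attribute.
#' @export
nni_search <- function(aln, model, start_tree, max_rounds = 20, tol = 1e-4) {
  fit <- optimize_branch_lengths(aln, start_tree, model)
  moves <- 0
  # tip indices are preserved by the NNI edge surgery, so the compressed
  # state matrix can be prepared once and reused for every neighbour
  pd0 <- prep_data(aln, fit$tree, compress = !inherits(model, "rs_pmsf"))
  pois <- is_poisson_exch(model$exch)
  score_tree <- function(nb) {
    pd <- pd0
    pd$edge <- nb$edge
    pd$blen <- nb$edge.length
    if (inherits(model, "rs_pmsf")) sum(pmsf_pattern_loglik(pd, model))
    else {
      cl <- class_loglik_matrix(pd, model)
      sum(pd$wpat * logsumexp_rows(sweep(cl, 2, log(model$weights), "+")))
    }
  }
  for (round in seq_len(max_rounds)) {
    nbs <- nni_neighbors(fit$tree)
    if (!length(nbs)) break
    scores <- vapply(nbs, score_tree, 0)
    best <- which.max(scores)
    cand <- optimize_branch_lengths(aln, nbs[[best]], model)
    if (cand$lnl > fit$lnl + tol) {
      fit <- cand
      moves <- moves + 1
    } else break
  }
  attr(fit, "n_moves") <- moves
  fit
}

#' Nonparametric (Felsenstein) bootstrap over candidate topologies
#'
#' Columns are resampled with replacement (same length).  In `"rell"` mode
#' each candidate's per-site log-likelihoods from the original fits are
#' re-weighted (no re-optimization); in `"full"` mode every replicate is
#' re-optimized through [evaluate_candidates()].  The winner of each
#' replicate is recorded; pooled winner trees feed the CUBS consensus.
#'
#' @param aln an `rs_alignment`.
#' @param model an `rs_mixture` or `rs_pmsf`.
#' @param candidate_trees candidate topologies (identical leaf sets).
#' @param B number of bootstrap replicates.
#' @param seed integer seed.
#' @param mode `"rell"` (default) or `"full"`.
#' @return an `rs_bootstrap` list: `trees` (B winning trees, with the
#'   fitted branch lengths), `winner` (indices), `lnl` (original-data lnL
#'   per candidate), `B`, `seed`, `mode`.
#' @export
felsenstein_bootstrap <- function(aln, model, candidate_trees, B, seed,
                                  mode = c("rell", "full")) {
  mode <- match.arg(mode)
  stopifnot(B >= 1)
  ev <- evaluate_candidates(aln, model, candidate_trees)
  if (mode == "rell") {
    L <- vapply(seq_along(candidate_trees), function(i)
      site_log_likelihoods(aln, ev$fits[[i]]$tree, model)$site_lnl,
      numeric(n_sites(aln)))
    n <- nrow(L)
    winner <- with_seed(seed, {
      W <- resample_counts(n, n, B)
      R <- crossprod(W, L)
      apply(R, 1, which.max)  # ties: lowest index = input order
    })
    trees <- lapply(winner, function(i) ev$fits[[i]]$tree)
  } else {
    winner <- integer(B)
    trees <- vector("list", B)
    idx_list <- with_seed(seed, lapply(seq_len(B), function(b)
      sample.int(n_sites(aln), n_sites(aln), replace = TRUE)))
    for (b in seq_len(B)) {
      sub <- new_alignment(aln$mat[, idx_list[[b]], drop = FALSE],
                           alphabet = aln$alphabet)
      evb <- evaluate_candidates(sub, model, candidate_trees)
      winner[b] <- evb$ranking[1]
      trees[[b]] <- evb$fits[[winner[b]]]$tree
    }
  }
  structure(list(trees = trees, winner = winner, lnl = ev$lnl, B = B,
                 seed = seed, mode = mode), class = "rs_bootstrap")
}
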