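# Likelihood evaluation and optimization for profile mixtures and
# per-site frequency (PMSF) models.
#
# Poisson exchangeabilities go through the closed-form C++ engine; general
# exchangeabilities build per-class transition matrices from the
# symmetrized eigendecomposition and use the dense C++ pruning path.

# uniform multinomial resampling: n x B matrix of site counts, each column
# summing to m (equivalent to rmultinom with uniform probabilities, but
# built by categorical sampling + tabulation, which is much faster)
resample_counts <- function(n, m, B) {
  idx <- sample.int(n, m * B, replace = TRUE)
  dim(idx) <- c(m, B)
  vapply(seq_len(B), function(b) tabulate(idx[, b], nbins = n),
         integer(n))
}

# align tree and alignment; returns compressed data for the engines
prep_data <- function(aln, tree, compress = TRUE) {
  tips <- tree$tip.label
  missing <- setdiff(tips, taxa_names(aln))
  if (length(missing)) stop("leaf without sequence: ", missing[1])
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.null(tree$edge.length)) stop("branch lengths required")
  sub <- aln$mat[tips, , drop = FALSE]
  m <- alignment_states_int(new_alignment(sub, alphabet = aln$alphabet))
  if (compress) {
    key <- apply(m, 2, paste, collapse = ",")
    first <- !duplicated(key)
    idx <- match(key, key[first])
    states <- m[, first, drop = FALSE]
    wpat <- as.vector(table(factor(idx, levels = seq_len(sum(first)))))
  } else {
    states <- m
    idx <- seq_len(ncol(m))
    wpat <- rep(1, ncol(m))
  }
  list(tree = tree, states = states, wpat = wpat, index = idx,
       edge = tree$edge, blen = tree$edge.length)
}

logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# per-class transition matrices for the dense path:
# classes are (profile k, gamma category g) pairs, flattened k-major
dense_P_list <- function(S, profiles, rates, blen) {
  K <- ncol(profiles); G <- length(rates)
  out <- vector("list", K * G)
  rootf <- matrix(0, nrow(profiles), K * G)
  for (k in seq_len(K)) {
    eg <- eigen_q(S, profiles[, k])
    for (g in seq_len(G)) {
      cidx <- (k - 1) * G + g
      out[[cidx]] <- lapply(blen, function(t) {
        P <- diag(eg$s)
        Ps <- eg$U %*% (exp(eg$lambda * t * rates[g]) * eg$Uinv)
        Ps[Ps < 0] <- 0
        P[eg$support, eg$support] <- Ps
        P
      })
      rootf[, cidx] <- profiles[, k]
    }
  }
  list(P = out, rootf = rootf)
}

# n_pat x K matrix of log L_ik (mean over gamma categories), any model type
class_loglik_matrix <- function(pd, model) {
  rates <- model$gamma$rates
  if (is_poisson_exch(model$exch)) {
    cpp_mix_classlog(pd$states, pd$edge, pd$blen, model$profiles, rates)
  } else {
    dp <- dense_P_list(model$exch, model$profiles, rates, pd$blen)
    cl <- cpp_dense_loglik(pd$states, pd$edge, dp$P, dp$rootf)
    K <- ncol(model$profiles); G <- length(rates)
    out <- matrix(0, nrow(cl), K)
    for (k in seq_len(K)) {
      block <- cl[, ((k - 1) * G + 1):(k * G), drop = FALSE]
      out[, k] <- logsumexp_rows(block) - log(G)
    }
    out
  }
}

pmsf_pattern_loglik <- function(pd, model) {
  rates <- model$gamma$rates
  pis <- model$site_freqs
  if (ncol(pis) != ncol(pd$states))
    stop("one site profile per alignment site required")
  if (is_poisson_exch(model$exch)) {
    cpp_pmsf_loglik(pd$states, pd$edge, pd$blen, pis, rates)
  } else {
    # per-site rate matrix: eigendecomposition per site (slow, exact)
    n <- ncol(pd$states)
    out <- numeric(n)
    for (i in seq_len(n)) {
      dp <- dense_P_list(model$exch, pis[, i, drop = FALSE], rates, pd$blen)
      cl <- cpp_dense_loglik(pd$states[, i, drop = FALSE], pd$edge, dp$P,
                             dp$rootf)
      out[i] <- logsumexp_rows(cl) - log(length(rates))
    }
    out
  }
}

#' Per-site log-likelihoods
#'
#' Felsenstein pruning under a profile mixture ([mixture_model()]) or a
#' per-site frequency model ([site_frequency_model()]).  Gaps and missing
#' states contribute all-ones conditional vectors, so an all-missing column
#' has site log-likelihood 0.
#'
#' @param aln an `rs_alignment` containing at least the tree's leaves.
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param model an `rs_mixture` or `rs_pmsf` model.
#' @return an `rs_sitelik` list: `site_lnl` (per original site), `lnl`
#'   (total), and for mixtures `class_log` (sites x K matrix of per-profile
#'   log-likelihoods, marginal over rate categories).
#' @export
site_log_likelihoods <- function(aln, tree, model) {
  if (inherits(model, "rs_pmsf")) {
    pd <- prep_data(aln, tree, compress = FALSE)
    site <- pmsf_pattern_loglik(pd, model)
    return(structure(list(site_lnl = site, lnl = sum(site),
                          class_log = NULL), class = "rs_sitelik"))
  }
  pd <- prep_data(aln, tree)
  cl <- class_loglik_matrix(pd, model)
  persite_pat <- logsumexp_rows(sweep(cl, 2, log(model$weights), "+"))
  site <- persite_pat[pd$index]
  structure(list(site_lnl = site, lnl = sum(site),
                 class_log = cl[pd$index, , drop = FALSE]),
            class = "rs_sitelik")
}

#' @export
print.rs_sitelik <- function(x, ...) {
  cat(sprintf("site log-likelihoods: %d sites, total lnL = %.4f\n",
              length(x$site_lnl), x$lnl))
  invisible(x)
}

# dense-path coordinate-wise branch optimization (general exchangeabilities)
optimize_blens_dense <- function(pd, model, tol, max_rounds,
                                 bounds = c(1e-8, 10)) {
  rates <- model$gamma$rates
  logw <- rep(log(model$weights / length(rates)), each = length(rates))
  blen <- pd$blen
  evalf <- function(bl) {
    dp <- dense_P_list(model$exch, model$profiles, rates, bl)
    cl <- cpp_dense_loglik(pd$states, pd$edge, dp$P, dp$rootf)
    sum(pd$wpat * logsumexp_rows(sweep(cl, 2, logw, "+")))
  }
  cur <- evalf(blen)
  trace <- cur
  for (round in seq_len(max_rounds)) {
    for (i in seq_along(blen)) {
      f <- function(t) {
        b <- blen; b[i] <- t; evalf(b)
      }
      blen[i] <- exp(optimize(function(u) f(exp(u)), interval = log(bounds),
                              maximum = TRUE, tol = 1e-4)$maximum)
    }
    new <- evalf(blen)
    if (new < cur) break
    gain <- new - cur
    cur <- new
    trace <- c(trace, cur)
    if (gain < tol) break
  }
  list(blen = blen, lnl = cur, trace = trace)
}

#' Optimize branch lengths
#'
#' Coordinate-wise maximization of the log-likelihood over branch lengths
#' (bounds `[1e-8, 10]`), iterated until the improvement per round drops
#' below `tol`.  The log-likelihood trace is non-decreasing; rounds that
#' fail to improve are rejected.
#'
#' @inheritParams site_log_likelihoods
#' @param tol stop when a round improves lnL by less than this (default 1e-4).
#' @param max_rounds maximum optimization rounds.
#' @param init initial length for branches lacking one (default 0.1).
#' @return an `rs_fit` list: `tree` (optimized lengths), `model`, `lnl`,
#'   `trace`.
#' @export
optimize_branch_lengths <- function(aln, tree, model, tol = 1e-4,
                                    max_rounds = 20, init = 0.1) {
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(init, nrow(tree$edge))
  tree$edge.length[tree$edge.length <= 0] <- init
  compress <- !inherits(model, "rs_pmsf")
  pd <- prep_data(aln, tree, compress = compress)
  rates <- model$gamma$rates
  if (inherits(model, "rs_pmsf")) {
    if (!is_poisson_exch(model$exch))
      stop("branch optimization under per-site frequencies requires Poisson exchangeabilities")
    res <- cpp_optimize_blens_pmsf(pd$states, pd$wpat, pd$edge, pd$blen,
                                   model$site_freqs, rates, max_rounds, tol,
                                   1e-8, 10)
  } else if (is_poisson_exch(model$exch)) {
    res <- cpp_optimize_blens_mix(pd$states, pd$wpat, pd$edge, pd$blen,
                                  model$profiles, model$weights, rates,
                                  max_rounds, tol, 1e-8, 10)
  } else {
    res <- optimize_blens_dense(pd, model, tol, max_rounds)
  }
  out <- pd$tree
  out$edge.length <- as.numeric(res$blen)
  structure(list(tree = out, model = model, lnl = res$lnl,
                 trace = as.numeric(res$trace)), class = "rs_fit")
}

#' @export
print.rs_fit <- function(x, ...) {
  cat(sprintf("rs_fit: lnL = %.4f%s%s\n", x$lnl,
              if (!is.null(x$bic)) sprintf(", BIC = %.2f", x$bic) else "",
              if (!is.null(x$model$name)) paste0(" [", x$model$name, "]") else ""))
  invisible(x)
}

#' Estimate the Gamma shape parameter
#'
#' One-dimensional bounded maximization of the log-likelihood over the
#' shape `alpha`, holding tree and all other parameters fixed.
#'
#' @inheritParams site_log_likelihoods
#' @param bounds search interval for alpha (default `c(0.02, 100)`).
#' @return the model with updated `gamma`, plus attributes `lnl` and `alpha`.
#' @export
estimate_alpha <- function(aln, tree, model, bounds = c(0.02, 100)) {
  if (model$gamma$K < 2) stop("alpha estimation needs >= 2 rate categories")
  compress <- !inherits(model, "rs_pmsf")
  pd <- prep_data(aln, tree, compress = compress)
  evalf <- function(loga) {
    m2 <- model
    m2$gamma <- discrete_gamma(exp(loga), model$gamma$K)
    if (inherits(model, "rs_pmsf")) sum(pd$wpat * pmsf_pattern_loglik(pd, m2))
    else {
      cl <- class_loglik_matrix(pd, m2)
      sum(pd$wpat * logsumexp_rows(sweep(cl, 2, log(m2$weights), "+")))
    }
  }
  opt <- optimize(evalf, interval = log(bounds), maximum = TRUE, tol = 1e-3)
  alpha <- exp(opt$maximum)
  # pin to bound when the optimum sits at the edge
  if (evalf(log(bounds[2])) >= opt$objective) alpha <- bounds[2]
  model$gamma <- discrete_gamma(alpha, model$gamma$K)
  attr(model, "lnl") <- max(opt$objective, evalf(log(alpha)))
  attr(model, "alpha") <- alpha
  model
}

#' Fit mixture weights by EM
#'
#' E-step responsibilities proportional to `w_k L_ik`; M-step sets each
#' weight to the mean responsibility.  The per-site per-profile likelihoods
#' do not depend on the weights, so they are computed once.  The lnL is
#' non-decreasing over sweeps (standard EM property).
#'
#' @inheritParams site_log_likelihoods
#' @param tol stop when a sweep gains less than this in lnL (default 1e-6).
#' @param max_sweeps cap on EM sweeps (default 500).
#' @return the model with fitted weights; attributes `lnl` and `trace`.
#' @export
fit_mixture_weights_em <- function(aln, tree, model, tol = 1e-6,
                                   max_sweeps = 500) {
  pd <- prep_data(aln, tree)
  cl <- class_loglik_matrix(pd, model)  # n_pat x K, independent of weights
  w <- model$weights
  n <- sum(pd$wpat)
  lnl <- function(w) sum(pd$wpat * logsumexp_rows(sweep(cl, 2, log(w), "+")))
  cur <- lnl(w)
  trace <- cur
  for (sweep_i in seq_len(max_sweeps)) {
    lw <- sweep(cl, 2, log(w), "+")
    r <- exp(lw - logsumexp_rows(lw))
    w <- colSums(pd$wpat * r) / n
    w <- w / sum(w)
    new <- lnl(w)
    gain <- new - cur
    cur <- new
    trace <- c(trace, cur)
    if (gain < tol) break
  }
  model$weights <- as.numeric(w)
  attr(model, "lnl") <- cur
  attr(model, "trace") <- trace
  model
}

#' Posterior-mean site frequencies (PMSF)
#'
#' For each site, the posterior-mean profile under the fitted mixture and
#' fixed tree: responsibilities proportional to `w_k L_ik`, site profile
#' `sum_k resp_ik pi_k`.  The result is used as a fixed per-site frequency
#' model; site profiles are not counted as free parameters downstream.
#'
#' @inheritParams site_log_likelihoods
#' @return an [site_frequency_model()] with the mixture's exchangeabilities
#'   and gamma setting.
#' @export
pmsf_site_frequencies <- function(aln, tree, model) {
  stopifnot(inherits(model, "rs_mixture"))
  pd <- prep_data(aln, tree)
  cl <- class_loglik_matrix(pd, model)
  lw <- sweep(cl, 2, log(model$weights), "+")
  r <- exp(lw - logsumexp_rows(lw))            # n_pat x K
  pis <- model$profiles %*% t(r[pd$index, , drop = FALSE])  # s x n_sites
  pis <- sweep(pis, 2, colSums(pis), "/")
  site_frequency_model(model$exch, pis, model$gamma,
                       name = paste0("PMSF(", model$name, ")"))
}

#' Approximately unbiased (AU) topology test
#'
#' Multiscale RELL bootstrap: at each scale factor `r` the per-site
#' log-likelihood columns are resampled `B` times at size `ceiling(r * n)`;
#' the bootstrap proportion `BP` of each hypothesis (ties split equally) is
#' converted to `z = qnorm(1 - BP)` and the signed distance `d` and
#' curvature `c` are obtained by weighted least squares of
#' `z ~ d * sqrt(r) + c / sqrt(r)`; finally `p_AU = 1 - pnorm(d - c)`.
#' Boundary proportions (0 or 1) get the continuity correction `0.5 / B`.
#'
#' @param site_lnl matrix of per-site log-likelihoods (sites x hypotheses).
#' @param scales scale factors (default `seq(0.5, 1.4, by = 0.1)`).
#' @param B bootstrap replicates per scale (default 1000).
#' @param seed integer seed.
#' @return an `rs_au` list: `p_au` (per hypothesis), `d`, `c`, `bp` (scales
#'   x hypotheses), `degenerate` (per-hypothesis flag: fewer than two
#'   informative scales), `scales`, `B`, `seed`.
#' @export
au_test <- function(site_lnl, scales = seq(0.5, 1.4, by = 0.1), B = 1000,
                    seed = 1) {
  site_lnl <- as.matrix(site_lnl)
  n <- nrow(site_lnl)
  H <- ncol(site_lnl)
  if (H < 2) stop("need at least 2 hypotheses")
  if (n < 10) stop("need at least 10 sites")
  hyp <- colnames(site_lnl)
  if (is.null(hyp)) hyp <- paste0("h", seq_len(H))
  bp <- matrix(0, length(scales), H, dimnames = list(NULL, hyp))
  with_seed(seed, {
    for (k in seq_along(scales)) {
      m <- ceiling(scales[k] * n)
      W <- resample_counts(n, m, B)
      R <- crossprod(W, site_lnl)              # B x H resampled lnL
      mx <- apply(R, 1, max)
      isw <- R >= mx - 1e-9                    # tie tolerance
      share <- isw / rowSums(isw)
      bp[k, ] <- colMeans(share)
    }
  })
  inform <- bp > 0 & bp < 1
  bpc <- pmin(pmax(bp, 0.5 / B), 1 - 0.5 / B)
  z <- qnorm(1 - bpc)
  d <- c_ <- p <- numeric(H)
  degen <- logical(H)
  sq <- sqrt(scales)
  for (h in seq_len(H)) {
    if (sum(inform[, h]) < 2) {
      degen[h] <- TRUE
      p[h] <- if (mean(bp[, h]) > 0.5) 1 else 0
      d[h] <- c_[h] <- NA_real_
      next
    }
    v <- B * dnorm(z[, h])^2 / (bpc[, h] * (1 - bpc[, h]))
    X <- cbind(sq, 1 / sq)
    fit <- lm.wfit(X, z[, h], w = v)
    d[h] <- fit$coefficients[1]
    c_[h] <- fit$coefficients[2]
    p[h] <- 1 - pnorm(d[h] - c_[h])
  }
  if (any(degen))
    warning("AU test degenerate for ", sum(degen),
            " hypothesis(es): fewer than 2 informative scales")
  structure(list(p_au = setNames(p, hyp), d = setNames(d, hyp),
                 c = setNames(c_, hyp), bp = bp, degenerate = degen,
                 scales = scales, B = B, seed = seed), class = "rs_au")
}

#' @export
print.rs_au <- function(x, ...) {
  cat("AU test p-values:\n")
  print(round(x$p_au, 4))
  invisible(x)
}

#' Export/import per-site log-likelihood matrices as TSV
#'
#' @param site_lnl sites x hypotheses matrix.
#' @param path file path.
#' @export
write_site_lnl_tsv <- function(site_lnl, path) {
  write.table(as.data.frame(site_lnl), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_lnl_tsv
#' @export
read_site_lnl_tsv <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t"))
}
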