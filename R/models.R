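#' Exchangeability matrices
#'
#' A symmetric non-negative matrix of relative substitution rates with zero
#' diagonal.  The built-in `"Poisson"` matrix has all off-diagonal entries
#' equal to one; together with a frequency profile it yields the F81-style
#' closed-form transition probabilities used by the fast likelihood path.
#'
#' @param S symmetric numeric matrix, zero diagonal, non-negative.
#' @param name tag (e.g. `"Poisson"`, `"LG"`, `"GTR-free"`).
#' @return the matrix with a `name` attribute, class `rs_exchangeability`.
#' @export
exchangeability_matrix <- function(S, name = "custom") {
  S <- as.matrix(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10))) stop("S must be symmetric")
  if (any(S < 0)) stop("S must be non-negative")
  if (any(diag(S) != 0)) stop("S must have zero diagonal")
  if (all(S[upper.tri(S)] == 0)) stop("S needs a positive off-diagonal entry")
  structure(S, name = name, class = c("rs_exchangeability", "matrix", "array"))
}

#' @rdname exchangeability_matrix
#' @param s alphabet size.
#' @export
poisson_exchangeabilities <- function(s = 20) {
  S <- matrix(1, s, s); diag(S) <- 0
  exchangeability_matrix(S, "Poisson")
}

is_poisson_exch <- function(S) {
  off <- S[upper.tri(S)]
  length(unique(off)) == 1 && off[1] > 0
}

#' Load exchangeabilities from a PAML-style .dat file
#'
#' Expects the lower-triangular block of `s - 1` rows (row `i` holding `i`
#' entries) followed, optionally, by a line of `s` equilibrium frequencies,
#' which are attached as attribute `freq`.
#'
#' @param path text file in PAML rate-matrix layout.
#' @param s alphabet size (default 20).
#' @param name model tag.
#' @export
load_exchangeabilities <- function(path, s = 20, name = basename(path)) {
  vals <- scan(path, what = numeric(), comment.char = "#", quiet = TRUE)
  ntri <- s * (s - 1) / 2
  if (length(vals) != ntri && length(vals) != ntri + s)
    stop(sprintf("expected %d (or %d) numbers, found %d",
                 ntri, ntri + s, length(vals)))
  if (any(vals < 0)) stop("negative entries in exchangeability file")
  S <- matrix(0, s, s)
  k <- 0
  for (i in 2:s) for (j in 1:(i - 1)) {
    k <- k + 1
    S[i, j] <- S[j, i] <- vals[k]
  }
  out <- exchangeability_matrix(S, name)
  if (length(vals) == ntri + s) {
    f <- vals[(ntri + 1):(ntri + s)]
    attr(out, "freq") <- f / sum(f)
  }
  out
}

#' Discrete Gamma rate categories
#'
#' `K` equal-probability categories with the category rate equal to the mean
#' of the Gamma(shape = alpha, rate = alpha) distribution within each
#' inter-quantile bin, renormalized so the mean rate is exactly one.
#'
#' @param alpha shape parameter (> 0).
#' @param K number of categories (>= 1).
#' @return list with `alpha`, `K`, and `rates` (strictly increasing).
#' @export
discrete_gamma <- function(alpha, K = 4) {
  if (alpha <= 0) stop("alpha must be positive")
  if (K < 1) stop("K must be >= 1")
  if (K == 1) return(list(alpha = alpha, K = 1L, rates = 1))
  q <- qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  # E[X; X in bin] via the incomplete-gamma identity for shape alpha + 1
  cum <- pgamma(q, shape = alpha + 1, rate = alpha)
  rates <- K * diff(cum)
  rates <- rates / mean(rates)
  list(alpha = alpha, K = as.integer(K), rates = rates)
}

validate_profile <- function(pi, s = NULL) {
  if (!is.null(s) && length(pi) != s) stop("profile has wrong length")
  if (any(pi < 0)) stop("profile entries must be non-negative")
  if (abs(sum(pi) - 1) > 1e-9) stop("profile must sum to 1")
  invisible(pi)
}

#' Profile mixture models
#'
#' A substitution model made of one exchangeability matrix, `K` frequency
#' profiles with mixture weights, and discrete Gamma rate categories.
#'
#' @param exch an [exchangeability_matrix()].
#' @param profiles states x K matrix of frequency profiles (columns on the
#'   simplex).
#' @param weights mixture weights summing to one.
#' @param gamma a [discrete_gamma()] list (use `discrete_gamma(alpha, 1)` for
#'   rate homogeneity).
#' @param name model tag used in reports.
#' @return an object of class `rs_mixture`.
#' @export
mixture_model <- function(exch, profiles, weights = NULL,
                          gamma = discrete_gamma(1, 4), name = "mixture") {
  profiles <- as.matrix(profiles)
  if (is.null(weights)) weights <- rep(1 / ncol(profiles), ncol(profiles))
  if (length(weights) != ncol(profiles)) stop("one weight per profile")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  apply(profiles, 2, validate_profile, s = nrow(profiles))
  if (nrow(profiles) != nrow(exch)) stop("profile/exchangeability size mismatch")
  structure(list(exch = exch, profiles = profiles, weights = weights,
                 gamma = gamma, name = name), class = "rs_mixture")
}

#' @export
print.rs_mixture <- function(x, ...) {
  cat(sprintf("rs_mixture '%s': %s exchangeabilities, K = %d profiles, %d gamma categories (alpha = %.3g)\n",
              x$name, attr(x$exch, "name"), ncol(x$profiles), x$gamma$K,
              x$gamma$alpha))
  invisible(x)
}

#' Per-site frequency (PMSF-style) models
#'
#' One frequency profile per alignment site, used as fixed input at
#' evaluation time (site profiles are not counted as free parameters).
#'
#' @param exch an [exchangeability_matrix()].
#' @param site_freqs states x n_sites matrix, one simplex column per site.
#' @param gamma a [discrete_gamma()] list.
#' @param name model tag.
#' @return an object of class `rs_pmsf`.
#' @export
site_frequency_model <- function(exch, site_freqs, gamma = discrete_gamma(1, 4),
                                 name = "PMSF") {
  site_freqs <- as.matrix(site_freqs)
  if (nrow(site_freqs) != nrow(exch)) stop("profile/exchangeability size mismatch")
  sums <- colSums(site_freqs)
  if (any(abs(sums - 1) > 1e-9) || any(site_freqs < 0))
    stop("each site profile must lie on the simplex")
  structure(list(exch = exch, site_freqs = site_freqs, gamma = gamma,
                 name = name), class = "rs_pmsf")
}

#' @export
print.rs_pmsf <- function(x, ...) {
  cat(sprintf("rs_pmsf '%s': %d site profiles, %d gamma categories (alpha = %.3g)\n",
              x$name, ncol(x$site_freqs), x$gamma$K, x$gamma$alpha))
  invisible(x)
}

#' Normalized rate matrix
#'
#' `Q[a,b] = S[a,b] * pi[b]` off the diagonal, diagonal set so rows sum to
#' zero, rescaled so the expected rate `-sum(pi * diag(Q))` equals one.
#' States with zero frequency are dropped from the support and reinserted
#' as zero rows/columns.
#'
#' @param S an [exchangeability_matrix()].
#' @param pi frequency vector.
#' @export
rate_matrix <- function(S, pi) {
  validate_profile(pi, nrow(S))
  s <- length(pi)
  sup <- pi > 0
  Q <- matrix(0, s, s)
  Ssub <- S[sup, sup, drop = FALSE]
  psub <- pi[sup]
  Qs <- Ssub * matrix(psub, sum(sup), sum(sup), byrow = TRUE)
  diag(Qs) <- 0
  diag(Qs) <- -rowSums(Qs)
  mu <- -sum(psub * diag(Qs))
  if (mu <= 0) stop("degenerate rate matrix")
  Q[sup, sup] <- Qs / mu
  Q
}

# eigendecomposition of Q via the symmetrized form diag(sqrt(pi)) Q diag(1/sqrt(pi))
eigen_q <- function(S, pi) {
  s <- length(pi)
  sup <- pi > 0
  Q <- rate_matrix(S, pi)
  sq <- sqrt(pi[sup])
  B <- diag(sq) %*% Q[sup, sup, drop = FALSE] %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(lambda = e$values,
       U = diag(1 / sq) %*% e$vectors,
       Uinv = t(e$vectors) %*% diag(sq),
       support = sup, s = s)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t)` computed from the symmetrized eigendecomposition.
#' Zero-frequency states get identity rows.
#'
#' @param S an [exchangeability_matrix()].
#' @param pi frequency vector.
#' @param t branch length (>= 0), in expected substitutions per site.
#' @export
transition_matrix <- function(S, pi, t) {
  if (t < 0) stop("negative branch length")
  eg <- eigen_q(S, pi)
  P <- diag(eg$s)
  Psub <- eg$U %*% (exp(eg$lambda * t) * eg$Uinv)
  Psub[Psub < 0] <- 0
  P[eg$support, eg$support] <- Psub / rowSums(Psub)
  P
}

#' Learn site-frequency profiles by k-means (CAT surrogate)
#'
#' Per-site residue frequency vectors (pseudocount-smoothed) are clustered
#' into `K` centroids by k-means with a fixed seed; centroids are
#' renormalized to profiles and initial weights are the cluster occupancies.
#' This is a deterministic finite-mixture stand-in for Dirichlet-process
#' profile inference; no equivalence with Bayesian CAT posteriors is
#' claimed.  Weights are typically refined afterwards with
#' [fit_mixture_weights_em()].
#'
#' @param aln an `rs_alignment`.
#' @param K number of profiles.
#' @param seed integer seed for the k-means initialization.
#' @param pseudocount smoothing count added per state to each site's counts
#'   before clustering.  The default `0.5 / n_taxa` keeps profiles off the
#'   simplex vertices while adding only half a phantom residue per site in
#'   total; a fixed large pseudocount would flatten the learned profiles
#'   and inflate the diversity of data simulated from them.
#' @param gamma a [discrete_gamma()] list attached to the returned model.
#' @return an `rs_mixture` with Poisson exchangeabilities.
#' @export
learn_profiles <- function(aln, K, seed = 1, pseudocount = NULL,
                           gamma = discrete_gamma(1, 4)) {
  if (K < 1) stop("K must be >= 1")
  if (is.null(pseudocount)) pseudocount <- 0.5 / n_taxa(aln)
  states <- alphabet_states(aln$alphabet)
  m <- alignment_states_int(aln)
  cnt <- vapply(seq_len(ncol(m)), function(j)
    tabulate(m[, j] + 1L, nbins = length(states)), numeric(length(states)))
  cnt <- cnt + pseudocount
  fr <- t(cnt) / colSums(cnt)  # sites x states
  if (K == 1) {
    prof <- matrix(colMeans(fr), ncol = 1)
    prof <- prof / sum(prof)
    return(mixture_model(poisson_exchangeabilities(length(states)), prof,
                         1, gamma, name = "CAT-surrogate-K1"))
  }
  ndist <- nrow(unique(fr))
  if (K > ndist) stop("K exceeds the number of distinct site frequency vectors")
  km <- with_seed(seed, kmeans(fr, centers = K, nstart = 5, iter.max = 50))
  prof <- t(km$centers)
  prof[prof < 0] <- 0
  prof <- sweep(prof, 2, colSums(prof), "/")
  w <- as.vector(table(factor(km$cluster, levels = seq_len(K)))) / nrow(fr)
  # deterministic order: decreasing weight, ties by first profile entry
  o <- order(-w, prof[1, ])
  mixture_model(poisson_exchangeabilities(length(states)),
                prof[, o, drop = FALSE], w[o], gamma,
                name = sprintf("CAT-surrogate-K%d", K))
}

#' Read a profile dictionary from TSV
#'
#' Layout: K rows x alphabet columns (optionally a leading `weight` column);
#' rows are renormalized to the simplex.  This is how externally estimated
#' fixed profile sets (C10-C60 style) are supplied; none are bundled.
#'
#' @param path TSV file.
#' @param s alphabet size.
#' @export
read_profile_dictionary <- function(path, s = 20) {
  d <- read.table(path, header = TRUE, sep = "\t")
  w <- NULL
  if ("weight" %in% names(d)) {
    w <- d$weight / sum(d$weight)
    d <- d[, setdiff(names(d), "weight"), drop = FALSE]
  }
  if (ncol(d) != s) stop("expected ", s, " state columns")
  prof <- t(as.matrix(d))
  prof <- sweep(prof, 2, colSums(prof), "/")
  list(profiles = prof, weights = w)
}
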