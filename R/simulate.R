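# Synthetic multi-signal data generator.
#
# The generator emulates the structure of a root-placement conflict study:
# an outgroup, a deep clade L, a focal taxon M whose attachment defines
# three competing root hypotheses, and remaining ingroup taxa.  Genes draw
# their true topology from the three hypotheses at chosen proportions and
# evolve under site-heterogeneous profile mixtures, optionally with a
# lineage-specific compositional bias on selected clades.

#' Taxon roles for the synthetic study
#'
#' @param n_outgroup,n_L,n_other counts per role (defaults 2, 2, 11: with
#'   the focal taxon, 16 taxa in total).
#' @return list with `outgroup`, `L`, `focal`, `other` label vectors.
#' @export
taxon_roles <- function(n_outgroup = 2, n_L = 2, n_other = 11) {
  stopifnot(n_outgroup >= 1, n_L >= 1, n_other >= 1)
  list(outgroup = paste0("OUT", seq_len(n_outgroup)),
       L = paste0("L", seq_len(n_L)),
       focal = "M",
       other = paste0("T", seq_len(n_other)))
}

# pectinate newick for a label vector; the returned string carries no
# stem length (the caller appends ":length")
clade_newick <- function(labs, bl_tip, bl_int) {
  if (length(labs) == 1) return(labs)
  rest <- clade_newick(labs[-1], bl_tip, bl_int)
  rest_len <- if (length(labs) == 2) bl_tip else bl_int
  sprintf("(%s:%g,%s:%g)", labs[1], bl_tip, rest, rest_len)
}

#' The three root-hypothesis trees
#'
#' Builds three topologies identical everywhere except the focal taxon's
#' attachment at the ingroup root: sister to the L clade (`LM_SISTER`),
#' sister to the non-L ingroup (`L_SISTER`), or sister to everything else
#' in the ingroup (`M_SISTER`).  The contentious branches around the
#' ingroup root are short (`bl_root`), mimicking a hard polytomy.
#'
#' @param roles a [taxon_roles()] list.
#' @param bl_tip terminal branch length (default 0.25).
#' @param bl_int internal branch length (default 0.1).
#' @param bl_root length of the hypothesis-defining branches at the
#'   ingroup root (default 0.05).
#' @return named list of three `ape::phylo` trees
#'   (`LM_SISTER`, `L_SISTER`, `M_SISTER`).
#' @export
make_hypothesis_trees <- function(roles, bl_tip = 0.25, bl_int = 0.1,
                                  bl_root = 0.05) {
  lenf <- function(labs) if (length(labs) == 1) bl_tip else bl_int
  out <- clade_newick(roles$outgroup, bl_tip, bl_int)
  L <- clade_newick(roles$L, bl_tip, bl_int)
  rest <- clade_newick(roles$other, bl_tip, bl_int)
  lL <- lenf(roles$L); lR <- lenf(roles$other)
  m <- sprintf("%s:%g", roles$focal, bl_tip)
  ing <- c(
    LM_SISTER = sprintf("((%s:%g,%s):%g,%s:%g)", L, lL, m, bl_root, rest, lR),
    L_SISTER  = sprintf("(%s:%g,(%s,%s:%g):%g)", L, lL, m, rest, lR, bl_root),
    M_SISTER  = sprintf("(%s,(%s:%g,%s:%g):%g)", m, L, lL, rest, lR, bl_root))
  lapply(ing, function(x)
    parse_newick(sprintf("(%s:%g,%s:%g);", out, lenf(roles$outgroup), x,
                         bl_int)))
}

#' Lineage-specific compositional bias
#'
#' On every branch strictly inside `clade` (plus the stem branch when
#' `include_stem`), state frequencies are replaced by
#' `(1 - lambda) * pi + lambda * tau` before transition probabilities are
#' built, emulating a compositional shift originating on the stem lineage.
#'
#' @param clade leaf labels of the biased clade.
#' @param tau target frequency profile (simplex vector).
#' @param lambda intensity in `[0, 1]`.
#' @param include_stem bias the stem branch too (default TRUE).
#' @export
lineage_bias <- function(clade, tau, lambda, include_stem = TRUE) {
  stopifnot(length(clade) >= 1, lambda >= 0, lambda <= 1)
  validate_profile(tau)
  structure(list(clade = clade, tau = tau, lambda = lambda,
                 include_stem = include_stem), class = "rs_bias")
}

# edges affected by a bias: child subtree within the clade
bias_edges <- function(tree, bias) {
  if (is.null(bias) || bias$lambda == 0)
    return(rep(FALSE, nrow(tree$edge)))
  sets <- node_clades(tree)
  vapply(seq_len(nrow(tree$edge)), function(i) {
    sub <- sets[[tree$edge[i, 2]]]
    inside <- all(sub %in% bias$clade)
    if (!inside) return(FALSE)
    if (length(sub) == length(bias$clade) && !bias$include_stem) return(FALSE)
    TRUE
  }, TRUE)
}

# draw one state per column from per-column simplex profiles (s x n);
# the cumulative sums are built row-wise so the whole draw is vectorized
sample_states_percol <- function(pis) {
  s <- nrow(pis)
  cum <- pis
  for (a in 2:s) cum[a, ] <- cum[a, ] + cum[a - 1, ]
  u <- runif(ncol(pis))
  1L + .colSums(cum < rep(u, each = s), s, ncol(pis))
}

#' Simulate an alignment along a tree
#'
#' Per site, a mixture class (profile) and a Gamma rate category are drawn
#' (for per-site frequency models each site uses its own profile); the root
#' state is drawn from the site's profile and evolved along each branch
#' with the model's transition probabilities.  Poisson exchangeabilities
#' use the closed-form transition sampling (copy with probability `e`,
#' redraw from the profile otherwise); other exchangeabilities build dense
#' transition matrices per branch and class.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param model `rs_mixture` or `rs_pmsf`.
#' @param L number of sites (for `rs_pmsf` this must equal the number of
#'   site profiles).
#' @param seed integer seed.
#' @param bias optional [lineage_bias()].
#' @return an `rs_alignment`; attributes `site_class` and `site_rate`
#'   record the generating assignments.
#' @export
simulate_alignment <- function(tree, model, L, seed, bias = NULL) {
  if (is.null(tree$edge.length)) stop("missing branch lengths")
  tree <- ape::reorder.phylo(tree, "postorder")
  pmsf <- inherits(model, "rs_pmsf")
  s <- nrow(if (pmsf) model$site_freqs else model$profiles)
  states <- alphabet_states(if (s == 20) "aa" else "dayhoff6")
  if (pmsf && ncol(model$site_freqs) != L)
    stop("per-site frequency model: L must match the number of site profiles")
  poisson <- is_poisson_exch(model$exch)
  baff <- if (is.null(bias)) rep(FALSE, nrow(tree$edge))
          else bias_edges(tree, bias)
  with_seed(seed, {
    G <- model$gamma$K
    rate_cat <- sample.int(G, L, replace = TRUE)
    rates <- model$gamma$rates[rate_cat]
    if (pmsf) {
      cls <- seq_len(L)
      pis <- model$site_freqs
    } else {
      cls <- sample.int(ncol(model$profiles), L, replace = TRUE,
                        prob = model$weights)
      pis <- model$profiles[, cls, drop = FALSE]
    }
    n_tip <- ape::Ntip(tree)
    n_node <- max(tree$edge)
    node_states <- matrix(0L, n_node, L)
    root <- tree$edge[nrow(tree$edge), 1]
    if (pmsf) {
      node_states[root, ] <- sample_states_percol(pis)
    } else {
      rs <- integer(L)
      for (k in unique(cls)) {
        ii <- which(cls == k)
        rs[ii] <- sample.int(s, length(ii), replace = TRUE,
                             prob = pis[, ii[1]])
      }
      node_states[root, ] <- rs
    }
    biased_pis <- NULL
    if (!is.null(bias) && bias$lambda > 0)
      biased_pis <- (1 - bias$lambda) * pis + bias$lambda * bias$tau
    for (i in rev(seq_len(nrow(tree$edge)))) {   # preorder
      par <- tree$edge[i, 1]; chi <- tree$edge[i, 2]
      t <- tree$edge.length[i]
      pp <- if (baff[i]) biased_pis else pis
      if (poisson) {
        beta <- 1 - colSums(pp^2)
        e <- exp(-t * rates / beta)
        keep <- runif(L) < e
        cs <- node_states[par, ]
        redraw <- which(!keep)
        if (length(redraw)) {
          if (pmsf) {
            cs[redraw] <- sample_states_percol(pp[, redraw, drop = FALSE])
          } else {
            # profiles are shared within a mixture class: vectorize per class
            for (k in unique(cls[redraw])) {
              ii <- redraw[cls[redraw] == k]
              cs[ii] <- sample.int(s, length(ii), replace = TRUE,
                                   prob = pp[, ii[1]])
            }
          }
        }
        node_states[chi, ] <- cs
      } else {
        # dense sampling; profiles are shared within a mixture class
        for (k in unique(cls)) {
          idx <- which(cls == k)
          pk <- pp[, idx[1]]
          for (g in unique(rate_cat[idx])) {
            ii <- idx[rate_cat[idx] == g]
            P <- transition_matrix(model$exch, pk,
                                   t * model$gamma$rates[g])
            for (a in unique(node_states[par, ii])) {
              jj <- ii[node_states[par, ii] == a]
              node_states[chi, jj] <- sample.int(s, length(jj),
                                                 replace = TRUE,
                                                 prob = P[a, ])
            }
          }
        }
      }
    }
    mat <- matrix(states[node_states[seq_len(n_tip), , drop = FALSE]],
                  n_tip, L, dimnames = list(tree$tip.label, NULL))
    aln <- new_alignment(mat, alphabet = if (s == 20) "aa" else "dayhoff6")
    attr(aln, "site_class") <- cls
    attr(aln, "site_rate") <- rate_cat
    aln
  })
}

#' Built-in site-heterogeneous profile set
#'
#' Five interpretable amino-acid profiles, each concentrating 80% of its
#' mass uniformly on one biochemical group (AGPST, DENQ, HKR, ILMV, FWY)
#' with the remaining 20% spread over all states.  These drive the default
#' synthetic study's across-site compositional heterogeneity.
#'
#' @param concentration mass placed on the group (default 0.8).
#' @return 20 x 5 profile matrix.
#' @export
default_profiles <- function(concentration = 0.8) {
  groups <- DAYHOFF6_GROUPS[1:5]
  prof <- vapply(groups, function(g) {
    v <- rep((1 - concentration) / 20, 20)
    v[match(g, AA_STATES)] <- v[match(g, AA_STATES)] + concentration / length(g)
    v
  }, numeric(20))
  rownames(prof) <- AA_STATES
  prof
}

#' Specification of a synthetic multi-signal gene set
#'
#' Defaults define the package's reference synthetic study: 16 taxa
#' (2 outgroup, 2 L, focal M, 11 others), 300 genes with lengths uniform
#' on 300-1200, per-gene Gamma shape uniform on 0.5-1.5, topology
#' proportions (LM, L, M) = (0.44, 0.31, 0.25) echoing a three-signal
#' census, and the built-in 5-profile mixture.
#'
#' @param n_genes number of genes.
#' @param proportions named numeric `(LM_SISTER, L_SISTER, M_SISTER)`
#'   summing to 1 (a 4th `OTHER`-style entry is not supported; OTHER arises
#'   from estimation error, not the generator).
#' @param len_range inclusive integer range of gene lengths.
#' @param alpha_range range of per-gene Gamma shapes.
#' @param roles a [taxon_roles()] list.
#' @param trees optional list of the three hypothesis trees (defaults to
#'   [make_hypothesis_trees()] on `roles`).
#' @param profiles states x K profile matrix (default [default_profiles()]).
#' @param weights mixture weights (default uniform).
#' @param gamma_categories discrete Gamma categories (default 4).
#' @param seed integer seed driving all gene-level randomness.
#' @export
gene_set_spec <- function(n_genes = 300,
                          proportions = c(LM_SISTER = 0.44, L_SISTER = 0.31,
                                          M_SISTER = 0.25),
                          len_range = c(300, 1200),
                          alpha_range = c(0.5, 1.5),
                          roles = taxon_roles(),
                          trees = NULL,
                          profiles = default_profiles(),
                          weights = NULL,
                          gamma_categories = 4,
                          seed = 1) {
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (is.null(trees)) trees <- make_hypothesis_trees(roles)
  stopifnot(setequal(names(trees), c("LM_SISTER", "L_SISTER", "M_SISTER")))
  if (is.null(weights)) weights <- rep(1 / ncol(profiles), ncol(profiles))
  structure(list(n_genes = n_genes, proportions = proportions,
                 len_range = len_range, alpha_range = alpha_range,
                 roles = roles, trees = trees, profiles = profiles,
                 weights = weights, gamma_categories = gamma_categories,
                 seed = seed), class = "rs_geneset_spec")
}

#' Generate a multi-signal gene set
#'
#' Per gene: the true topology label is multinomial on the spec
#' proportions, the length uniform on the length range, the Gamma shape
#' uniform on the shape range; the alignment is simulated on the labelled
#' hypothesis tree.  All randomness derives from the spec seed.
#'
#' @param spec a [gene_set_spec()].
#' @return list: `genes` (each with `aln`, `label`, `length`, `alpha`,
#'   `seed`), `truth` (data.frame: gene_id, label, length, alpha, seed),
#'   `spec`.
#' @export
generate_multisignal_geneset <- function(spec) {
  labels <- names(spec$proportions)
  draws <- with_seed(spec$seed, {
    lab <- sample(labels, spec$n_genes, replace = TRUE,
                  prob = spec$proportions)
    len <- sample(seq(spec$len_range[1], spec$len_range[2]), spec$n_genes,
                  replace = TRUE)
    alpha <- runif(spec$n_genes, spec$alpha_range[1], spec$alpha_range[2])
    gseed <- sample.int(.Machine$integer.max - 1L, spec$n_genes)
    list(lab = lab, len = len, alpha = alpha, gseed = gseed)
  })
  genes <- lapply(seq_len(spec$n_genes), function(i) {
    model <- mixture_model(poisson_exchangeabilities(nrow(spec$profiles)),
                           spec$profiles, spec$weights,
                           discrete_gamma(draws$alpha[i],
                                          spec$gamma_categories),
                           name = "generator")
    aln <- simulate_alignment(spec$trees[[draws$lab[i]]], model,
                              draws$len[i], seed = draws$gseed[i])
    list(aln = aln, label = draws$lab[i], length = draws$len[i],
         alpha = draws$alpha[i], seed = draws$gseed[i])
  })
  truth <- data.frame(gene_id = sprintf("g%04d", seq_len(spec$n_genes)),
                      label = draws$lab, length = draws$len,
                      alpha = draws$alpha, seed = draws$gseed,
                      stringsAsFactors = FALSE)
  list(genes = genes, truth = truth, spec = spec)
}

#' Independent parametric-bootstrap replicates
#'
#' `N` alignments of length `L` simulated under a fitted (tree, model)
#' pair, with per-replicate seeds derived deterministically from `seed`.
#'
#' @param tree fitted tree with branch lengths.
#' @param model `rs_mixture` or `rs_pmsf`.
#' @param L sites per replicate.
#' @param N number of replicates.
#' @param seed integer seed.
#' @return list of `rs_alignment` objects.
#' @export
parametric_replicates <- function(tree, model, L, N, seed) {
  stopifnot(N >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, N))
  lapply(seeds, function(sd) simulate_alignment(tree, model, L, seed = sd))
}
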