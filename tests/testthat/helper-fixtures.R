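# shared fixtures and independent oracles

aln_from_strings <- function(seqs, alphabet = "aa") {
  mat <- do.call(rbind, strsplit(unname(unlist(seqs)), ""))
  rownames(mat) <- names(seqs)
  new_alignment(mat, alphabet = alphabet)
}

random_profile <- function(s, conc = 1) {
  v <- rgamma(s, conc) + 1e-3
  v / sum(v)
}

# closed-form Poisson (F81-analogue) transition matrix
pois_P <- function(pi, t) {
  beta <- 1 - sum(pi^2)
  e <- exp(-t / beta)
  e * diag(length(pi)) + (1 - e) * matrix(pi, length(pi), length(pi),
                                          byrow = TRUE)
}

# brute-force site likelihood by exhaustive enumeration of internal states;
# Pfun(t) must return the transition matrix for one branch of length t
brute_site_lik <- function(tree, states_vec, pi, Pfun) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  n_node <- max(tree$edge)
  internal <- (n_tip + 1):n_node
  root <- tree$edge[nrow(tree$edge), 1]
  s <- length(pi)
  grid <- as.matrix(expand.grid(rep(list(1:s), length(internal))))
  Pe <- lapply(tree$edge.length, Pfun)
  lik <- 0
  for (r in seq_len(nrow(grid))) {
    assign_states <- integer(n_node)
    assign_states[internal] <- grid[r, ]
    p <- pi[assign_states[root]]
    for (i in seq_len(nrow(tree$edge))) {
      par <- tree$edge[i, 1]; chi <- tree$edge[i, 2]
      P <- Pe[[i]]
      pc <- if (chi <= n_tip) {
        st <- states_vec[chi]
        if (st < 0) 1 else P[assign_states[par], st + 1]
      } else P[assign_states[par], assign_states[chi]]
      p <- p * pc
    }
    lik <- lik + p
  }
  lik
}

# small default study used across tests (cheap genes)
tiny_spec <- function(n_genes = 12, seed = 11, len = c(150, 250),
                      proportions = c(LM_SISTER = 0.44, L_SISTER = 0.31,
                                      M_SISTER = 0.25)) {
  gene_set_spec(n_genes = n_genes, proportions = proportions,
                len_range = len, roles = taxon_roles(2, 2, 4), seed = seed)
}
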