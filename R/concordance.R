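# Gene and site concordance factors.
#
# For each internal branch of a reference tree, the gene concordance
# factor (gCF) is the percentage of decisive gene trees whose induced
# topology contains the branch; the site concordance factor (sCF) is the
# mean, over sampled quartets around the branch, of the fraction of
# decisive sites (exactly two states pairing the four taxa 2+2) that pair
# the branch's own sides together.

# the four adjacent subtree tip sets around each internal branch of a
# (binary at that branch) reference tree
branch_quadripartitions <- function(ref_tree) {
  tree <- ref_tree
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  sets <- node_clades(tree)
  universe <- sort(tree$tip.label)
  out <- list()
  for (i in seq_len(nrow(tree$edge))) {
    v <- tree$edge[i, 2]
    if (v <= n_tip) next
    u <- tree$edge[i, 1]
    kids_v <- tree$edge[tree$edge[, 1] == v, 2]
    if (length(kids_v) != 2) stop("reference not binary at an internal branch")
    A <- sets[[kids_v[1]]]; B <- sets[[kids_v[2]]]
    others_u <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
    if (length(others_u) >= 1) {
      C <- sets[[others_u[1]]]
      D <- setdiff(universe, c(A, B, C))
    } else {
      next
    }
    if (!length(C) || !length(D)) next
    out[[length(out) + 1]] <- list(A = A, B = B, C = C, D = D,
                                   key = split_key(c(A, B), universe))
  }
  out
}

#' Gene concordance factors
#'
#' A gene tree is decisive for a branch when it contains at least one
#' taxon from each of the branch's four adjacent subtrees; it is
#' concordant when its induced bipartition on those taxa matches the
#' branch.  Gene trees lacking decisiveness are excluded from both
#' numerator and denominator; branch lengths and gene order are
#' irrelevant.
#'
#' @param ref_tree reference tree (binary at the queried branches).
#' @param gene_trees list of gene trees with leaf sets within the
#'   reference leaf set.
#' @return `rs_concordance` data.frame: one row per internal branch with
#'   `split`, `gCF`, `gCF_N` (decisive genes), `gDF1`, `gDF2` (the two
#'   alternative pairings).
#' @export
gene_concordance <- function(ref_tree, gene_trees) {
  quads <- branch_quadripartitions(ref_tree)
  ref_tips <- ref_tree$tip.label
  for (gt in gene_trees)
    if (!all(gt$tip.label %in% ref_tips))
      stop("gene tree contains taxa absent from the reference")
  gene_splits <- lapply(gene_trees, function(gt) {
    if (ape::Ntip(gt) < 4) character(0) else bipartitions(gt)
  })
  gene_tips <- lapply(gene_trees, function(gt) gt$tip.label)
  rows <- lapply(quads, function(q) {
    conc <- df1 <- df2 <- dec <- 0
    for (gi in seq_along(gene_trees)) {
      g <- gene_tips[[gi]]
      A <- intersect(q$A, g); B <- intersect(q$B, g)
      C <- intersect(q$C, g); D <- intersect(q$D, g)
      if (!length(A) || !length(B) || !length(C) || !length(D)) next
      dec <- dec + 1
      guni <- sort(g)
      has <- function(side) {
        if (length(side) <= 1 || length(side) >= length(g) - 1) return(TRUE)
        split_key(side, guni) %in% gene_splits[[gi]]
      }
      if (has(c(A, B))) conc <- conc + 1
      else if (has(c(A, C))) df1 <- df1 + 1
      else if (has(c(A, D))) df2 <- df2 + 1
    }
    data.frame(split = q$key,
               gCF = if (dec) 100 * conc / dec else NA_real_,
               gCF_N = dec, gDF1 = if (dec) 100 * df1 / dec else NA_real_,
               gDF2 = if (dec) 100 * df2 / dec else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("rs_concordance", "data.frame"))
}

#' Site concordance factors by quartet sampling
#'
#' For each internal branch, `n_quartets` quartets are drawn (one taxon
#' uniformly from each adjacent subtree; without replacement over distinct
#' quartets until exhausted, then with replacement).  A site is decisive
#' for a quartet when all four taxa carry residues (no gaps/missing) with
#' exactly two distinct states pairing 2+2; it is concordant when the
#' pairing matches the branch.  Quartets with zero decisive sites are
#' skipped; a branch with no decisive quartet reports `NA`.
#'
#' @param ref_tree reference tree.
#' @param aln alignment containing all reference leaves.
#' @param n_quartets quartets per branch (default 100).
#' @param seed integer seed.
#' @return `rs_concordance` data.frame: `split`, `sCF`, `sCF_N` (mean
#'   decisive sites per quartet), `sDF1`, `sDF2`.
#' @export
site_concordance <- function(ref_tree, aln, n_quartets = 100, seed = 1) {
  stopifnot(all(ref_tree$tip.label %in% taxa_names(aln)))
  quads <- branch_quadripartitions(ref_tree)
  m <- alignment_states_int(aln)
  rows <- with_seed(seed, lapply(quads, function(q) {
    nA <- length(q$A); nB <- length(q$B)
    nC <- length(q$C); nD <- length(q$D)
    ndist <- nA * nB * nC * nD
    if (ndist == 0) stop("branch with an empty adjacent subtree")
    ndraw <- n_quartets
    if (ndist <= ndraw) {
      combos <- expand.grid(a = q$A, b = q$B, c = q$C, d = q$D,
                            stringsAsFactors = FALSE)
      extra <- ndraw - ndist
      idx <- c(seq_len(ndist),
               if (extra > 0) sample.int(ndist, extra, replace = TRUE))
      combos <- combos[idx, , drop = FALSE]
    } else {
      # sample distinct quartets without replacement
      idx <- sample.int(ndist, ndraw, replace = FALSE)
      combos <- data.frame(
        a = q$A[((idx - 1) %% nA) + 1],
        b = q$B[(((idx - 1) %/% nA) %% nB) + 1],
        c = q$C[(((idx - 1) %/% (nA * nB)) %% nC) + 1],
        d = q$D[(((idx - 1) %/% (nA * nB * nC)) %% nD) + 1],
        stringsAsFactors = FALSE)
    }
    cf <- df1 <- df2 <- nsites <- numeric(0)
    for (r in seq_len(nrow(combos))) {
      sa <- m[combos$a[r], ]; sb <- m[combos$b[r], ]
      sc <- m[combos$c[r], ]; sd_ <- m[combos$d[r], ]
      ok <- sa >= 0 & sb >= 0 & sc >= 0 & sd_ >= 0
      p_ab <- ok & sa == sb & sc == sd_ & sa != sc
      p_ac <- ok & sa == sc & sb == sd_ & sa != sb
      p_ad <- ok & sa == sd_ & sb == sc & sa != sb
      dec <- sum(p_ab) + sum(p_ac) + sum(p_ad)
      if (dec == 0) next
      cf <- c(cf, sum(p_ab) / dec)
      df1 <- c(df1, sum(p_ac) / dec)
      df2 <- c(df2, sum(p_ad) / dec)
      nsites <- c(nsites, dec)
    }
    data.frame(split = q$key,
               sCF = if (length(cf)) 100 * mean(cf) else NA_real_,
               sCF_N = if (length(nsites)) mean(nsites) else 0,
               sDF1 = if (length(df1)) 100 * mean(df1) else NA_real_,
               sDF2 = if (length(df2)) 100 * mean(df2) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(do.call(rbind, rows), class = c("rs_concordance", "data.frame"))
}

#' Combine gene- and site-concordance tables and export as TSV
#'
#' @param gcf table from [gene_concordance()].
#' @param scf table from [site_concordance()].
#' @param path optional TSV output path.
#' @return merged data.frame keyed by branch split.
#' @export
concordance_table <- function(gcf, scf, path = NULL) {
  tab <- merge(as.data.frame(gcf), as.data.frame(scf), by = "split",
               all = TRUE)
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}
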