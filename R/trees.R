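#' Parse and write Newick trees
#'
#' Thin wrappers over ape's Newick reader/writer with stricter error
#' behaviour: malformed strings and duplicate leaf labels are errors.
#'
#' @param text a Newick string.
#' @return an `ape::phylo` tree.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                 error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) stop("malformed Newick string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ", tr$tip.label[duplicated(tr$tip.label)][1])
  tr
}

#' @rdname parse_newick
#' @param tree an `ape::phylo` tree.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

# canonical key for the bipartition induced by a tip set within a universe:
# the smaller side (ties broken lexicographically on the joined string),
# sorted and comma-joined.
split_key <- function(side, universe) {
  side <- sort(side)
  other <- sort(setdiff(universe, side))
  a <- paste(side, collapse = ",")
  b <- paste(other, collapse = ",")
  if (length(side) < length(other)) return(a)
  if (length(other) < length(side)) return(b)
  if (a <= b) a else b
}

# tip-label sets descending from each internal node (including root)
node_clades <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(tree)
  n_node <- max(tree$edge)
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]; chi <- tree$edge[i, 2]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  sets
}

#' Non-trivial bipartitions of a tree
#'
#' One entry per internal branch; trivial (single-leaf) splits are
#' excluded.  Each bipartition is a canonical string key: the smaller side,
#' sorted and comma-joined (ties broken lexicographically).
#'
#' @param tree an `ape::phylo` tree (>= 4 leaves).
#' @return character vector of canonical split keys.
#' @export
bipartitions <- function(tree) {
  n_tip <- ape::Ntip(tree)
  if (n_tip < 4) stop("need at least 4 leaves")
  sets <- node_clades(tree)
  universe <- sort(tree$tip.label)
  keys <- character(0)
  root <- n_tip + 1L
  for (nd in (n_tip + 1L):max(tree$edge)) {
    if (nd == root) next
    side <- sets[[nd]]
    if (length(side) <= 1 || length(side) >= n_tip - 1) next
    keys <- c(keys, split_key(side, universe))
  }
  unique(keys)
}

#' Root a tree on an outgroup
#'
#' Places the root on the branch separating the outgroup from the ingroup.
#' If no single branch separates them (outgroup not monophyletic on the
#' unrooted tree) an error is raised carrying the offending split.
#'
#' @param tree an `ape::phylo` tree.
#' @param outgroup_taxa non-empty proper subset of the leaf labels.
#' @return a rooted `ape::phylo` tree.
#' @export
root_on_outgroup <- function(tree, outgroup_taxa) {
  tips <- tree$tip.label
  if (!length(outgroup_taxa) || !all(outgroup_taxa %in% tips) ||
      length(outgroup_taxa) >= length(tips))
    stop("outgroup must be a non-empty proper subset of the leaves")
  if (length(outgroup_taxa) > 1) {
    key <- split_key(outgroup_taxa, sort(tips))
    if (!(key %in% bipartitions(tree)))
      stop("outgroup not separable by a single branch: ", key)
  }
  ape::root(tree, outgroup = outgroup_taxa, resolve.root = TRUE)
}

#' Classify the focal taxon's placement into the three root hypotheses
#'
#' After rooting on the outgroup, the first split of the ingroup determines
#' the label: `L_SISTER` when clade L is sister to all other ingroup taxa,
#' `M_SISTER` when the focal taxon is, `LM_SISTER` when the clade (L, focal)
#' is (requiring L monophyly within it), `OTHER` otherwise (including
#' unresolved ingroup-root polytomies and unrootable trees).
#'
#' @param tree an `ape::phylo` tree.
#' @param outgroup_taxa outgroup leaf labels.
#' @param L_taxa labels of the L clade role.
#' @param focal label of the focal taxon role.
#' @return list with `label` (one of `L_SISTER`, `M_SISTER`, `LM_SISTER`,
#'   `OTHER`), `L_monophyletic`, `ants_monophyletic` (TRUE when the
#'   outgroup is separable so the ingroup forms a clade).
#' @export
classify_focal_placement <- function(tree, outgroup_taxa, L_taxa, focal) {
  tips <- tree$tip.label
  if (focal %in% c(L_taxa, outgroup_taxa)) stop("focal must be outside L and outgroup")
  ingroup <- setdiff(tips, outgroup_taxa)
  rest <- setdiff(ingroup, c(L_taxa, focal))
  if (!length(rest))
    stop("ingroup must contain at least one taxon outside L and the focal taxon")
  rooted <- tryCatch(root_on_outgroup(tree, outgroup_taxa),
                     error = function(e) NULL)
  if (is.null(rooted))
    return(list(label = "OTHER", L_monophyletic = NA,
                ants_monophyletic = FALSE))
  sets <- node_clades(rooted)
  n_tip <- ape::Ntip(rooted)
  internal_sets <- sets[(n_tip + 1L):max(rooted$edge)]
  setmatch <- function(x, y) length(x) == length(y) && setequal(x, y)
  L_mono <- length(L_taxa) == 1 ||
    any(vapply(internal_sets, setmatch, TRUE, y = L_taxa))
  # ingroup root node = smallest clade containing the whole ingroup
  cand <- which(vapply(internal_sets, function(s) all(ingroup %in% s), TRUE))
  sizes <- vapply(internal_sets[cand], length, 0L)
  ignode <- cand[which.min(sizes)] + n_tip
  kids <- rooted$edge[rooted$edge[, 1] == ignode, 2]
  parts <- lapply(kids, function(k) sets[[k]])
  if (length(parts) != 2)
    return(list(label = "OTHER", L_monophyletic = L_mono,
                ants_monophyletic = TRUE))
  S <- parts[[1]]
  lab <- "OTHER"
  if (setmatch(S, L_taxa) || setmatch(S, setdiff(ingroup, L_taxa))) {
    lab <- "L_SISTER"
    if (!L_mono) lab <- "OTHER"  # unreachable, kept for clarity
  } else if (setmatch(S, focal) || setmatch(S, setdiff(ingroup, focal))) {
    lab <- "M_SISTER"
  } else if (setmatch(S, c(L_taxa, focal)) ||
             setmatch(S, setdiff(ingroup, c(L_taxa, focal)))) {
    lab <- if (L_mono) "LM_SISTER" else "OTHER"
  }
  list(label = lab, L_monophyletic = L_mono, ants_monophyletic = TRUE)
}

# TRUE when two canonical splits over the same universe are compatible
splits_compatible <- function(a, b, universe) {
  A <- strsplit(a, ",", fixed = TRUE)[[1]]
  B <- strsplit(b, ",", fixed = TRUE)[[1]]
  Ac <- setdiff(universe, A)
  Bc <- setdiff(universe, B)
  !length(intersect(A, B)) || !length(intersect(A, Bc)) ||
    !length(intersect(Ac, B)) || !length(intersect(Ac, Bc))
}

# build a phylo tree from a set of pairwise-compatible canonical splits,
# annotating internal nodes with `labels` (same order as splits).
# Splits are turned into clades relative to a reference taxon; compatible
# clades nest, so each clade's parent is the smallest strictly containing
# clade (or the root).
tree_from_splits <- function(splits, labels, universe) {
  ref <- universe[1]
  clades <- lapply(splits, function(k) {
    side <- strsplit(k, ",", fixed = TRUE)[[1]]
    if (ref %in% side) setdiff(universe, side) else side
  })
  nc <- length(clades)
  sizes <- vapply(clades, length, 0L)
  parent <- integer(nc)
  for (i in seq_len(nc)) {
    best <- 0L; bestsize <- Inf
    for (j in seq_len(nc)) {
      if (j != i && sizes[j] > sizes[i] && sizes[j] < bestsize &&
          all(clades[[i]] %in% clades[[j]])) {
        best <- j; bestsize <- sizes[j]
      }
    }
    parent[i] <- best
  }
  emit <- function(id) {
    members <- if (id == 0L) universe else clades[[id]]
    kids <- which(parent == id)
    covered <- unlist(lapply(kids, function(k) clades[[k]]))
    tips <- setdiff(members, covered)
    inner <- paste(c(vapply(kids, emit, ""), tips), collapse = ",")
    if (id == 0L) paste0("(", inner, ");")
    else paste0("(", inner, ")", labels[id])
  }
  ape::read.tree(text = emit(0L))
}

#' Extended majority-rule consensus with pooled support
#'
#' Bipartition frequencies are computed over the pooled input trees; the
#' consensus keeps every split above 50% and then greedily adds compatible
#' splits with support at least `min_support`, in decreasing frequency
#' (ties broken lexicographically on the canonical split key).  Per-branch
#' support is `100 * frequency`; when the inputs pool bootstrap trees
#' across jackknife replicates this is the cumulative bootstrap support
#' (CUBS) summary.
#'
#' @param trees list of `ape::phylo` trees on identical leaf sets.
#' @param min_support minimum support (percent) for greedy additions
#'   (default 0 = extended majority rule).
#' @return an `rs_consensus` list: `tree` (with supports as node labels),
#'   `support` data.frame (split, support), `n_trees`.
#' @export
majority_consensus <- function(trees, min_support = 0) {
  stopifnot(length(trees) >= 1)
  universe <- sort(trees[[1]]$tip.label)
  for (tr in trees)
    if (!setequal(tr$tip.label, universe)) stop("leaf-set mismatch")
  n <- length(trees)
  tab <- table(unlist(lapply(trees, bipartitions)))
  freq <- 100 * as.vector(tab) / n
  keys <- names(tab)
  o <- order(-freq, keys)
  keys <- keys[o]; freq <- freq[o]
  chosen <- character(0); chosen_freq <- numeric(0)
  for (i in seq_along(keys)) {
    if (freq[i] <= 50 && freq[i] < min_support) next
    ok <- all(vapply(chosen, splits_compatible, TRUE, b = keys[i],
                     universe = universe))
    if (ok) {
      chosen <- c(chosen, keys[i])
      chosen_freq <- c(chosen_freq, freq[i])
    }
  }
  tree <- tree_from_splits(chosen, sprintf("%.6g", chosen_freq), universe)
  structure(list(tree = tree,
                 support = data.frame(split = chosen, support = chosen_freq,
                                      stringsAsFactors = FALSE),
                 n_trees = n), class = "rs_consensus")
}

#' @export
print.rs_consensus <- function(x, ...) {
  cat(sprintf("consensus of %d pooled trees, %d supported splits (min %.1f%%, max %.1f%%)\n",
              x$n_trees, nrow(x$support),
              if (nrow(x$support)) min(x$support$support) else NA,
              if (nrow(x$support)) max(x$support$support) else NA))
  invisible(x)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' bipartition sets.
#'
#' @param t1,t2 `ape::phylo` trees on the same leaf set.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf-set mismatch")
  b1 <- bipartitions(t1); b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Support of one split among a set of trees
#'
#' @param trees list of trees on one leaf set.
#' @param side leaf labels of one side of the split.
#' @return percentage of trees containing the split.
#' @export
split_support <- function(trees, side) {
  universe <- sort(trees[[1]]$tip.label)
  key <- split_key(side, universe)
  100 * mean(vapply(trees, function(tr) key %in% bipartitions(tr), TRUE))
}
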