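# Per-gene signal census: classify the focal taxon's placement across
# many gene trees, count support for the three root hypotheses, test the
# counts by chi-squared, build single-signal concatenations and screen
# genes by AU decisiveness.

#' Chi-squared goodness-of-fit test
#'
#' `statistic = sum((O - E)^2 / E)` with `df = categories - 1`; `expected`
#' defaults to uniform, and is rescaled to the observed total.
#'
#' @param counts non-negative integer counts.
#' @param expected optional expected counts (rescaled to `sum(counts)`).
#' @return list: `statistic`, `df`, `p`.
#' @export
chisq_gof <- function(counts, expected = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(expected)) expected <- rep(1, length(counts))
  if (length(expected) != length(counts)) stop("length mismatch")
  expected <- expected / sum(expected) * sum(counts)
  if (any(expected == 0)) stop("zero expected count")
  statistic <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  list(statistic = statistic, df = df,
       p = pchisq(statistic, df, lower.tail = FALSE))
}

# Poisson-corrected pairwise distances (JC-style for s states)
ml_distance <- function(aln) {
  m <- alignment_states_int(aln)
  s <- length(alphabet_states(aln$alphabet))
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(taxa_names(aln), taxa_names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] >= 0 & m[j, ] >= 0
    p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
    arg <- 1 - p * s / (s - 1)
    d <- if (arg <= 0.01) -log(0.01) * (s - 1) / s
         else -log(arg) * (s - 1) / s
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbour-joining starting tree
#'
#' NJ on Poisson-corrected distances; negative branch lengths are clamped
#' to a small positive value.
#'
#' @param aln an `rs_alignment`.
#' @export
nj_tree <- function(aln) {
  tr <- ape::nj(ml_distance(aln))
  tr$edge.length[tr$edge.length < 1e-6] <- 1e-6
  tr
}

# does a gene pass the retention rules for the census?
retention_check <- function(aln, roles) {
  tx <- taxa_names(aln)
  if (!(roles$focal %in% tx)) return("missing focal taxon")
  if (!any(roles$L %in% tx)) return("missing L taxa")
  if (!any(roles$outgroup %in% tx)) return("missing outgroup")
  if (!any(roles$other %in% tx)) return("missing other ingroup taxa")
  NULL
}

#' Run the per-gene signal census
#'
#' For each retained gene: select a model from the menu by BIC (skipped if
#' the menu has one entry), infer the gene tree (greedy NNI from a
#' neighbour-joining start, or NJ alone, or accept a provided tree),
#' classify the focal taxon's placement into the three root hypotheses,
#' and optionally run a per-gene AU test over the three hypothesis
#' topologies.  Counts are tested by chi-squared both among resolved genes
#' and against the total (the latter flagged experimental).
#'
#' @param genes list of `rs_alignment` objects, or of lists with an `aln`
#'   element (as produced by [generate_multisignal_geneset()]).
#' @param roles a [taxon_roles()] list.
#' @param model_menu list of [model_spec()]; default single Poisson+F+G.
#' @param tree_method `"nni"` (default), `"nj"`, or `"provided"` (then
#'   `gene_trees` must be given).
#' @param gene_trees optional list of trees, one per gene.
#' @param with_au run the per-gene AU test (default FALSE).
#' @param hypothesis_trees the three labelled topologies (default
#'   [make_hypothesis_trees()] on `roles`).
#' @param alpha significance level for AU decisiveness (default 0.05,
#'   unadjusted: the per-gene screen).
#' @param au_B,au_scales AU test settings.
#' @param seed integer seed for the AU resampling.
#' @return an `rs_census` list: `per_gene` (data.frame), `counts`,
#'   `proportions` (among resolved), `chisq_resolved`, `chisq_total`
#'   (experimental), `n_L_paraphyletic`, `excluded`, `roles`.
#' @export
run_census <- function(genes, roles, model_menu = NULL,
                       tree_method = c("nni", "nj", "provided"),
                       gene_trees = NULL, with_au = FALSE,
                       hypothesis_trees = NULL, alpha = 0.05,
                       au_B = 1000, au_scales = seq(0.5, 1.4, by = 0.1),
                       seed = 1) {
  tree_method <- match.arg(tree_method)
  if (tree_method == "provided" && is.null(gene_trees))
    stop("tree_method 'provided' requires gene_trees")
  if (is.null(model_menu))
    model_menu <- list(model_spec("Poisson+F+G"))
  if (is.null(hypothesis_trees))
    hypothesis_trees <- make_hypothesis_trees(roles)
  hyp_names <- c("LM_SISTER", "L_SISTER", "M_SISTER")

  alns <- lapply(genes, function(g) if (inherits(g, "rs_alignment")) g else g$aln)
  n_genes <- length(alns)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))

  excluded <- data.frame(gene_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  rows <- list()
  au_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_genes))
  for (i in seq_len(n_genes)) {
    aln <- alns[[i]]
    reason <- retention_check(aln, roles)
    if (!is.null(reason)) {
      excluded <- rbind(excluded,
                        data.frame(gene_id = gene_ids[i], reason = reason))
      next
    }
    if (tree_method == "provided") {
      gtree <- gene_trees[[i]]
      best_name <- NA_character_
      fit <- NULL
    } else {
      start <- nj_tree(aln)
      if (length(model_menu) > 1) {
        sel <- select_model_bic(aln, start, model_menu)
        fit0 <- sel$best
      } else {
        fit0 <- fit_model(aln, start, model_menu[[1]])
      }
      best_name <- fit0$spec$name
      if (tree_method == "nni") {
        fit <- nni_search(aln, fit0$model, fit0$tree)
        gtree <- fit$tree
      } else {
        fit <- fit0
        gtree <- fit0$tree
      }
    }
    cls <- classify_focal_placement(gtree,
                                    intersect(roles$outgroup, taxa_names(aln)),
                                    intersect(roles$L, taxa_names(aln)),
                                    roles$focal)
    au_p <- rep(NA_real_, 3)
    if (with_au && !is.null(fit)) {
      # hypothesis trees restricted to the gene's taxa
      Lmat <- vapply(hyp_names, function(h) {
        ht <- ape::keep.tip(hypothesis_trees[[h]], taxa_names(aln))
        f <- optimize_branch_lengths(aln, ht, fit$model)
        site_log_likelihoods(aln, f$tree, fit$model)$site_lnl
      }, numeric(n_sites(aln)))
      au <- au_test(Lmat, scales = au_scales, B = au_B, seed = au_seeds[i])
      au_p <- au$p_au
    }
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = gene_ids[i], label = cls$label,
      L_monophyletic = isTRUE(cls$L_monophyletic),
      ants_monophyletic = isTRUE(cls$ants_monophyletic),
      model = best_name,
      p_LM = au_p[1], p_L = au_p[2], p_M = au_p[3],
      stringsAsFactors = FALSE)
  }
  per_gene <- if (length(rows)) do.call(rbind, rows)
              else stop("no valid genes")
  counts <- table(factor(per_gene$label,
                         levels = c(hyp_names, "OTHER")))
  resolved <- counts[hyp_names]
  chisq_resolved <- chisq_gof(as.numeric(resolved))
  chisq_total <- chisq_gof(as.numeric(resolved),
                           expected = rep(nrow(per_gene) / 3, 3))
  structure(list(per_gene = per_gene,
                 counts = counts,
                 proportions = as.numeric(resolved) / sum(resolved),
                 chisq_resolved = chisq_resolved,
                 chisq_total = chisq_total,
                 n_L_paraphyletic = sum(!per_gene$L_monophyletic,
                                        na.rm = TRUE),
                 excluded = excluded, roles = roles,
                 hypothesis_trees = hypothesis_trees),
            class = "rs_census")
}

#' @export
print.rs_census <- function(x, ...) {
  cat("signal census:\n")
  print(x$counts)
  cat(sprintf("resolved proportions: %s\n",
              paste(sprintf("%.1f%%", 100 * x$proportions), collapse = " / ")))
  cat(sprintf("chi-squared (resolved): %.3f, df = %d, p = %.3g\n",
              x$chisq_resolved$statistic, x$chisq_resolved$df,
              x$chisq_resolved$p))
  if (nrow(x$excluded)) cat(sprintf("%d genes excluded\n", nrow(x$excluded)))
  invisible(x)
}

#' Build single-signal concatenations
#'
#' Concatenates genes grouped by census label; `OTHER` genes are excluded
#' from the three main outputs.  Empty label groups are omitted with a
#' warning.
#'
#' @param census an `rs_census`.
#' @param genes the gene list used for the census (same order).
#' @return named list of concatenated `rs_alignment`s (subset of
#'   `LM_SISTER`, `L_SISTER`, `M_SISTER`).
#' @export
build_single_signal_datasets <- function(census, genes) {
  alns <- lapply(genes, function(g) if (inherits(g, "rs_alignment")) g else g$aln)
  gene_ids <- sprintf("g%04d", seq_along(alns))
  out <- list()
  for (h in c("LM_SISTER", "L_SISTER", "M_SISTER")) {
    ids <- census$per_gene$gene_id[census$per_gene$label == h]
    if (!length(ids)) {
      warning("no genes labelled ", h, "; output omitted")
      next
    }
    sel <- match(ids, gene_ids)
    out[[h]] <- concatenate_alignments(alns[sel], gene_ids = ids)
  }
  out
}

#' Screen genes for AU decisiveness
#'
#' A gene is decisive when exactly one hypothesis survives: one AU p-value
#' at or above the (optionally Bonferroni-adjusted) threshold and all
#' others below it.
#'
#' @param census an `rs_census` run with `with_au = TRUE`.
#' @param alpha base significance level (default 0.05).
#' @param n_tests Bonferroni divisor (default 1 = unadjusted, the per-gene
#'   screen; the pipeline-level AU suite uses its number of tests).
#' @return list: `decisive` (subset of `per_gene`), `alpha_adj`,
#'   `percentage` of the censused genes.
#' @export
au_screen <- function(census, alpha = 0.05, n_tests = 1) {
  pg <- census$per_gene
  pm <- as.matrix(pg[, c("p_LM", "p_L", "p_M")])
  if (anyNA(pm)) stop("missing AU p-values: run the census with with_au = TRUE")
  alpha_adj <- alpha / n_tests
  surv <- rowSums(pm >= alpha_adj)
  dec <- surv == 1
  list(decisive = pg[dec, , drop = FALSE], alpha_adj = alpha_adj,
       percentage = 100 * sum(dec) / nrow(pg))
}

#' Export a census as TSV + JSON
#'
#' @param census an `rs_census`.
#' @param tsv_path,json_path output files (NULL to skip).
#' @export
write_census <- function(census, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(census$per_gene, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(
      counts = as.list(census$counts),
      proportions = census$proportions,
      chisq_resolved = census$chisq_resolved,
      chisq_total = census$chisq_total,
      n_L_paraphyletic = census$n_L_paraphyletic,
      n_excluded = nrow(census$excluded)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(census)
}

#' Write a RAxML-style partition file
#'
#' One `MODEL, gene = start-end` line per partition (1-based inclusive
#' coordinates, as conventional for partition files).
#'
#' @param aln an `rs_alignment` with a partition map.
#' @param path output file.
#' @param model model string to print (default `"AUTO"`).
#' @export
write_partition_file <- function(aln, path, model = "AUTO") {
  if (is.null(aln$partition)) stop("alignment has no partition map")
  lines <- sprintf("%s, %s = %d-%d", model, aln$partition$gene,
                   aln$partition$start + 1, aln$partition$end)
  writeLines(lines, path)
  invisible(path)
}
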