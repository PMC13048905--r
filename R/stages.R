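# Workflow stages.
#
# Each stage is a plain function over the package's modules, reading and
# writing files under a study directory so stages can be rerun
# independently.  The numbered scripts under analysis/ drive these stages
# on the default synthetic study.

#' Study configuration
#'
#' Bundles every tunable of the workflow with desk-scale defaults.  The
#' jackknife draws `jackknife_sites` columns per replicate (5,000 by
#' default; the full-scale analogue of this design uses 50,000) and the
#' adequacy test simulates `adequacy_N` replicates (100).
#'
#' @param geneset a [gene_set_spec()] (synthetic mode).
#' @param jackknife_replicates number of jackknife datasets (default 10).
#' @param jackknife_sites columns per jackknife dataset (default 5000).
#' @param bootstrap_B bootstrap replicates per analysis (default 100).
#' @param adequacy_N parametric-bootstrap simulations (default 100).
#' @param au_B,au_scales AU test settings.
#' @param K profiles for the CAT-surrogate mixture (default 5).
#' @param composition_alpha_gene per-gene composition threshold (0.05).
#' @param composition_alpha_concat taxon-removal threshold (0.10).
#' @param consensus_min_support greedy-consensus support floor (default 0).
#' @param alpha significance level (0.05).
#' @param seed master seed.
#' @export
study_config <- function(geneset = gene_set_spec(),
                         jackknife_replicates = 10,
                         jackknife_sites = 5000,
                         bootstrap_B = 100,
                         adequacy_N = 100,
                         au_B = 1000,
                         au_scales = seq(0.5, 1.4, by = 0.1),
                         K = 5,
                         composition_alpha_gene = 0.05,
                         composition_alpha_concat = 0.10,
                         consensus_min_support = 0,
                         alpha = 0.05,
                         seed = 1) {
  stopifnot(composition_alpha_gene > 0, composition_alpha_gene < 1,
            composition_alpha_concat > 0, composition_alpha_concat < 1,
            alpha > 0, alpha < 1)
  structure(list(geneset = geneset,
                 jackknife_replicates = jackknife_replicates,
                 jackknife_sites = jackknife_sites,
                 bootstrap_B = bootstrap_B, adequacy_N = adequacy_N,
                 au_B = au_B, au_scales = au_scales, K = K,
                 composition_alpha_gene = composition_alpha_gene,
                 composition_alpha_concat = composition_alpha_concat,
                 consensus_min_support = consensus_min_support,
                 alpha = alpha, seed = seed), class = "rs_config")
}

stage_result <- function(name, outputs, warnings = character(0)) {
  list(stage = name, outputs = outputs[file.exists(outputs)],
       warnings = warnings, time = format(Sys.time()))
}

#' Stage: simulate the synthetic study
#'
#' Writes one FASTA per gene plus `truth.tsv` (gene_id, label, length,
#' alpha, seed).
#'
#' @param config an [study_config()].
#' @param dir output directory (created).
#' @return stage result with the gene set attached (`$geneset`).
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gs <- generate_multisignal_geneset(config$geneset)
  paths <- character(0)
  for (i in seq_along(gs$genes)) {
    p <- file.path(dir, sprintf("%s.fasta", gs$truth$gene_id[i]))
    write_alignment(gs$genes[[i]]$aln, p, "fasta")
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.tsv")
  write.table(gs$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- stage_result("simulate", c(paths, tp))
  res$geneset <- gs
  res
}

#' Stage: per-gene signal census
#'
#' Runs [run_census()] on the gene set, writes the census table, the
#' chi-squared report and the single-signal concatenations (FASTA +
#' partition file).
#'
#' @param config an [study_config()].
#' @param geneset result of [generate_multisignal_geneset()] (or the
#'   `$geneset` of [stage_simulate()]'s result).
#' @param dir output directory.
#' @param ... passed on to [run_census()] (e.g. `tree_method`, `with_au`).
#' @return stage result with `$census` and `$single_signal`.
#' @export
stage_census <- function(config, geneset, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cz <- run_census(geneset$genes, config$geneset$roles,
                   hypothesis_trees = config$geneset$trees,
                   alpha = config$alpha, au_B = config$au_B,
                   au_scales = config$au_scales, seed = config$seed, ...)
  write_census(cz, file.path(dir, "census.tsv"),
               file.path(dir, "census.json"))
  ss <- build_single_signal_datasets(cz, geneset$genes)
  paths <- c(file.path(dir, "census.tsv"), file.path(dir, "census.json"))
  for (h in names(ss)) {
    fp <- file.path(dir, sprintf("single_signal_%s.fasta", h))
    write_alignment(ss[[h]], fp, "fasta")
    write_partition_file(ss[[h]],
                         file.path(dir, sprintf("single_signal_%s.part", h)))
    paths <- c(paths, fp)
  }
  res <- stage_result("census", paths)
  res$census <- cz
  res$single_signal <- ss
  res
}

#' CAT-surrogate + PMSF fitting procedure
#'
#' On a fixed topology: learn `K` profiles by k-means, optimize branch
#' lengths, refit mixture weights by EM, estimate the Gamma shape, derive
#' posterior-mean site frequencies (PMSF) and re-optimize branch lengths
#' under them.
#'
#' @param aln an `rs_alignment`.
#' @param topology fixed tree topology.
#' @param K number of learned profiles.
#' @param seed seed for profile learning.
#' @param tol lnL tolerance per stage.
#' @return list: `mixture` (fitted `rs_mixture`), `mixture_fit` (`rs_fit`),
#'   `pmsf` (`rs_pmsf`), `pmsf_fit` (`rs_fit`).
#' @export
fit_cat_pmsf <- function(aln, topology, K, seed, tol = 1e-4) {
  mix <- learn_profiles(aln, K, seed = seed)
  f1 <- optimize_branch_lengths(aln, topology, mix, tol = tol)
  mix <- fit_mixture_weights_em(aln, f1$tree, mix)
  mix <- estimate_alpha(aln, f1$tree, mix)
  f2 <- optimize_branch_lengths(aln, f1$tree, mix, tol = tol)
  pmsf <- pmsf_site_frequencies(aln, f2$tree, mix)
  fp <- optimize_branch_lengths(aln, f2$tree, pmsf, tol = tol)
  list(mixture = mix, mixture_fit = f2, pmsf = pmsf, pmsf_fit = fp)
}

#' Stage: jackknife + CAT-PMSF + pooled bootstrap consensus (CUBS)
#'
#' For each jackknife replicate and each of the three hypothesis
#' topologies: learn the CAT-surrogate profile mixture on that topology,
#' derive posterior-mean site frequencies (PMSF), evaluate the three
#' candidate topologies under the PMSF model, and bootstrap (RELL).  All
#' bootstrap winner trees are pooled into an extended majority-rule
#' consensus whose supports are the cumulative bootstrap support (CUBS).
#'
#' @param config an [study_config()].
#' @param concat concatenated `rs_alignment` (all genes).
#' @param dir output directory.
#' @return stage result with `$consensus`, `$winners` (per replicate x
#'   profile-topology), `$site_lnl` (cached per-site lnL matrices for the
#'   AU stage), `$pooled_trees`.
#' @export
stage_jackknife_cubs <- function(config, concat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (config$jackknife_sites > n_sites(concat))
    stop("jackknife_sites exceeds alignment length")
  trees <- config$geneset$trees
  hyp <- names(trees)
  R <- config$jackknife_replicates
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L,
                                             R * (length(hyp) + 1)))
  pooled <- list()
  winners <- list()
  site_lnl <- list()
  k <- 0
  for (r in seq_len(R)) {
    k <- k + 1
    jk <- jackknife_sites(concat, config$jackknife_sites, seed = seeds[k])
    for (h in hyp) {
      k <- k + 1
      cp <- fit_cat_pmsf(jk, trees[[h]], config$K, seed = seeds[k])
      bs <- felsenstein_bootstrap(jk, cp$pmsf, unname(trees),
                                  B = config$bootstrap_B, seed = seeds[k])
      pooled <- c(pooled, bs$trees)
      winners[[length(winners) + 1]] <-
        data.frame(replicate = r, profile_topology = h,
                   winner = hyp[which.max(bs$lnl)],
                   lnl_LM = bs$lnl[1], lnl_L = bs$lnl[2], lnl_M = bs$lnl[3],
                   stringsAsFactors = FALSE)
      L <- vapply(hyp, function(h2) {
        f <- optimize_branch_lengths(jk, trees[[h2]], cp$pmsf)
        site_log_likelihoods(jk, f$tree, cp$pmsf)$site_lnl
      }, numeric(n_sites(jk)))
      site_lnl[[sprintf("rep%02d_%s", r, h)]] <- L
    }
  }
  winners <- do.call(rbind, winners)
  cons <- majority_consensus(pooled, config$consensus_min_support)
  ape::write.tree(cons$tree, file.path(dir, "consensus_cubs.nwk"))
  write.table(cons$support, file.path(dir, "cubs_support.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(winners, file.path(dir, "winners.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(site_lnl))
    write_site_lnl_tsv(site_lnl[[nm]],
                       file.path(dir, sprintf("site_lnl_%s.tsv", nm)))
  res <- stage_result("jackknife_cubs",
                      file.path(dir, c("consensus_cubs.nwk",
                                       "cubs_support.tsv", "winners.tsv")))
  res$consensus <- cons
  res$winners <- winners
  res$site_lnl <- site_lnl
  res$pooled_trees <- pooled
  res
}

#' Stage: parametric-bootstrap model adequacy comparison
#'
#' On one jackknife replicate, fits three model families on a fixed
#' topology - homogeneous Poisson+F+G, a mixture over a FIXED generic
#' profile dictionary (weights and shape fitted, profiles not learned
#' from the data; the role the empirical CXX dictionaries play in ML
#' software), and the dataset-specific CAT-surrogate PMSF - and compares
#' their DIV adequacy Z-scores.
#'
#' @param config an [study_config()].
#' @param aln alignment to test (e.g. one jackknife replicate).
#' @param topology fixed topology for the fits.
#' @param dir output directory.
#' @param statistic `"DIV"` (default) or `"MAX"`.
#' @param dictionary fixed profile dictionary for the middle family
#'   (default [default_profiles()]).
#' @return stage result with `$results` (list of `rs_adequacy`) and
#'   `$table` (ranked comparison).
#' @export
stage_adequacy <- function(config, aln, topology, dir, statistic = "DIV",
                           dictionary = default_profiles()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 3))
  homo <- fit_model(aln, topology, model_spec("Poisson+F+G"))
  fixd <- fit_model(aln, topology,
                    model_spec("fixed-dictionary", profiles = dictionary))
  cp <- fit_cat_pmsf(aln, topology, config$K, seed = config$seed)
  res <- list(
    parametric_bootstrap_test(aln, homo$tree, homo$model, statistic,
                              N = config$adequacy_N, seed = seeds[1],
                              model_tag = "Poisson+F+G"),
    parametric_bootstrap_test(aln, fixd$tree, fixd$model, statistic,
                              N = config$adequacy_N, seed = seeds[2],
                              model_tag = sprintf("fixed-dictionary-K%d",
                                                  ncol(dictionary))),
    parametric_bootstrap_test(aln, cp$pmsf_fit$tree, cp$pmsf, statistic,
                              N = config$adequacy_N, seed = seeds[3],
                              model_tag = "CAT-PMSF-surrogate"))
  tab <- compare_adequacy(res)
  write.table(tab, file.path(dir, "adequacy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- stage_result("adequacy", file.path(dir, "adequacy.tsv"))
  out$results <- res
  out$table <- tab
  out
}

#' Stage: across-lineage compositional heterogeneity
#'
#' Produces the per-taxon composition report on a jackknife replicate,
#' prunes taxa failing at the removal threshold and re-evaluates the three
#' hypotheses, then recodes to Dayhoff-6 and re-evaluates under a 6-state
#' GTR and the 6-state CAT-surrogate mixture; finally contrasts MAX
#' adequacy before and after recoding.
#'
#' @param config an [study_config()].
#' @param aln a jackknife replicate alignment.
#' @param dir output directory.
#' @return stage result with `$report`, `$pruned_winner`, `$d6_winners`,
#'   `$max_adequacy` (before/after recoding).
#' @export
stage_heterogeneity <- function(config, aln, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trees <- config$geneset$trees
  hyp <- names(trees)
  report <- composition_chisq(aln, config$composition_alpha_concat)
  write_composition_tsv(report, file.path(dir, "composition.tsv"))
  fails <- report$table$taxon[report$table$fail]
  protected <- c(config$geneset$roles$focal, config$geneset$roles$outgroup)
  drop <- setdiff(fails, protected)
  # the three hypotheses are indistinguishable without clade L: always
  # retain the least-heterogeneous L taxon
  Lrole <- config$geneset$roles$L
  if (all(Lrole %in% drop)) {
    pL <- report$table$p[match(Lrole, report$table$taxon)]
    drop <- setdiff(drop, Lrole[which.max(pL)])
  }
  pruned_winner <- NA_character_
  if (length(drop) && n_taxa(aln) - length(drop) >= 4) {
    pr <- remove_taxa(aln, drop)
    ptrees <- lapply(trees, function(tr) ape::keep.tip(tr, taxa_names(pr)))
    mix <- learn_profiles(pr, config$K, seed = config$seed)
    ev <- evaluate_candidates(pr, mix, unname(ptrees))
    pruned_winner <- hyp[ev$ranking[1]]
  }
  d6 <- recode_dayhoff6(aln)
  d6_winners <- vapply(list(
    gtr = model_spec("D6-GTR+F+G", exch = "gtr"),
    cat = model_spec("D6-CAT-surrogate", K = config$K)),
    function(sp) {
      fit <- fit_model(d6, trees[[1]], sp)
      ev <- evaluate_candidates(d6, fit$model, unname(trees))
      hyp[ev$ranking[1]]
    }, "")
  # MAX adequacy before vs after recoding, each under its own fitted model
  mix_aa <- learn_profiles(aln, config$K, seed = config$seed)
  f_aa <- optimize_branch_lengths(aln, trees[[1]], mix_aa)
  ad_aa <- parametric_bootstrap_test(aln, f_aa$tree, mix_aa, "MAX",
                                     N = config$adequacy_N,
                                     seed = config$seed, model_tag = "aa")
  mix_d6 <- learn_profiles(d6, min(config$K, 5), seed = config$seed)
  f_d6 <- optimize_branch_lengths(d6, trees[[1]], mix_d6)
  ad_d6 <- parametric_bootstrap_test(d6, f_d6$tree, mix_d6, "MAX",
                                     N = config$adequacy_N,
                                     seed = config$seed + 1,
                                     model_tag = "dayhoff6")
  summary <- data.frame(
    n_fail = length(fails), pruned = paste(drop, collapse = ","),
    pruned_winner = pruned_winner,
    d6_gtr_winner = d6_winners["gtr"], d6_cat_winner = d6_winners["cat"],
    z_max_aa = ad_aa$z, z_max_d6 = ad_d6$z, stringsAsFactors = FALSE)
  write.table(summary, file.path(dir, "heterogeneity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- stage_result("heterogeneity",
                      file.path(dir, c("composition.tsv",
                                       "heterogeneity.tsv")))
  out$report <- report
  out$pruned_winner <- pruned_winner
  out$d6_winners <- d6_winners
  out$max_adequacy <- list(aa = ad_aa, dayhoff6 = ad_d6)
  out
}

#' Stage: AU test suite over jackknife replicates
#'
#' One AU test per (replicate, profile topology) pair using the cached
#' per-site log-likelihood matrices from the jackknife stage; the
#' significance level is Bonferroni-adjusted by the number of tests.
#'
#' @param config an [study_config()].
#' @param site_lnl named list of per-site lnL matrices
#'   (from [stage_jackknife_cubs()]'s `$site_lnl`).
#' @param dir output directory.
#' @return stage result with `$p_matrix`, `$decisions`, `$mean_p`,
#'   `$alpha_adj`.
#' @export
stage_au <- function(config, site_lnl, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_tests <- length(site_lnl)
  alpha_adj <- config$alpha / n_tests
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L,
                                             n_tests))
  p <- t(vapply(seq_along(site_lnl), function(i)
    au_test(site_lnl[[i]], scales = config$au_scales, B = config$au_B,
            seed = seeds[i])$p_au, numeric(ncol(site_lnl[[1]]))))
  rownames(p) <- names(site_lnl)
  colnames(p) <- colnames(site_lnl[[1]])
  decisions <- p < alpha_adj
  mean_p <- colMeans(p)
  tab <- data.frame(test = rownames(p), p, row.names = NULL)
  write.table(tab, file.path(dir, "au_pvalues.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- stage_result("au", file.path(dir, "au_pvalues.tsv"))
  out$p_matrix <- p
  out$decisions <- decisions
  out$mean_p <- mean_p
  out$alpha_adj <- alpha_adj
  out
}
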