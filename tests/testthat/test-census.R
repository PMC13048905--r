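test_that("chi-squared goodness of fit matches hand computations", {
  r <- chisq_gof(c(10, 10, 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  r2 <- chisq_gof(c(20, 10), expected = c(15, 15))
  expect_equal(r2$statistic, 10 / 3, tolerance = 1e-12)
  expect_equal(r2$df, 1)
  expect_error(chisq_gof(c(5, 5), expected = c(0, 10)), "zero expected")
  expect_error(chisq_gof(c(-1, 2)), "non-negative")
})

test_that("the census recovers synthetic signal proportions and conserves genes", {
  spec <- tiny_spec(n_genes = 24, len = c(500, 700), seed = 77)
  gs <- generate_multisignal_geneset(spec)
  cz <- run_census(gs$genes, spec$roles, tree_method = "nj",
                   hypothesis_trees = spec$trees)
  expect_equal(sum(cz$counts) + nrow(cz$excluded), 24)
  # per-gene agreement with the generator's truth table
  agree <- mean(cz$per_gene$label == gs$truth$label)
  expect_gte(agree, 0.8)
  expect_equal(sum(cz$proportions), 1, tolerance = 1e-9)
  expect_gte(cz$chisq_resolved$statistic, 0)
  # NNI from the NJ start must not do worse than NJ alone
  cz2 <- run_census(gs$genes[1:6], spec$roles, tree_method = "nni",
                    hypothesis_trees = spec$trees)
  agree2 <- mean(cz2$per_gene$label == gs$truth$label[1:6])
  expect_gte(agree2, 0.8)
})

test_that("provided trees short-circuit inference and bad genes are logged", {
  spec <- tiny_spec(n_genes = 6, len = c(100, 150), seed = 78)
  gs <- generate_multisignal_geneset(spec)
  gts <- lapply(gs$genes, function(g) spec$trees[[g$label]])
  cz <- run_census(gs$genes, spec$roles, tree_method = "provided",
                   gene_trees = gts, hypothesis_trees = spec$trees)
  expect_equal(unname(cz$per_gene$label), gs$truth$label)
  # a gene without the focal taxon is excluded with a reason, not an error
  broken <- gs$genes
  broken[[2]]$aln <- remove_taxa(broken[[2]]$aln, spec$roles$focal)
  cz2 <- run_census(broken, spec$roles, tree_method = "provided",
                    gene_trees = gts, hypothesis_trees = spec$trees)
  expect_equal(nrow(cz2$excluded), 1)
  expect_match(cz2$excluded$reason, "focal")
  expect_equal(nrow(cz2$per_gene) + nrow(cz2$excluded), 6)
})

test_that("single-signal datasets concatenate genes by label", {
  spec <- tiny_spec(n_genes = 9, len = c(100, 120), seed = 79)
  gs <- generate_multisignal_geneset(spec)
  gts <- lapply(gs$genes, function(g) spec$trees[[g$label]])
  cz <- run_census(gs$genes, spec$roles, tree_method = "provided",
                   gene_trees = gts, hypothesis_trees = spec$trees)
  ss <- build_single_signal_datasets(cz, gs$genes)
  for (h in names(ss)) {
    ids <- cz$per_gene$gene_id[cz$per_gene$label == h]
    lens <- gs$truth$length[match(ids, gs$truth$gene_id)]
    expect_equal(n_sites(ss[[h]]), sum(lens))
    expect_equal(nrow(ss[[h]]$partition), length(ids))
  }
  # an absent label yields a warning and a missing output
  only_lm <- gene_set_spec(n_genes = 4,
                           proportions = c(LM_SISTER = 1, L_SISTER = 0,
                                           M_SISTER = 0),
                           len_range = c(80, 90), roles = spec$roles,
                           trees = spec$trees, seed = 3)
  gs2 <- generate_multisignal_geneset(only_lm)
  cz3 <- run_census(gs2$genes, spec$roles, tree_method = "provided",
                    gene_trees = lapply(gs2$genes,
                                        function(g) spec$trees[[g$label]]),
                    hypothesis_trees = spec$trees)
  ws <- capture_warnings(ss2 <- build_single_signal_datasets(cz3, gs2$genes))
  expect_length(ws, 2)  # both empty labels are reported
  expect_match(ws, "no genes labelled", all = TRUE)
  expect_named(ss2, "LM_SISTER")
})

test_that("single-signal datasets support their own topology on reanalysis", {
  spec <- tiny_spec(n_genes = 12, len = c(400, 600), seed = 80)
  gs <- generate_multisignal_geneset(spec)
  gts <- lapply(gs$genes, function(g) spec$trees[[g$label]])
  cz <- run_census(gs$genes, spec$roles, tree_method = "provided",
                   gene_trees = gts, hypothesis_trees = spec$trees)
  ss <- build_single_signal_datasets(cz, gs$genes)
  model <- mixture_model(poisson_exchangeabilities(20), spec$profiles,
                         spec$weights, discrete_gamma(1, 4))
  for (h in names(ss)) {
    ev <- evaluate_candidates(ss[[h]], model, unname(spec$trees))
    expect_equal(names(spec$trees)[ev$ranking[1]], h)
  }
})

test_that("AU screening keeps genes with exactly one surviving hypothesis", {
  spec <- tiny_spec(n_genes = 4, len = c(150, 200), seed = 81)
  gs <- generate_multisignal_geneset(spec)
  gts <- lapply(gs$genes, function(g) spec$trees[[g$label]])
  cz <- run_census(gs$genes, spec$roles, tree_method = "provided",
                   gene_trees = gts, hypothesis_trees = spec$trees)
  expect_error(au_screen(cz), "missing AU")
  # synthetic p-value matrices exercise the decision rule directly
  cz$per_gene$p_LM <- c(0.9, 0.9, 0.001, 1)
  cz$per_gene$p_L <- c(0.001, 0.5, 0.0001, 1)
  cz$per_gene$p_M <- c(0.0001, 0.2, 0.0005, 1)
  sc <- au_screen(cz, alpha = 0.05, n_tests = 1)
  expect_equal(sc$decisive$gene_id, cz$per_gene$gene_id[1])
  expect_equal(sc$percentage, 25)
  sc30 <- au_screen(cz, alpha = 0.05, n_tests = 30)
  expect_equal(sc30$alpha_adj, 0.05 / 30, tolerance = 1e-12)
  expect_equal(trunc(sc30$alpha_adj * 1e4) / 1e4, 0.0016)
  allflat <- cz
  allflat$per_gene$p_LM <- allflat$per_gene$p_L <- allflat$per_gene$p_M <- 1
  expect_equal(nrow(au_screen(allflat)$decisive), 0)
})

test_that("per-gene AU tests run inside the census", {
  spec <- tiny_spec(n_genes = 3, len = c(300, 400), seed = 82)
  gs <- generate_multisignal_geneset(spec)
  cz <- run_census(gs$genes, spec$roles, tree_method = "nj", with_au = TRUE,
                   hypothesis_trees = spec$trees, au_B = 200)
  pm <- as.matrix(cz$per_gene[, c("p_LM", "p_L", "p_M")])
  expect_false(anyNA(pm))
  expect_true(all(pm >= 0 & pm <= 1))
  # the true label should never be strongly rejected while a rival wins
  for (i in 1:3) {
    truth <- c(LM_SISTER = "p_LM", L_SISTER = "p_L",
               M_SISTER = "p_M")[gs$truth$label[i]]
    expect_gt(pm[i, truth], 0.01)
  }
})

test_that("census and partition exports are readable", {
  spec <- tiny_spec(n_genes = 4, len = c(80, 100), seed = 83)
  gs <- generate_multisignal_geneset(spec)
  gts <- lapply(gs$genes, function(g) spec$trees[[g$label]])
  cz <- run_census(gs$genes, spec$roles, tree_method = "provided",
                   gene_trees = gts, hypothesis_trees = spec$trees)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_census(cz, tsv, js)
  expect_equal(nrow(read.table(tsv, header = TRUE, sep = "\t")),
               nrow(cz$per_gene))
  expect_equal(jsonlite::read_json(js)$n_excluded, 0)
  cc <- concatenate_alignments(lapply(gs$genes, function(g) g$aln))
  pf <- withr::local_tempfile(fileext = ".part")
  write_partition_file(cc, pf)
  lines <- readLines(pf)
  expect_length(lines, 4)
  expect_match(lines[1], "^AUTO, g1 = 1-")
})
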