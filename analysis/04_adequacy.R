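#!/usr/bin/env Rscript
# Parametric-bootstrap model adequacy on one jackknife replicate:
# compare the amino-acid diversity (DIV) Z-scores of the homogeneous
# Poisson+F+G model, the fixed-K CAT-surrogate mixture, and its PMSF
# refinement.  A model is adequate when -2 < Z < 2.

source(file.path("analysis", "config.R"))

gs <- readRDS(file.path(SCRATCH, "geneset.rds"))
concat <- concatenate_alignments(lapply(gs$genes, function(g) g$aln),
                                 gs$truth$gene_id)
jk1 <- jackknife_sites(concat, CONFIG$jackknife_sites, seed = CONFIG$seed)

ad <- stage_adequacy(CONFIG, jk1, CONFIG$geneset$trees$LM_SISTER,
                     file.path(RESULTS, "adequacy"))
print(ad$table)
cat("\nnote: on this default study the generic fixed dictionary coincides",
    "\nwith the generating profiles, so it is adequate by construction;",
    "\nthe dataset-specific PMSF comes close without that advantage and",
    "\nthe homogeneous model fails by a wide margin\n")
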