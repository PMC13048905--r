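# rootsignal

Tools for detecting and dissecting **conflicting root-placement signals**
in phylogenomic amino-acid datasets.

When a focal lineage M and a deep clade L sit near the root of a
radiation, three placements compete: clade L sister to all other ingroup
taxa (`L_SISTER`), the focal taxon sister to all other ingroup taxa
(`M_SISTER`), or the clade (L, M) sister to everything else
(`LM_SISTER`). With short internal branches, different loci genuinely
support different resolutions, and compositional heterogeneity across
sites and lineages can masquerade as phylogenetic signal. rootsignal is
for phylogeneticists who want to quantify such a conflict rather than
average over it.

The package implements, as tested reusable components:

* a **per-gene signal census** — classify every gene tree's placement of
  the focal taxon, count support per hypothesis, and test the counts with
  χ² = Σ(O−E)²/E (df = 2 for three hypotheses);
* **single-signal concatenations** of the genes behind each hypothesis;
* **site jackknifing** + CAT-style profile-mixture / **PMSF** likelihood
  analyses (π̂ᵢ = Σₖ rᵢₖ πₖ posterior-mean site frequencies), summarized
  by pooled bootstrap support (**CUBS**);
* **parametric-bootstrap model adequacy**: Z = (obs − mean_sim)/sd_sim on
  the mean per-site amino-acid diversity (div) or the maximum squared
  compositional deviation (MAX); a model is adequate iff −2 < Z < 2;
* **compositional diagnostics**: per-taxon χ² against pooled frequencies,
  taxon removal, Dayhoff-6 recoding (AGPST / DENQ / HKR / ILMV / FWY / C);
* **gene and site concordance factors** (gCF/sCF by quartet sampling);
* the **AU topology test** via multiscale RELL resampling
  (z_k = Φ⁻¹(1−BP_k), z ≈ d√r + c/√r, p_AU = 1 − Φ(d − c));
* a **synthetic multi-signal generator** that draws gene topologies from
  the three hypotheses at known proportions under site-heterogeneous
  profile mixtures, with optional lineage-specific compositional bias —
  the ground truth against which the whole workflow is calibrated.

The likelihood engine (Felsenstein pruning under profile mixtures and
per-site frequencies, with an F81-analogue closed form for Poisson
exchangeabilities) is implemented in C++ via Rcpp.

## Worked example

Simulate a small three-signal gene set, run the census, and test the
counts:

```r
library(rootsignal)

spec <- gene_set_spec(n_genes = 60, len_range = c(500, 800),
                      proportions = c(LM_SISTER = 0.44, L_SISTER = 0.31,
                                      M_SISTER = 0.25),
                      seed = 7)
gs <- generate_multisignal_geneset(spec)
cz <- run_census(gs$genes, spec$roles, tree_method = "nj",
                 hypothesis_trees = spec$trees)
print(cz)
```

```
signal census:

LM_SISTER  L_SISTER  M_SISTER     OTHER 
       32        13        15         0 
resolved proportions: 53.3% / 21.7% / 25.0%
chi-squared (resolved): 10.900, df = 2, p = 0.0043
```

Each gene was classified by where its (neighbour-joining) gene tree
attaches the focal taxon after outgroup rooting; 32 of the 60 genes
support `LM_SISTER`, and the χ² test says the three counts are unlikely
to be draws from a uniform signal. Against the generator's truth table
the per-gene labels agree well (`mean(cz$per_gene$label ==
gs$truth$label)` is 0.92 here): at these gene lengths most
classification error comes from genuinely weak genes, not the pipeline.

Model adequacy on a 5,000-site jackknife of the concatenation,
contrasting a homogeneous model with the dataset-specific CAT-surrogate
PMSF:

```r
concat <- concatenate_alignments(lapply(gs$genes, `[[`, "aln"))
jk <- jackknife_sites(concat, 5000, seed = 1)
tree <- spec$trees$LM_SISTER
homo <- fit_model(jk, tree, model_spec("Poisson+F+G"))
parametric_bootstrap_test(jk, homo$tree, homo$model, "DIV",
                          N = 100, seed = 1)
cp <- fit_cat_pmsf(jk, tree, K = 5, seed = 1)
parametric_bootstrap_test(jk, cp$pmsf_fit$tree, cp$pmsf, "DIV",
                          N = 100, seed = 2)
```

```
DIV adequacy [Poisson+F+G]: observed 3.4418, simulated 4.1600 +- 0.0309, Z = -23.21 (inadequate)
DIV adequacy [PMSF(CAT-surrogate-K5)]: observed 3.4418, simulated 3.4872 +- 0.0275, Z = -1.65 (adequate)
```

The homogeneous model overproduces per-site amino-acid diversity by 23
standard deviations of its own null and is rejected; the PMSF model
reproduces the observed diversity (−2 < Z < 2, adequate). The vignette
(`vignettes/rootsignal-methods.Rmd`) documents every model, statistic
and convention; the numbered scripts under `analysis/` run the full
workflow (simulate → census → jackknife/CUBS → adequacy → heterogeneity
→ AU) on the default 300-gene study and write their tables under
`results/`.

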