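# Shared configuration for the analysis scripts: the default synthetic
# study (16 taxa, 300 genes, three root signals at 44/31/25%) at desk
# scale.  Every script sources this file and reads/writes under results/.

library(rootsignal)

RESULTS <- file.path("results")
CONFIG <- study_config(
  geneset = gene_set_spec(seed = 2026),
  jackknife_replicates = 10,
  jackknife_sites = 5000,
  bootstrap_B = 100,
  adequacy_N = 100,
  K = 5,
  seed = 2026)

dir.create(RESULTS, showWarnings = FALSE)

# stages cache their heavyweight in-memory products as RDS under
# scratch/ so later scripts can resume without recomputation
SCRATCH <- file.path("scratch", "analysis-cache")
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
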