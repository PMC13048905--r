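---
title: "Dissecting conflicting root-placement signals: models and methods"
author: "rootsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting conflicting root-placement signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep phylogenomic questions are often not one question but three. When a
focal lineage M and a deep clade L sit near the root of a radiation, three
placements compete: L sister to all other ingroup taxa (`L_SISTER`), M
sister to all other ingroup taxa (`M_SISTER`), or the clade (L, M) sister
to everything else (`LM_SISTER`). When the underlying branches are short,
different loci genuinely support different resolutions - through
incomplete lineage sorting or introgression - and systematic error
(especially compositional heterogeneity across sites and lineages) can
masquerade as signal. rootsignal implements a workflow for detecting and
dissecting such conflicts:

1. a **per-gene signal census**: classify every gene tree's placement of
   the focal taxon, count support per hypothesis, and test the counts by
   chi-squared;
2. **single-signal concatenations**: regroup genes by their own signal and
   confirm each group supports its own topology;
3. **site jackknifing** with site-heterogeneous likelihood analyses
   summarized by pooled bootstrap support (CUBS);
4. **parametric-bootstrap model adequacy** (Z-scores on compositional
   statistics);
5. **compositional-heterogeneity diagnostics** (per-taxon chi-squared,
   taxon removal, Dayhoff-6 recoding, the MAX statistic);
6. **gene and site concordance factors** and **AU topology tests**.

Because the workflow's statistical behaviour - not any single empirical
dataset - is what the package can verify, a synthetic multi-signal
generator is a first-class module: it creates gene sets whose true mixture
of topologies is known, so every stage can be tested for calibration and
power.

## Substitution models

All likelihood machinery works with **profile mixtures**: an
exchangeability matrix $S$, $K$ frequency profiles $\pi_k$ with weights
$w_k$, and discrete Gamma rates. The rate matrix for profile $\pi$ is the
usual reversible construction $Q_{ab} = s_{ab}\pi_b$, normalized to one
expected substitution per unit time. With **Poisson exchangeabilities**
(all $s_{ab}$ equal - the setting used throughout the workflow, as in
CAT-style analyses) the transition kernel has the closed form

$$P(t) = e^{-t/\beta} I + (1 - e^{-t/\beta})\,\mathbf{1}\pi^{\top},
  \qquad \beta = 1 - \textstyle\sum_a \pi_a^2 .$$

This makes a pruning step $O(\text{states})$ instead of
$O(\text{states}^2)$ and - more importantly - makes the site likelihood a
*linear* function of $e^{-t/\beta}$ per mixture class for any single
branch, which the branch-length optimizer exploits (below). General
exchangeabilities (LG loaded from a PAML-style `.dat` file, or a 6-state
GTR whose exchangeabilities are estimated by ML after Dayhoff-6 recoding)
go through a dense path built on the symmetrized eigendecomposition
$\mathrm{diag}(\sqrt{\pi})\,Q\,\mathrm{diag}(1/\sqrt{\pi})$.

Discrete Gamma rates use $K$ equal-probability categories with the
category rate equal to the **bin mean** of the Gamma(shape $\alpha$, rate
$\alpha$) distribution, renormalized to mean exactly one. Bin means (not
medians) were adopted as the single fixed convention; the unit tests pin
them against numerical quadrature.

### The CAT surrogate and PMSF

The workflow's site-heterogeneous model is a deterministic finite-mixture
stand-in for Dirichlet-process profile inference, called the **CAT
surrogate** throughout: per-site residue-frequency vectors
(pseudocount-smoothed) are clustered into $K$ centroids by k-means with a
fixed seed; centroid profiles are kept fixed while the weights are
refitted by EM and the Gamma shape by 1-D maximization. No equivalence
with Bayesian CAT posteriors is claimed; what the downstream PMSF step
needs is only a site-to-profile mixture.

Two tunables matter:

* **Pseudocount** (default $0.5/n_\text{taxa}$ per state). A site's raw
  frequency vector rests on roughly $n_\text{taxa}$ observations, so a
  fixed pseudocount of 0.5 *per state* would add 10 phantom residues to
  ~20 observed ones and flatten every learned profile. The consequence is
  not cosmetic: data simulated from such flattened profiles contain far
  more per-site diversity than real data, which wrecks parametric-
  bootstrap adequacy (|Z| in the tens even for the generating family).
  The default adds half a phantom residue per site *in total*, which
  still keeps profiles off the simplex vertices.
* **K** (default 5 in the pipeline configuration, matching the default
  generator; 10 in the adequacy experiment, whose generator uses 10
  sparse profiles). Underestimating K merges distinct profiles into
  flatter centroids and degrades adequacy in exactly the way the
  adequacy stage is designed to detect; K is therefore a config key, not
  a constant.

**PMSF** (posterior mean site frequencies): with the mixture and tree
fixed, each site receives
$\hat\pi_i = \sum_k r_{ik}\,\pi_k$ with responsibilities
$r_{ik} \propto w_k L_{ik}$, and these per-site profiles are then used as
*fixed inputs* in a final likelihood analysis. Following the convention
for this model family, per-site frequencies are not counted as free
parameters in BIC.

## Optimization

Branch lengths are optimized coordinate-wise under bounds
$[10^{-8}, 10]$. For the Poisson path, one round computes - per mixture
class - downward partials, upward partials, and per-branch coefficients
$(A, C)$ such that the site likelihood at branch length $t$ is
$e\,A + (1-e)\,C$ with $e = e^{-t r/\beta}$; each branch is then solved by
golden-section search on $\log t$ against its cached coefficients, all
branches are updated together, and the joint log-likelihood is recomputed.
A round that fails to improve is geometrically damped and, if still
failing, rejected - so the reported lnL trace is non-decreasing. Rounds
repeat until the gain drops below `tol` (default $10^{-4}$). Tree search
is greedy best-improvement NNI: neighbours are scored at the current
branch lengths (tip indices are invariant under the edge surgery, so the
compressed data are prepared once), and only the best neighbour is
re-optimized before acceptance. This is a desk-scale stand-in for a full
ML tree search; on the synthetic studies the NJ starting tree is usually
already the ML topology.

All tie-breaking is deterministic (input order, or lexicographic on
canonical split keys), and every stochastic operation takes an explicit
seed. One consequence, documented rather than hidden: on data with exact
likelihood ties (e.g. all-constant alignments) bootstrap winners go to the
first candidate instead of splitting randomly.

## Consensus and CUBS

The consensus over pooled bootstrap trees is **extended majority rule**:
every split above 50% enters, then remaining splits are added greedily in
decreasing frequency (lexicographic tie-break) while compatible. Support
is $100\times$ the pooled split frequency; when the pool gathers the
bootstrap trees of every (jackknife replicate x profile-inference
topology) analysis, this is the cumulative bootstrap support (CUBS)
summary. Pooling requires identical leaf sets; analyses run after taxon
removal are summarized separately rather than pooled. The package's
bootstrap is a standard Felsenstein column bootstrap with a RELL fast
path - how closely CUBS over these trees tracks CUBS over ultrafast
bootstrap trees from other software is unknown and no numerical equality
is claimed.

## Concordance factors

For each internal branch, four adjacent subtrees (A, B | C, D) are read
off the reference tree. A gene tree is *decisive* when it contains at
least one taxon from each of the four; it is *concordant* when it contains
the branch's restricted split, and the two alternative unit pairings are
tallied as gDF1/gDF2 (gene trees that break the units themselves fall in
neither bucket). sCF samples `n_quartets` quartets per branch (one taxon
per subtree, without replacement over distinct quartets until exhausted);
a site is decisive for a quartet when all four taxa carry residues with
exactly two distinct states pairing 2+2, and the strict 2+2 rule is a
documented convention, not asserted identical to any particular program's
variant. Under a hard polytomy every resolution expects 33%, which is the
package's acceptance anchor for both statistics.

## AU test

Per-site log-likelihoods for the competing hypotheses are resampled by
multinomial RELL at ten scales $r \in \{0.5, \dots, 1.4\}$, $B = 1000$
replicates per scale (ties split equally). Bootstrap proportions are
mapped through $z_k = \Phi^{-1}(1 - \mathrm{BP}_k)$, the signed distance
$d$ and curvature $c$ come from weighted least squares of
$z_k \approx d\sqrt{r_k} + c/\sqrt{r_k}$ with weights
$B\,\phi(z_k)^2 / (\mathrm{BP}_k(1-\mathrm{BP}_k))$, and
$p_\mathrm{AU} = 1 - \Phi(d - c)$. Boundary proportions receive the
$0.5/B$ continuity correction; a hypothesis with fewer than two
informative scales degenerates to $p \in \{0, 1\}$ with a warning flag.
The suite-level application runs one test per (jackknife replicate x
profile topology) - 30 at the defaults - with Bonferroni adjustment
$\alpha/30$.

## Model adequacy

Adequacy is tested by parametric bootstrap from point estimates: simulate
$N = 100$ replicates under the fitted (tree, model), compute a statistic
on each, and report $Z = (\text{obs} - \overline{\text{sim}})/s_\text{sim}$
(Bessel-corrected), with the verdict *adequate* iff $-2 < Z < 2$. Two
statistics are built in: **DIV**, the mean number of distinct residues per
column (gaps/missing never counted; an all-gap column contributes 0), and
**MAX**, the maximum over taxa of the *sum* of squared deviations between
taxon-specific and global frequencies - the per-taxon-aggregate reading of
the maximum-square-deviation statistic; the exact aggregation used
elsewhere is not printed anywhere authoritative, so the convention is
documented rather than asserted as identical.

Two empirical notes, both visible in the test suite. First, the sign: a
homogeneous +F model *overproduces* per-site diversity relative to
site-heterogeneous data (each real column draws from a concentrated
profile), so its DIV Z-score is strongly negative; the diagnostic
orderings are therefore stated on |Z|. Second, the middle family in the
adequacy contrast is a mixture over a *fixed generic profile dictionary*
(the built-in five biochemical-group profiles; weights and shape fitted) -
the role empirical CXX dictionaries play in ML software. The
dataset-specific learned mixture would be nearly the generating family on
synthetic data and adequate by construction, which would say nothing about
the contrast the workflow is meant to exhibit: dataset-specific PMSF
$\prec$ fixed dictionary $\prec$ homogeneous.

## Compositional diagnostics

Per-taxon chi-squared compares each taxon's residue counts against
expected counts from the pooled frequencies of all taxa (df = supported
states - 1, no continuity correction). Two thresholds are config keys:
0.05 for per-gene screening and 0.10 for the concatenated taxon-removal
screen. Dayhoff-6 recoding maps the 20 amino acids onto the six exchange
groups (AGPST, DENQ, HKR, ILMV, FWY, C), written as digit states; recoded
data can be analysed under a 6-state GTR (exchangeabilities estimated at
fixed branch lengths obtained under the fast Poisson path, then lengths
re-optimized) or the 6-state CAT surrogate.

## The synthetic generator

`gene_set_spec()` defaults define the reference study: 16 taxa (2
outgroup, 2 L, the focal M, 11 others), 300 genes with lengths uniform on
300-1200, per-gene Gamma shape uniform on 0.5-1.5, topology proportions
(LM, L, M) = (0.44, 0.31, 0.25), and a 5-profile mixture whose profiles
concentrate 80% of their mass on one biochemical group each. The three
hypothesis trees differ *only* in the focal taxon's attachment, with short
(0.05) contentious branches at the ingroup root - a near-polytomy.
Lineage bias replaces $\pi$ by $(1-\lambda)\pi + \lambda\tau$ on every
branch inside a chosen clade (stem included by default), emulating a
compositional shift originating on the stem lineage.

What the generator deliberately does **not** model: the population
process behind the signal mixture (gene topologies are drawn iid from the
three hypotheses - there is no coalescent branch-length signature),
indels and alignment error, site-specific rates beyond Gamma, covarion
behaviour, or non-stationarity beyond the single bias construct. Passing
tests therefore demonstrate calibration and power of the *statistics*
under a clean multi-signal process, not robustness to every real-data
pathology.

## Problem sizes used by the checks

The package's workflow-level checks run at desk scale, chosen once: the
census study uses 300 genes of 2,000 sites on 16 taxa (gene trees for the
large census come from neighbour joining, which at this length recovers
the ML topology essentially always; the model-based NNI path is validated
on smaller sets); single-signal trials use 20 replicates of 15-gene sets;
adequacy uses 20 calibration trials and 10 ordering replicates at 20
taxa x 2,000 sites with $N = 100$ simulations; AU calibration uses 200
replicates of 500 sites on 8 taxa under a rate-homogeneous
site-heterogeneous mixture; the compositional null uses 500 replicates of
20 taxa x 1,000 sites; jackknife defaults are 10 replicates x 5,000 sites
(the full-scale analogue of this design draws 50,000). The analysis
scripts under `analysis/` run the same stages on the default study.

## Known limitations

* The CAT surrogate is a point-estimate finite mixture; it cannot express
  posterior uncertainty in profile assignments, and its K must be chosen.
* PMSF posterior-mean profiles are slightly flatter than the profiles a
  site was generated from; on data where the learned mixture is already
  well specified the PMSF adequacy Z is marginally worse than the parent
  mixture's. The workflow contrast (PMSF vs fixed dictionary vs
  homogeneous) is unaffected.
* The bootstrap is standard Felsenstein/RELL, not ultrafast bootstrap;
  CUBS values are comparable in construction but not numerically.
* Unrooted trees with exact likelihood ties resolve deterministically by
  input order.
* The dense (non-Poisson) path scales as states^2 per pruning step and is
  intended for the 6-state recoded analyses and small LG checks, not for
  20-state genome-scale searches.
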