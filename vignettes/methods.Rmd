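---
title: "Methods: comparing structural and transcriptome-derived brain connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing structural and transcriptome-derived brain connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectosync)
```

# The question and the two connectomes

White matter tracts physically couple grey-matter regions; regions that are
coupled may also synchronize transcription. `connectosync` implements both
halves of that comparison — a structural connectome from probabilistic
tractography outputs and a genomic connectome from cross-region expression
correlation — together with the pathway-level and blood-level analyses that
sit on top, and a synthetic-data module that generates every input with
planted ground truth.

The package deliberately works from *derived* imaging artifacts (path-count
volumes and a label volume), not raw scans: tractography, segmentation and
diffusion preprocessing are upstream tools' jobs and out of scope here.

# Reach probability

For tract $t$ with voxel path counts $c_t(v)$ and ROI $r$ with one-voxel-deep
white-matter-facing boundary mask $M_r$ (an ROI voxel is in $M_r$ iff it has
a face-adjacent white-matter voxel; 6-connectivity by default, 26 available),
the support is trimmed to white matter plus all boundary masks, and

$$\mathrm{reach}(t, r) = \frac{1}{|M_r|} \sum_{v \in M_r} \frac{c_t(v)}{T_t},
\qquad T_t = \sum_{v \in \mathrm{trim}} c_t(v).$$

Design choices worth stating:

* **Mass normalization.** $T_t$ is the *sum of per-voxel counts* over the
  trimmed support, not the streamline count; this makes the row a proper
  partition of the trimmed mass (the suite asserts the partition sums to 1)
  and is scale-invariant under count rescaling. A streamline-count variant
  would only rescale rows; the mass convention is the one whose magnitudes
  are compatible with the conventional 0.002 cutoff.
* **Zero-count mask voxels count.** They contribute zeros to the average;
  excluding them would reward tiny masks.
* **Boundary restriction.** Averaging inside the full ROI would reward
  within-ROI streamline propagation; the one-voxel border isolates genuine
  arrival at the grey-white interface.

**Thresholding.** Two modes: a fixed cutoff (0.002 is the reproduction
default on real data) and an automatic elbow: sort the non-zero values,
anchor the ECDF curve at $(0, 0)$, and take the abscissa maximizing the
perpendicular distance to the chord to the last point (ties to the smallest
abscissa). With planted connections at a common mass scale and zero leak the
elbow lands on the smallest planted value and the planted set is recovered
exactly; values spread across several decades would instead be cut at the
largest gap, which is the intended behavior when leak noise is present. A
Gumbel (location, scale) moment fit of the non-zero values is attached as a
diagnostic, as the non-zero reach distribution is extreme-value shaped.

**Region-pair classes.** An expression-region pair is *tract-bound* iff some
tract is connected to mapped ROIs of both regions, and *AD-tract-bound* iff
such a tract is in the disease-associated list (default L-CAB, L-ILF,
L-SLFT, L-SLFP). AD-tract-bound is a subset of tract-bound: the partition is
not-bound vs tract-bound, with the AD flag carried separately, so the three
group sizes may sum to more than the number of pairs. At the default
synthetic configuration the 136 pairs split 72 / 64 / 43.

# Tissue-to-tissue correlation

Expression is residualized per gene on age, sex, post-mortem interval, pH,
ethnicity and Braak stage (dummy-coded least squares; aliased columns are
dropped with a warning). For each region pair, every cross-region gene pair
gets a Spearman correlation over shared subjects (average ranks for ties)
with the t approximation $t = \rho\sqrt{df/(1-\rho^2)}$, two-sided, and
pairs with $p < 10^{-8}$ are retained. Computation is blocked so memory is
proportional to the block, not to all pairs; constant genes are skipped and
counted.

**Degrees of freedom.** For raw matrices $df = n - 2$. Residualization
projects out the covariate span, so residual vectors live in a smaller
subspace and the plain $n-2$ formula anti-conservatively overstates the
degrees of freedom: at $n = 40$ with an 8-column design the null exceedance
at $\alpha = 10^{-3}$ triples. `residualize_expression()` therefore records
the design rank and `ttc_all_pairs()` subtracts it (beyond the centering
already implicit in correlation), restoring binomial-level calibration. The
adjustment is explicit (`df_adjust`) and defaults to 0 for raw input.

**Top-decile enrichment.** Pairs are ranked by significant-pair count, the
top $\lceil 0.1N \rceil$ marked (ties broken by pair id, giving 14 of 136),
and a one-sided (greater) Fisher exact test asks whether a binding class is
over-represented among them. Sidedness is a flag; over-representation is
the default question.

# Bipartite modules: Barber modularity and LPAb+

Retained TTC pairs form a bipartite graph (genes of region A on one side,
region B on the other). Barber modularity compares within-module edges to a
degree-preserving bipartite null:

$$Q_B = \frac{1}{m}\sum_{i \in \mathrm{bottom}}\sum_{j \in \mathrm{top}}
\left(A_{ij} - \frac{k_i d_j}{m}\right)\delta(g_i, g_j).$$

`lpab_plus()` maximizes it in two stages. Stage 1 gives every node a unique
label and sweeps nodes in seeded random order; a node adopts the neighbor
label with the best marginal contribution $e_i(\ell) - k_i D_\ell / m$,
accepting only strict improvements (ties to the smallest label id), so $Q_B$
is non-decreasing and convergence (a sweep with no changes; cap 100 sweeps
with a warning) is guaranteed. Stage 2 greedily merges module pairs sharing
at least one edge while any merge increases $Q_B$ — evaluating only
edge-sharing pairs avoids quadratic work over non-interacting modules. The
whole procedure restarts five times by default from child seeds
(`stream_seed(seed, restart)`), returning the best labeling (ties to the
first restart). On graphs small enough to enumerate every set partition the
two-stage heuristic with 20 restarts attains the exhaustive maximum in the
suite; that is an observed property of small instances, not a guarantee.

Modules with strictly more than `min_edges` internal interactions (1000 at
reproduction scale; configurable for desk-scale runs) are kept, and their
member genes pooled per tissue, deduplicated.

# Pathway layer

Over-representation is the hypergeometric upper tail (one-sided Fisher) of
the pooled list against each catalog pathway with a fixed background
(20,996 human genes for real catalogs; the synthetic catalog uses its own
universe size so null enrichment stays calibrated). BH-FDR is applied *per
gene list across pathways* — the conventional over-representation family —
and binarized at $q < 0.05$; with a 169-pathway catalog and 136 region
pairs, 22,984 pathway-pair tests are recorded. Eight categories
(biosynthesis, signaling, disease, physiology, development, gene
regulation, metabolism, catabolism) and signaling subtypes (synaptic,
immune, synaptic-immune, endocrine, unclassified) annotate the catalog;
Drosophila-specific entries are filtered at load. A pathway enriched on
both sides of a pair is *symmetrically* synchronized, on one side
*asymmetrically*.

Interaction analysis binarizes associations per side, forms
$M[p,q] = \mathbb{1}\{p \text{ on ROI1}\} \cdot \mathbb{1}\{q \text{ on ROI2}\}$,
and symmetrizes by element-wise max (region-pair order is arbitrary; the
diagonal is exactly symmetric synchronization and deliberately participates,
contributing self-loops of degree 1). Group proportions are mean adjacency
matrices per class; each cell is compared against the not-bound reference
with the closed-form 2x2 chi-square without continuity correction (the
count-based 2x2 is the only well-defined reading; Yates is a flag), and
cells with $p < 0.05$ become graph edges whose degrees rank pathways. An
optional Ward clustering of the $-\log_{10} p$ matrix is available for
reporting; memberships are not asserted anywhere.

# Tract statistics

Each diffusion measure is regressed on numeric diagnosis severity
(CN=0 < MCI=1 < Dementia=2) plus age, sex and TBV, after one pass of 3.5-SD
outlier removal on the raw measure within cohort (ties at the cut retained;
no re-trimming — asserted by construction). The severity coding yields the
single effect size $\beta$ that effect-size tables report; a two-dummy
categorical variant exists but is not the default. BH-FDR is applied within
cohort over all tract-measure combinations, and replication requires
$q < 0.05$ in both cohorts *and* sign concordance of $\beta$. The covariate
screen reports $-\log_{10} p$ per covariate before and after age/sex/TBV
adjustment, with adjustment terms entered first so an aliased screened
covariate is the one dropped (flagged, $p = 1$) rather than silently
re-labeled.

# Blood gene-set association

Probe-level expression collapses to gene level by mean-max: the probe with
the highest mean across subjects represents the gene (ties to the smallest
probe id; unmapped probes dropped and counted). Each gene's Wald
$\chi^2 = (\hat\beta/\mathrm{SE})^2$ comes from
`measure ~ expression + sex + age + RIN + plate`; the plate random intercept
of the original formulation is implemented as fixed-effect dummies, which
with a handful of plates is practically indistinguishable for the expression
coefficient and keeps the permutation scheme exact. The set statistic is the
sum of per-gene $\chi^2$; the null permutes the subject assignment of the
whole expression matrix (rows together, preserving inter-gene correlation —
the property a sum statistic is sensitive to) against fixed measure and
covariates, and $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) /
(1 + n_\mathrm{perm})$, the add-one convention that cannot return 0.
Internally the per-gene $\chi^2$ is computed by the partial-correlation
identity $\chi^2 = df\, r^2/(1-r^2)$ after QR residualization — algebraically
identical to the per-gene regression (asserted in the suite) and fast enough
for $10^5$ permutations. $n_\mathrm{perm} < 100$ is refused; 100,000 is the
reproduction default, 499–999 the test scale.

# The synthetic-data module

One `synth_config()` drives all generators; a single master seed fans out to
per-dataset child seeds via `stream_seed(seed, stream)` (documented additive
derivation, base R Mersenne-Twister), so each dataset is reproducible alone
and full runs are byte-identical. Truth records are returned separately and
written to a separate JSON; no pipeline stage reads them.

What it emulates, and how:

* **Volumes** are deterministic constructions: a central white-matter slab
  with ROI patches tiled on the two adjacent layers, so every ROI has a
  boundary mask by construction; tract volumes place configured fractions of
  a tract's mass uniformly on planted ROI masks (leak rate configurable,
  default 0) and the rest on white matter. Defaults plant a connection
  pattern over the 17-region map that reproduces the 72/64/43 class split.
* **Expression**: Gaussian margins, shared-latent-factor blocks
  ($x = \sqrt{\rho} f + \sqrt{1-\rho}\,e$, so every cross-block pair has
  population correlation $\rho$ — the closed form used for calibration),
  covariate confounding with per-gene random loadings on a shared design
  (age, sex, PMI, pH, ethnicity with 3 levels, Braak), 40 subjects by
  default (inside the realistic 30–51 shared-subject range). Real microarray
  data are not Gaussian; this is noted, not asserted — passing tests show
  the pipeline's statistical behavior, not platform realism.
* **Phenotypes**: a 499-subject discovery cohort (diagnosis mix 347/118/34)
  with measures = standardized covariate effects + $\beta \cdot$ severity +
  noise; the default plants the 11 replicated tract-measure effects at
  $|\beta| = 0.5$ (positive for diffusivities, negative for FA).
* **Blood**: a 102-subject cohort, 200 genes with 1–4 probes each (plus a
  few unmapped probes), RIN and plate batch structure, and a 49-gene
  immune-signaling target set whose summed expression drives one designated
  measure. A 169-pathway catalog with category/subtype annotations always
  contains the target set.

Gene counts per region default to 200 — a desk-scale stand-in for a
genome-wide panel; full 20k-gene runs are a cluster-mode contract, exercised
here only through the blocked-computation design.

# Numerical and testing choices

* Discrete test statistics (Fisher/hypergeometric) have conservative,
  lattice-valued p-values; calibration tests that assert uniformity under
  permuted labels therefore use the randomized-p construction
  $u\,P(X=x) + P(X>x)$, which is exactly U(0,1) under the null, before the
  KS test. The raw p is what users see; the randomization exists only to
  make the calibration check sharp.
* Binomial-CI checks for type-I error use 400 replicates; the permutation
  type-I check uses $n_\mathrm{perm} = 499$ where $P(p \le 0.05)$ is exactly
  0.05 by the lattice. Recovery suites use 100 cohort replicates
  ($\beta = 1$, noise 0.5, $n = 300$), 50 seeds of the planted 3-block
  bipartite model (30x30 blocks, densities 0.3/0.01), and retention of a
  planted $\rho = 0.9$, 50x50 block at $n = 40$ averaged over 5 plantings
  (a single shared-factor draw makes the one-dataset fraction fluctuate).
  These sizes keep the default suite under a couple of minutes while leaving
  the assertions statistically meaningful.
* All brute-force oracles (step-up FDR, hypergeometric tail sums, the
  literal double-sum modularity, exhaustive partition search, voxel-loop
  reach) live in the test helpers, independent of the production paths they
  check.

# Known limitations

* The ECDF elbow assumes the planted/non-planted mass scales are separated;
  connection strengths spread smoothly over decades will be cut at the
  largest internal gap.
* LPAb+ is a heuristic; global optimality is only verified on enumerable
  instances, and dense single-block graphs have near-zero modularity where
  any split is as good as none.
* The Spearman p is the t approximation throughout; at $n \approx 30$ and
  $\alpha = 10^{-8}$ exact permutation p-values are computationally out of
  reach and the approximation is the declared contract.
* The synthetic generators make no attempt at MR physics, scanner/site
  effects, realistic tract geometry, or microarray noise families; their
  purpose is planted-truth testability, not data realism.
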