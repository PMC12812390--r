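---
title: "Methods: episignature detection from nanopore methylation calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episignature detection from nanopore methylation calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoepisign)
```

## The problem

An episignature is a disorder-specific DNA methylation pattern at a curated
set of array probes. Detecting one from nanopore sequencing requires three
conversions that are each easy to get subtly wrong: per-strand sequencing
calls must be pooled into strand-agnostic CpG measurements, read counts must
become array-comparable beta values, and probe lists published against one
array manifest version must be carried to another. Only then do the actual
analytics — concordance, clustering, embedding, classification — mean
anything. This vignette records the model, the parameter choices, and the
numerical decisions behind each stage.

## From reads to betas

**Coordinates.** Everything internal is 0-based, half-open (the bedMethyl
convention); array-manifest positions (1-based) are converted exactly once,
at the file boundary. A CpG is keyed by the position of its forward-strand
C. One internal convention, converted only at I/O, is the cheapest insurance
against off-by-one drift between the two ecosystems.

**Strand collapsing.** A CpG dinucleotide yields a forward-strand call at
position $p$ and a reverse-strand call at $p+1$. Array probes interrogate
the CpG regardless of strand, so both calls are pooled into one site keyed
at $p$; an unpartnered reverse call is keyed at $p-1$. Counts are summed,
never averaged, so pooling is exactly conservative. Pooling is the default
because it doubles effective depth; per-strand analysis remains possible by
skipping `collapse_strands()`. No hemimethylation discordance filter is
applied by default — discarding strand-discordant sites would silently
change the estimand.

**Beta values.** For a probe whose CpG site carries $m$ methylated of $n$
valid reads, $\hat\beta = m/n$. This is the maximum-likelihood estimate
under the binomial read model and is used as-is: no background correction,
dye-bias or BMIQ-style adjustment is meaningful for sequencing-derived
fractions, and the comparison against array betas is deliberately raw.

**Coverage threshold.** `min_valid` (default **5** pooled reads) is the
minimum depth for a beta call; probes below it are reported as missing
rather than estimated. Five reads bounds the binomial standard error at
$\sqrt{0.25/5} \approx 0.22$ — coarse, but a call; the threshold is a
user-facing dial and is recorded per run. Genome-wide QC summaries (e.g.
fraction of calls at ≥ 20×) are a separate, descriptive matter and are not
used to filter extraction.

**Missingness.** Merging profiles into a matrix intersects the probes
defined in every column and warns with per-sample attribution. Imputation
(`impute_mean = TRUE`) exists but defaults off: at signature probes,
imputed values would manufacture exactly the signal being tested for.

## Manifest harmonization

A v1-defined probe list maps to v2 through an explicit manifest column:
each probe present on v2 contributes its v2 identifier (which may differ
from the v1 ID), the rest are dropped, and the mapped and dropped sets
always partition the input — a property cheap to guarantee and invaluable
for auditing. One-to-many v1→v2 relations are rejected at load time; if a
locus has replicate v2 probes, the manifest must designate one primary.
No genome-build liftover is attempted.

## Analytics

**Concordance** is the plain Pearson coefficient over the signature probes
for named sample pairs, refused (not silently `NA`ed) for constant input.

**Clustering** is agglomerative with Euclidean distance and complete
linkage (`stats::hclust`), whose merge heights are provably non-decreasing;
dendrograms export as Newick. The test suite checks the merge sequence
against an exhaustive $O(n^3)$ reference implementation on all small inputs.

**Classical MDS** is Torgerson scaling — eigendecomposition of the
double-centered squared distance matrix (`stats::cmdscale`) — with one
added convention: each axis is flipped, if needed, so its largest-magnitude
coordinate is positive, making output platform-stable. Requesting more
dimensions than there are positive eigenvalues is an error, except for the
fully degenerate all-identical input, which embeds at the origin. Point
sets that genuinely span two dimensions are recovered to $10^{-8}$.

**UMAP** is implemented in-package (no R implementation was available to
build on): smooth-kNN kernel with local connectivity 1 and bandwidth found
by 64-step bisection to hit mass $\log_2 k$, fuzzy-union symmetrization,
output-kernel coefficients $(a, b)$ fitted by Nelder–Mead least squares to
the `min_dist` curve, spectral initialisation from the normalized graph
Laplacian (sign-fixed like MDS, scaled to a $[-10, 10]$ box), then SGD on
the fuzzy cross-entropy with 5 negative samples per edge and a linearly
decaying learning rate. All randomness lives in the SGD phase and is driven
by the explicit `seed` argument (default 15, the package's reference
setting), so a fixed seed reproduces coordinates bit-for-bit; the caller's
RNG stream is saved and restored. Defaults: `n_neighbors = min(15, n-1)`,
`min_dist = 0.1`, 200 epochs — recorded in the result's `params` for
provenance. UMAP needs at least 4 samples; smaller sets are directed to
MDS.

## Classification

The reference model (`episign_fit()`) holds two decision rules over the
signature probes.

**Nearest-centroid score (primary).** With $d_{case}$ and $d_{control}$
the Euclidean distances to the labeled reference centroids,
$$ s = \frac{d_{control} - d_{case}}{d_{control} + d_{case}} \in [-1, 1], $$
positive iff $s > 0$. The score is parameter-free, exactly antisymmetric
under swapping the reference labels, and hits $\pm 1$ exactly at the
centroids — properties the tests assert literally. The tie $s = 0$ is
resolved to **negative**: for a diagnostic-style label the conservative
direction is to not call. Samples must cover at least 90 % of the signature
probes; below that, classification aborts naming the missing probes rather
than scoring a different signature than advertised.

**Linear SVM (secondary).** A soft-margin linear SVM
(`e1071::svm`, cost 1, inverse class weights, no feature scaling — betas
already share a scale). Margins are oriented so positive favors case.

**Leave-out validation.** `centroid_loo()` rescores every reference sample
against centroids rebuilt without it. `svm_loo_validate()` does the same
for the SVM but, by default, with *class-balanced folds*: each fold drops
the held-out sample **and one opposite-class sample** (deterministic
cycling). Plain leave-one-out has a well-documented pathology when probes
far outnumber samples: the held-out sample's class is under-represented by
one, the training points are linearly separable noise, and the max-margin
bias term places the independent held-out point on the majority side — so
null-data accuracy collapses toward 0 (an anti-learning artifact, not
signal). Balancing the class decrement restores the symmetry under which a
signal-free reference scores at chance while a genuinely shifted one still
validates perfectly. Plain LOO remains available via
`balance_folds = FALSE`.

**Specificity.** `specificity_check()` scores the case/control silhouette
of the matrix restricted to the target probe set against size-matched decoy
sets. The silhouette is computed over the full Euclidean geometry of the
restricted probes — equivalently over *all* metric-MDS coordinates — not
over a 2-D projection. The reason is distributional: projecting $n$
exchangeable samples onto their two leading axes selects exactly the
directions in which chance grouping is largest, giving the null statistic a
heavy upper tail, whereas in the full restricted-probe geometry distances
concentrate and a signal-free probe set scores near zero. The 2-D
embeddings remain the visualization companion, and the end-to-end
separation checks on UMAP/MDS coordinates are intentionally kept on the
2-D view.

## The synthetic-study generator

The generator (`simulate_study()`) emulates the statistical structure of a
small episignature study; its defaults are the package's reference
conditions and are not retuned per analysis.

| Parameter | Default | Meaning |
|---|---|---|
| `n_signature_probes` | 203 | v1-defined signature size |
| `n_v1_only_probes` | 24 | signature probes absent from v2 (→ 179 mapped) |
| `delta` | 0.15 | case mean beta shift at signature probes |
| `mean_depth` | 30 | target pooled reads per CpG (× coverage) |
| `n_controls`, `n_cases` | 20, 5 | reference cohort |
| `mix_low`, `mix_high` | Beta(2, 18), Beta(17, 3) | control beta modes (means ≈ 0.10 / 0.85) |
| `mix_weight` | 0.5 | low-mode probability |
| `noise_sd` | 0.03 | per-sample Gaussian beta noise |
| `depth_model` | `"poisson"` | per-CpG depth law (`"fixed"`, `"nbinom"` available) |

Control probe means are drawn from the bimodal mixture (the hallmark shape
of genome-scale methylation); each sample adds Gaussian noise, and case
samples add a **uniform** shift `delta` at the harmonized signature probes
(per-probe published effect sizes live in external supplements, so the
uniform shift is the minimal structure supporting every analysis here; a
per-probe vector can be passed instead by editing the truth betas). All
probabilities are clipped to $[0.01, 0.99]$ before binomial sampling.
Sequencing counts are drawn per CpG: depth from the depth model, split
binomially between strands, methylated reads Binomial(strand depth, β) per
strand — so the pooled methylated count is Binomial(depth, β) exactly, and
truth records retain realized depth and counts, making exact recounting
oracles possible.

Two modelling notes on the depth law. Poisson is the default for analytic
tractability; negative-binomial overdispersion is available. The binomial
calibration property — at depth $d$, at least 99 % of probes inside
$3\sqrt{\beta(1-\beta)/d}$ — is a statement about the binomial estimator
*at* depth $d$ and is therefore validated under `depth_model = "fixed"`:
under Poisson depth the nominal-$d$ band is misspecified for the low-depth
draws and the exceedance at $d = 10$ rises above 1 % for reasons that have
nothing to do with the estimator.

What the generator does **not** emulate: basecalling error structure,
mapping bias, per-read modification probabilities, array chemistry
(detection p-values, bead counts), batch effects, cell-type composition,
and correlated probe blocks. Passing tests therefore demonstrate that the
pipeline's arithmetic, bookkeeping and decision geometry are correct under
the stated statistical model — not that any real cohort will separate.

## Problem sizes used in validation

The shipped validation suite runs at desk scale, chosen to make each
property statistically decisive: exact oracle equivalence on a 1,000-probe
× 25-sample study; calibration on 10,000 probes per depth (the $d = 10$
exceedance sits near 0.8 % in expectation, so 10,000 probes give a
standard error well under the 1 % margin); 100-replicate null and
specificity studies; 200-replicate concordance checks. The null SVM check
is scored against an exact binomial band around ½, which by construction
is a 5 %-level test — an occasional out-of-band run on some seed is the
expected behavior of the band, not a defect.

## Known limitations

* The classifier is validated against user/synthetic references, not
  against any proprietary clinical reference database; scores are
  comparable within a reference set, not across laboratories.
* The uniform-shift signature model understates the heterogeneity of real
  per-probe effect sizes; silhouettes and scores on real data will be
  lower than on the generator's output at equal `delta`.
* UMAP at very small $n$ (< ~8) is dominated by its initialisation;
  prefer MDS there.
* Manifest harmonization requires an explicit `v2_id` column; it does not
  infer mappings by genomic position, by design.
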