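---
title: "Combining disease signatures across datasets for connectivity mapping"
author: "mdcmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining disease signatures across datasets for connectivity mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Connectivity mapping matches a disease *query gene signature* — an ordered
list of genes, each tagged `+` (up-regulated in disease) or `-`
(down-regulated) — against a reference database of compound-induced
expression profiles, to find compounds whose transcriptional effect
*reverses* the disease state. The quality of the query signature decides the
quality of the hits, and signatures derived from a single expression study
are notoriously unstable: a gene can be strongly significant in one
tumour/normal cohort and invisible in the next, or even change apparent
direction. Taking the intersection of per-study gene lists discards exactly
the genes that are informative in most — but not all — studies.

`mdcmap` implements an alternative: score every gene in every study on a
common, dimensionless scale, and let the studies vote.

## Signed normalized rank scores

Within one paired tumour/normal dataset, each gene is tested with a
classical paired t-test on the per-subject log2 differences. The
significance cut-off is adaptive,

$$p < \frac{1}{\pi_0 N},$$

where $N$ is the number of genes analysed and $\pi_0$ the estimated
proportion of non-differentially-expressed genes. Under this threshold the
expected number of false-positive genes per dataset is about one. $\pi_0$
estimation is a standard multiple-testing primitive, so the package
delegates it to `limma::propTrueNull()` (local-FDR flavour by default);
`estimate_pi0(method = "fixed")` substitutes a user-supplied value, which
keeps the threshold formula exactly reproducible in tests. The two-sided
test was chosen because both regulation directions carry signal downstream.

The $M$ significant genes of a dataset are ordered by p-value
(ties broken by larger $|t|$, then lexicographic gene id — the ordering
must be total because rank positions enter the score) and the $i$-th gene
receives

$$\mathrm{Score}_i = \frac{M - i + 1}{M},$$

signed by its regulation direction. Dividing by $M$ makes scores comparable
between a study with 4000 significant genes and one with 7: the
under-powered study's few genes still score near 1, but there are almost
none of them, so it contributes little to any sum — under-powered studies
down-weight themselves without explicit weights.

A biological-significance filter zeroes the score of significant genes with
less than a 2-fold change ($|\overline{\Delta\log_2}| < 1$, computed from
the mean of per-pair differences, consistent with the paired test). Two
details here were genuinely open and are fixed as package policy:

* **Zeroing happens after rank assignment.** Genes failing the fold filter
  consume their rank position $i$; survivors keep the score of their
  original position rather than being re-ranked. Re-ranking would change
  every score below the first filtered gene, and the published worked
  example's fractional scores derive from positions among *all*
  statistically significant genes.
* **Fold change** is $2^{\overline{\Delta\log_2}}$ (paired geometric-mean
  ratio), not a ratio of group means.

Scores are then summed per gene across the $D$ datasets, and genes are
ranked by $|\mathrm{TotalScore}|$ descending (ties: more contributing
datasets first, then gene id). A gene regulated oppositely in two studies
has its contributions cancel; only genes consistently strong in the same
direction stay at the top. Genes with total exactly 0 carry no direction
and are never admitted to a query signature.

The packaged worked example (`worked_example()`) reproduces this
arithmetic on the published per-dataset score columns of 15 genes; five of
the published totals differ from the exact column sums by 1–2 in the fourth
decimal because the published per-dataset scores are themselves rounded to
four decimals. The tests assert exact equality for the ten clean rows and
$|\Delta| \le 2\times10^{-4}$ for the five rounding-limited rows.

## Connectivity scoring and its null

A reference profile stores, for each of the $N$ universe genes, a signed
rank: magnitude $N$ for the gene most perturbed by the compound, 1 for the
least, the sign giving the regulation direction. For a signature of length
$m$ with signs $s_i$ the connection score is

$$c = \frac{\sum_{i=1}^{m} s_i\, R(g_i)}{\sum_{j=0}^{m-1} (N - j)} \in [-1, 1],$$

the signed-rank sum normalized by its maximal attainable value, so $c = 1$
is perfect mimicry and $c = -1$ perfect reversal.

Significance is assessed against the null of a *random signature*: a
uniformly random gene subset of size $m$ with independent uniform signs.
Two evaluation modes share this definition:

* **Exhaustive** enumeration of all $\binom{N}{m} 2^m$ signed subsets,
  exact, used automatically when that count is at most $10^6$ (and as the
  oracle in the test suite).
* **Monte-Carlo** sampling with the $(r+1)/(n_{\mathrm{null}}+1)$ estimator,
  so p-values are never exactly zero. Every stochastic operation takes an
  explicit integer seed.

P-values are one-sided in the direction of the observed score (the
procedure explicitly filters on negative scores); fixed-tail variants are
exposed because a direction-of-observed p-value is uniform on $(0, 1/2)$
rather than $(0,1)$, and calibration studies need a fixed tail.

A compound with $K$ replicate profiles is scored by the mean of its
replicate scores. Its null is the mean of the *same* random signature's
scores across those $K$ replicates, so replicate-rich compounds have
tighter nulls — the z-score is the observed mean against this null's mean
and SD. One shared null-signature set prices every profile of the database
in a single call, which keeps compounds comparable and the engine fast. The
exact per-profile p-value and replicate-set statistic of published
connectivity-mapping frameworks are not restated in the literature this
package draws on; the null and aggregation above are this package's
documented contract.

A compound connection is declared significant when $p \le E_{fp}/N_c$,
where $N_c$ is the number of compounds in the database and $E_{fp}$ the
tolerated expected number of false-positive compounds (default 1; with
$N_c = 1309$ the threshold is $1/1309 \approx 7.6\times10^{-4}$).

## Choosing the signature length

Including every significant gene dilutes the prominent features of the
disease state, so the signature length $m$ is chosen by *progression*:
starting at $m = 1$, query the database with the top-$m$ signature, count
the significant hits $N_s$ in the desired (negative) direction, and stop at
the first $m$ whose empirical FDR

$$\mathrm{FDR} = \frac{E_{fp}}{N_s}$$

reaches the target (default 0.10, i.e. at least 10 hits when
$E_{fp} = 1$); if the ranked nonzero-total genes are exhausted first, the
state with the largest $N_s$ is returned with an exhausted flag. The
Monte-Carlo seed for length $m$ is derived as `seed XOR m`, so iterations
are independent, nothing is cached across lengths, and the whole trace is
bit-reproducible from the base seed.

## Perturbation stability

A hit worth pursuing should not hinge on a handful of signature genes.
Each hit compound is re-tested under perturbed signatures with `n_remove`
genes deleted; its stability is the fraction of perturbations under which
it stays significant at the same threshold and direction. The default mode
is exhaustive leave-one-out whenever $m \le 200$ (deterministic,
seed-independent); otherwise random deletion sets are drawn with a seed.
Stability is computed only for compounds significant under the unperturbed
signature, and only the hit compounds' profiles are rescored — the
significance threshold keeps the full database's $N_c$.

## What the synthetic data emulates

`generate_study()` draws, per gene, a Gaussian log2 baseline
(mean 8, SD 2, typical of microarray intensities); per subject, a Gaussian
offset (SD 1) shared by the tumour and normal samples — this is what makes
the design paired; and per sample, Gaussian noise (SD 0.5). Planted DEGs
shift the tumour sample by ±2 log2 units, are present in each dataset with
probability 0.8, and flip sign with probability 0.05 — the presence and
flip mechanisms exist precisely to exercise the cross-dataset
inconsistency the combiner is designed for. The default pair counts
(15, 19, 4, 18, 15) mix well-powered studies with one severely
under-powered 4-pair study; with 4 pairs the paired t-test needs
$|t| \gtrsim 15$ at the adaptive threshold, so that dataset ends with a
handful of significant genes and a near-zero score column, demonstrating
the automatic down-weighting.

`generate_reference_db()` gives null compounds uniformly random signed-rank
permutations. A planted inhibitor forces, in every one of its replicates,
the same `strength` fraction of the target signature's genes onto the
extreme rank magnitudes with opposite signs (mimics: matching signs); the
forced subset is a per-compound property, replicates differing only in
rank assignment and in the unforced genes. Replicate counts are drawn
uniformly from 2–8 (mean 5), emulating the roughly 4.7 replicate profiles
per compound of the large public reference collections.

The generator does **not** emulate probe-level artefacts, batch effects,
correlated genes, heavy-tailed noise, or compound profiles with biological
structure beyond the planted signature. Passing the planted-truth tests
therefore shows that the pipeline's machinery is correct and calibrated
under its own model assumptions; it does not show that real microarray
cohorts satisfy those assumptions.

## Numerical and scale choices

* Degenerate genes (zero variance of differences) get $t = 0$, $p = 1$,
  flagged, rather than propagating NaN.
* Score comparisons in the null tails use a $10^{-12}$ tolerance so that
  exhaustive and floating-point-computed observed scores tie correctly.
* The test suite runs the planted-truth study at 2000 genes, 5 datasets,
  200 compounds, with Monte-Carlo nulls of 1500 signatures, and the null
  calibration at 2000 draws of 2000 null signatures each — sizes chosen so
  the whole suite completes in about a minute on one core while leaving
  the stochastic assertions with comfortable margins.
* The pipeline writes plain UTF-8 TSVs plus a JSON manifest (package
  version, seed, configuration, per-stage counts); a rerun from the
  manifest's seed reproduces every output byte-identically.

## Limitations

The real-data path (paired tumour/normal microarray cohorts and a
compound reference database such as CMap02/LINCS) requires inputs this
package deliberately does not download or parse: raw CEL processing,
MAS5/RMA normalization and GEO retrieval are out of scope, and published
full-scale results (a 148-gene colorectal-cancer signature, specific drug
hits and their connection statistics) require those external resources.
The package documents the input formats so such data can be supplied as
TSVs; its own guarantees are the exact worked-example arithmetic, the
enumeration-verified scoring engine, the calibrated null, and
planted-truth recovery on synthetic studies.
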