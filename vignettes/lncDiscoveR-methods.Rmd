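---
title: "Models and design decisions in lncDiscoveR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in lncDiscoveR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncDiscoveR)
```

# The statistical problem

Long non-coding RNAs are expressed at far lower levels than most
protein-coding mRNAs — in tumor transcriptomes often below 10 reads per
transcript. A discovery design with only a few matched tumor/normal pairs
therefore faces two compounding problems: count noise dominates at low
abundance, and between-patient variation dwarfs the within-pair signal
unless the pairing is modelled explicitly. lncDiscoveR addresses this with
a paired count model for discovery, an independent large-cohort
confirmation step, and orthogonal validation statistics (qPCR rank tests,
correlation-rank enrichment, a co-expression network).

# Paired negative-binomial likelihood-ratio test

For feature $g$ and sample $i$, counts are modelled as
$y_{gi} \sim \mathrm{NB}(\mu_{gi}, \phi)$ with
$\mathrm{Var}(y_{gi}) = \mu_{gi} + \phi\,\mu_{gi}^2$ and log link
$\log \mu_{gi} = x_i^\top \beta_g + o_i$, where $o_i$ is the log effective
library size. Two nested models are fitted per feature:

* reduced: `~ patient` — one intercept per patient absorbs all
  between-pair variation;
* full: `~ patient + condition` — one extra coefficient for tumor versus
  normal, whose value divided by $\log 2$ is the reported log2 fold
  change.

The test statistic $2(\ell_{\text{full}} - \ell_{\text{reduced}})$ is
referred to $\chi^2_1$. The same machinery with `~ condition` versus
`~ 1` (`groupLRT()`) serves the unpaired confirmation cohort.

**Fitting.** Each GLM is fitted by iteratively reweighted least squares in
compiled code (weights $\mu/(1+\phi\mu)$, working response
$\eta - o + (y-\mu)/\mu$), declared converged when the largest coefficient
update falls below $10^{-8}$ within 100 iterations; the linear predictor
is clamped to $[-30, 30]$ to keep the weights finite. The reported
log-likelihood is the exact NB log-likelihood at the fitted means, with
$\phi < 10^{-10}$ treated as the Poisson limit. A reduced-model likelihood
exceeding the full model's by more than $10^{-4}$ is raised as an internal
error rather than clipped — it would indicate an optimizer failure.
Non-converged fits are reported with a missing p-value and all-zero
features are flagged untested, so the feature accounting is always exact.

**Normalization.** The TMM method: per-feature log-ratios (M) and average
log-abundances (A) against a reference sample, trimming 30% of M values
and 5% of A values from each tail, then a precision-weighted mean of the
surviving M values. The reference is the sample whose upper-quartile
expression (depth-scaled) is closest to the mean; factors are rescaled to
geometric mean 1. TMM is the natural choice here because the discovery
model follows the edgeR tradition of NB GLMs on raw counts with offsets;
the test suite cross-checks the factors against edgeR's implementation.

**Dispersion.** A single common $\phi$ is estimated by maximizing the
Cox–Reid adjusted profile likelihood
$\sum_g \big[\ell_g(\phi) - \tfrac12 \log\det X^\top W_g X\big]$ of the
full model, by bounded search on $\log\phi \in [\log 10^{-6}, \log 10]$.
With three pairs, per-feature (tagwise) dispersion estimation is too
unstable to be the default; the common estimate pools thousands of
features and, in the simulations the suite runs, recovers the generating
value closely. Features with identical counts in every sample carry no
dispersion information and are excluded with a message.

**Multiple testing.** Benjamini–Hochberg step-up adjustment, implemented
directly (adjusted $p_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$, capped at 1,
missing values propagated); the suite checks it against `stats::p.adjust`.
The discovery threshold FDR < 0.2 is deliberately permissive — with three
pairs, power is the binding constraint and the confirmation cohort
controls the false positives; the confirmation threshold is the
conventional FDR < 0.05. Both are exposed as arguments.

**Low-count filter.** Features with nonzero counts in fewer than 2 samples
are reported as untested (configurable via `minExpressedSamples`). The
filter is recorded in the result metadata rather than silently shrinking
the table.

# Dual-cohort confirmation

`confirmHits()` takes the intersection of features with discovery
FDR < 0.2 and confirmation FDR < 0.05 (strict inequalities) and, by
default, requires the effect direction to agree across cohorts —
confirmation of an up-regulated discovery hit by a down-regulated
confirmation signal would be spurious. Features absent from the
confirmation cohort are never confirmed. Censored significance entries in
printed tables (e.g. `<0.001`) are parsed as the midpoint of the censoring
interval (0.0005); this matters only for display since any censored value
below a threshold passes it regardless. Novelty is a case-sensitive exact
symbol lookup against a user-supplied known list — the package ships a
7-symbol example list but makes no attempt at literature mining.

# qPCR statistics

Relative expression is $2^{-\Delta Ct}$ with
$\Delta Ct = Ct_\text{target} - Ct_\text{reference}$; duplicate wells are
averaged on the Ct scale before differencing, and undetermined wells
propagate as missing (never zero, which would fake infinite
down-regulation). All group comparisons are rank-based, hence invariant to
whether $2^{-\Delta Ct}$ or $-\Delta Ct$ is analysed:

* **Wilcoxon signed-rank** (tumor vs matched normal): zero differences
  dropped, midranks for ties; for $n \le 25$ the exact two-sided p comes
  from the null distribution over all $2^n$ sign assignments, computed by
  dynamic programming over doubled midranks (identical to full
  enumeration, which the test suite verifies for every $n \le 10$); above
  that, the normal approximation with tie and continuity corrections.
* **Kruskal–Wallis** across tumor stages (CA = adenoma, I–IV), with tie
  correction and the $\chi^2_{k-1}$ reference.
* **Steel–Dwass** all-pairs comparison: for each pair of stages the
  rank-sum statistic on those two groups alone, standardized with the
  tie-corrected variance, and $q = |z|\sqrt 2$ referred to the
  studentized-range distribution with $k$ groups and infinite degrees of
  freedom. For $k = 2$ this collapses to the two-sided
  normal-approximation rank-sum test. Because the small-sample behaviour
  of the studentized-range limit is approximate, a permutation mode
  (`method = "permutation"`) calibrates the family-wise p against the
  permutation distribution of the maximum standardized statistic; the
  acceptance suite compares the default against a $10^5$-resample oracle.

`stagewiseAnalysis()` gates the pairwise table on a Kruskal–Wallis p below
`alpha` (default 0.05) and excludes stages with fewer than two tumors.

# Correlation ranking and rank-shift enrichment

Expression is transformed to $\log_2(\mathrm{CPM} + 0.5)$ on TMM effective
library sizes before correlation (raw counts are available behind a flag;
the log transform keeps a handful of extreme libraries from dominating the
Pearson statistic). Correlations are computed over tumor samples by
default, matching the cohort on which the network is defined. Rank 1 is
the most positively correlated feature; zero-variance features are
excluded and accounted for, ties are broken by feature id, and the target
is excluded from its own ranking.

The enrichment question — are a set's correlation ranks shifted toward the
positive end relative to background — is answered directly by a
Mann–Whitney rank-sum test on the ranks. This is the minimal faithful
reading of a rank-based GO enrichment on a correlation-ordered gene list;
graph-aware GO algorithms (term hierarchies, elim/weight decorrelation)
are deliberately out of scope. For rankings of $m \le 30$ features the
exact permutation null of the rank sum is used (subset-sum dynamic
programming); otherwise the normal approximation with continuity
correction, which the suite checks against enumeration at small $m$.

# Co-expression network

Vertices are the features differentially expressed in *both* cohorts
(discovery FDR < 0.2, confirmation FDR < 0.05), split into lncRNA and
protein-coding classes. Edges connect lncRNAs to protein-coding genes
only; with $P$ defined candidate pairs, the
$\lceil 0.005\,P \rceil$ most positive and most negative correlations
become edges. Three readings were genuinely open:

* *Fraction of what?* The 0.5% is taken over all candidate lncRNA–mRNA
  pairs globally (the closest literal reading); a per-lncRNA variant is
  not offered as a default because nothing in the source setup suggests
  per-hub thresholds.
* *Signed or absolute?* The percentile is over signed r — "strongest
  negative" and "strongest positive" are separate tails, not |r|.
* *Ceiling, not floor*, so a nonempty pool always yields at least one edge
  per sign; ties at the cutoff break by (lncRNA id, protein-coding id)
  lexicographic order, making the edge list deterministic regardless of
  iteration order.

Isolated candidate vertices are dropped by default (the drawn graph
contains only connected vertices); `keepIsolated = TRUE` retains them.
`hubReport()` ranks lncRNAs by degree and quantifies shared targets
between hubs by the Jaccard overlap of protein-coding neighbor sets.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the analysis is built for:

| Parameter | Default | Rationale |
|---|---|---|
| `nPairsDiscovery` | 3 | matched discovery pairs |
| `nTumorConfirm` / `nNormalConfirm` | 682 / 41 | confirmation cohort shape |
| `lncMeanCount` | 5 | lncRNAs "mostly less than 10" reads |
| `pcgMeanCount` | 200 | mRNAs far more abundant than lncRNAs |
| `logfcRange` | [3, 8] | range of planted \|log2FC\| |
| `dispersion` | 0.2 | BCV ≈ 0.45, typical of human tissue cohorts |
| `patientEffectSd` | 0.5 | substantial between-patient variation |
| `latentFactorLoading` | 1 | detectable co-expression at cohort scale |
| `plantedSetSize` | 40 | a mid-sized GO-like set |

Counts are NB draws with log-mean = baseline + patient effect +
condition × log2FC·log 2; patient effects are drawn once per patient and
shared by the pair, mirroring the paired design's patient regressor.
Per-sample depth factors are log-normal (sd 0.15 on the log scale) so
normalization is actually exercised; they can be disabled. The
confirmation cohort reuses the truth table's effects (hence concordant
directions) and adds a standard-normal latent factor, with the configured
loading, to the log-mean of the designated target lncRNA and every
planted-set gene *in tumor samples only* — correlations downstream are
computed across tumor samples, so that is where the structure must live.
qPCR pairs share a per-pair baseline ΔCt (mean 8 cycles — a low-abundance
transcript against a reference gene); the tumor ΔCt is shifted by
−`effectDeltaCt`, optional per-stage shifts allow planted stage contrasts,
and duplicate-well noise is a fifth of the biological noise.

What the generator does **not** emulate: read-level artifacts (mapping,
junctions, positional bias), correlated feature–feature structure beyond
the single latent factor, batch effects, GC/length biases, tumor purity
gradients and stage-dependent expression drift. Passing tests therefore
demonstrate statistical correctness of the methods under the generative
model they assume — not robustness to every failure mode of real RNA-seq.

# Problem sizes and seeds in the test and acceptance suites

The suites run at deliberately chosen sizes: 100 seeded replicates of
2000-feature null cohorts for type-I calibration, 500 planted features for
fold-change recovery, 1000 seeds for enrichment-null uniformity, a
$10^5$-resample permutation oracle for Steel–Dwass, and full enumeration
oracles at small $n$/$m$. These sizes give the calibration estimates
standard errors well inside the asserted bands while keeping a complete
run in the minutes range on one CPU. Every random draw flows from an
explicit seed, and `runPipeline()` writes a manifest with MD5 checksums so
a rerun with the same configuration is verifiably bit-identical.

# Known limitations

* The common-dispersion model ignores genuine dispersion heterogeneity;
  an empirical-Bayes tagwise mode is a natural extension but is not
  needed for the planted-effect regimes the package targets.
* The LRT's $\chi^2_1$ reference is asymptotic; at three pairs it is
  mildly liberal for very low counts, which the permissive discovery
  threshold plus confirmation step absorbs by design.
* The enrichment test treats genes as exchangeable — no term hierarchy,
  no correlation-aware null beyond the rank permutation.
* Network edges are marginal Pearson correlations; no claim of
  directness (partial correlation, mutual information) is made.
* Transcript- versus gene-level identifiers are treated opaquely; the
  package never attempts to collapse one to the other.
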