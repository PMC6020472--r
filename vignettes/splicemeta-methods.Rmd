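---
title: "Methods: direction-consistent meta-analysis of therapy-induced spliceosome changes"
author: "splicemeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direction-consistent meta-analysis of therapy-induced spliceosome changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicemeta)
```

# The scientific question

Many independent public expression studies compare cancer cells before and
after a therapeutic insult (platinum agents, taxanes, irradiation, hypoxia,
kinase inhibitors).  Each study alone is small and platform-specific, but a
pathway that is genuinely suppressed by therapy should leave the same
fingerprint in all of them: its genes move in the *same direction*
everywhere, and the per-study evidence, however weak individually, combines
into strong joint evidence.  `splicemeta` implements this meta-analytic
strategy, together with the companion analyses that probe the same biology
from other angles: recurrence of differential-splicing events (especially
retained introns) across treated samples, the reading-frame consequences of
intron retention, the temporal trajectory of spliceosomal gene expression
after treatment, transcription factors that may co-regulate splicing- and
mitosis-related genes, and exact set-overlap statistics for cross-omics
comparisons.

Everything runs on plain-text inputs (expression TSV, rMATS-style event
tables, FASTA, BED, GMT) or on synthetic data generated by the package with
known ground truth, so the full pipeline is exercisable and testable
offline.

# The meta-analysis model

## Per-dataset testing

Within one study, each gene is tested for a treated-versus-control
difference of log2 means with a moderated t-statistic.  Writing
$s_g^2$ for the pooled residual variance of gene $g$ on
$d_g = n_1 + n_2 - 2$ degrees of freedom, the gene variances are assumed
exchangeable around a scaled inverse-chi-square prior
$\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$, giving the shrunken estimate

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad
\tilde t_g = \frac{\bar x_{g,\mathrm{trt}} - \bar x_{g,\mathrm{ctl}}}
  {\tilde s_g \sqrt{1/n_1 + 1/n_2}},$$

referred to a t distribution on $d_0 + d_g$ degrees of freedom.  The prior
parameters $(d_0, s_0^2)$ are estimated by moment-matching the mean and
variance of $\log s_g^2$ against their digamma/trigamma expressions; the
trigamma equation is inverted by Newton iteration with a bisection
safeguard (relative tolerance $10^{-8}$), and estimates of $d_0$ above
$10^6$ are treated as infinite, in which case every gene simply uses
$s_0^2$.  With a single gene no prior can be fitted and the statistic
degrades gracefully to the ordinary pooled-variance t.  A Welch test with
Satterthwaite degrees of freedom is available as an unmoderated fallback.
Only the per-gene pair (p-value, sign of the difference) flows downstream,
which is what makes the combination step platform-agnostic.

## Combining studies

Given the per-dataset p-values $p_{g1}, \dots, p_{gk}$ of a gene measured
in $k$ studies, Wilkinson's order-statistic method uses the $r$-th smallest
value: under the joint null $p_{(r)} \sim \mathrm{Beta}(r,\, k - r + 1)$,
so the combined p-value is the Beta CDF at $p_{(r)}$.  The default $r = 1$
is Tippett's minimum-p rule, $1 - (1 - p_{(1)})^k$; $r = k$ gives
$p_{(k)}^k$.  $r$ is exposed as a configuration key because no single
choice dominates: $r = 1$ is sensitive to one strong study, larger $r$
demands breadth.  Benjamini–Hochberg FDR is applied *after* combination,
over the aggregated gene list.

Between-study heterogeneity is deliberately not modeled.  P-value
combination needs only per-study validity of the p-values, which is the
reason to prefer it over effect-size meta-analysis when studies span
incompatible platforms; the cost is that no pooled effect size is
estimated.

## The exclusive-direction filter

A gene enters the final set only if its difference has the same sign in
*every* contributing study (genes with an exact zero difference in any
study are excluded — a zero is neither up nor down).  This filter is what
turns "significant somewhere" into "concertedly shifted"; it is also very
conservative, and its consequences are quantified below under
*Statistical power at small sample sizes*.

By default a gene must be present in all datasets to be aggregated
(`min_datasets = NULL` means "all"), matching the all-studies consistency
requirement; relaxing `min_datasets` trades stringency for coverage.  An
optional `per_dataset_alpha` gate additionally requires each study's own
p-value to clear a cutoff before combination; it is off by default because
combining weak-but-concordant evidence is the point of the method.

# Splicing recurrence

Differential-splicing events arrive in the rMATS table dialect, one file
per event type (SE, A5SS, A3SS, RI, MXE), with 0-based half-open
coordinates.  Per-replicate inclusion levels are averaged per condition and
the inclusion-level difference is re-signed so that positive always means
more inclusion after treatment, regardless of which condition the caller
put in the "sample 1" slot.  Events are filtered at `FDR < 0.05` and
`|ΔIncLevel| > 0.05` — both strict, with the 5% read on the [0, 1]
proportion scale on which inclusion levels are reported.

Two events from different samples are *the same event* when they share
type, chromosome, strand, the full type-specific coordinate tuple, and the
sign of ΔIncLevel.  The gene symbol is intentionally not part of the
identity key: coordinates are sufficient and annotation versions drift.
Zero-difference events have no sign and therefore no key.  An event is
recurrent when it appears in at least `ceiling(f × n_samples)` samples
(default `f = 0.5`); the ceiling makes "at least half" well defined for
odd counts (9 of 17 qualifies).  Within one sample an event key is counted
once, and its per-sample mean ΔIncLevel feeds the recurrent event's mean.

# Retained introns and reading frames

For a transcript carrying a retained intron, the scan walks codons in the
annotated frame fixed by the CDS start and counts TAA/TAG/TGA codons that
overlap the intron interval by at least one base.  A stop straddling the
exon–intron boundary exists only because of retention, so boundary overlaps
are attributed to the intron.  All overlapping in-frame stops are tallied
(not just the first), because "multiple in-frame stops" is itself the
observable of interest; the first stop's offset is reported separately.
Only the annotated frame is scanned — whether the retained transcript can
still encode its protein is a frame-specific question.  Sequences must be
uppercase ACGT; ambiguity codes are rejected rather than guessed.

# Time-course soft clustering

Z-scored per-gene trajectories (replicates averaged within timepoints; at
least four timepoints) are clustered with fuzzy c-means: minimize
$\sum_{i,c} u_{ic}^m \lVert x_i - v_c \rVert^2$ subject to
$\sum_c u_{ic} = 1$, alternating the closed-form membership and center
updates.  Numerical choices:

* fuzzifier `m = 2` (the standard default for expression time courses);
* initialization draws `c` *distinct data rows* as starting centers under
  the caller's seed — reproducible and faster than random points;
* a point coincident with a center receives full membership there (the
  standard singularity rule), avoiding 0/0;
* convergence when the objective changes by less than `1e-6`; the
  objective trace is stored and is non-increasing by construction, which
  the tests assert at every iteration.

The cluster count `c` is not knowable a priori; `select_cluster_number()`
sweeps a range (default 4–12) and reports the minimum between-center
distance per candidate, suggesting the elbow (the point after which the
largest relative collapse occurs).  Both `c` and `m` are configuration
keys.  Hard assignments for enrichment use the argmax membership subject
to a 0.5 threshold; trend labels (increasing / decreasing / non-monotone)
are judged on the strict ordering of the converged center.

# Co-regulation network

Within each dataset, every (splicing-set gene, mitotic-set gene) pair is
tested by Spearman correlation — Pearson on average ranks, p-value from
the t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n - 2$ df, with
an exact permutation option for $n \le 8$.  BH-FDR is applied over the
full tested pair family within the dataset (the datasets are analyzed
independently, so the family is per-dataset), and a pair is retained when
$\rho > 0.7$ (strict) and $q < 0.05$.  The candidate gene sets are
user-supplied GMT entries, not hard-coded lists, to avoid freezing an
annotation version into the package.

A transcription factor qualifies in a dataset when its binding intervals
overlap the promoter windows of *both* members of at least one retained
pair; the promoter is the strand-agnostic window ±2000 bp around a single
canonical TSS (a conventional ChIP-seq promoter width; configurable), with
0-based half-open interval arithmetic and 1-bp minimum overlap.  The
reported factors are the intersection of the qualifying sets across all
datasets — adding a dataset can only shrink it.  The mapping of ChIP
experiments to a biological context is left to the user: the peak set is
an explicit input.

# Set statistics

Over-representation of a query set against a GMT collection uses the exact
hypergeometric upper tail; the overlap of two sets uses Fisher's exact
test on the 2×2 table.  The one-sided "greater" Fisher p and the
hypergeometric tail are the same number, which the tests assert to 1e-12
and validate against full enumeration of all draws for universes up to
N = 12.  The two-sided Fisher p sums the probabilities of all tables no
more probable than the observed one (the dominant convention; conventions
differ, so this is stated explicitly).  The background universe is a
*mandatory* argument everywhere: defaulting to "all known genes" silently
inflates significance, so the caller must pass what was actually measured
or detected.  Venn region counts for two or three sets come with
per-region annotation sub-counts (e.g. how many members of each region are
spliceosomal).

# What the synthetic data emulates — and what it does not

The generators reproduce the *statistical structure* the analyses assume,
with ground truth recorded:

* `gen_expression_multiset()`: per-dataset gene baselines
  `Normal(platform_shift, 1) × platform_scale` (platforms differ mildly in
  location and scale by default: shifts 7, 7.5, 8 and scales 1, 1.1, 1.2),
  a planted 100-gene "spliceosome" set shifted by −1 log2 unit in treated
  samples of every dataset, 3 datasets × (3 control + 3 treated) samples,
  and unit-variance Gaussian noise on the log2 scale — small two-group
  public studies with a halving of planted-gene expression.
* `gen_timecourse()`: template trajectories (gradually decreasing, its
  mirror, and a flat profile) over four timepoints (0, 6, 12, 24 h) plus
  Gaussian noise (sd 0.3), rows z-scored.
* `gen_splice_tables()`: rMATS-dialect files for 18 samples; planted
  events carry `FDR < 0.05` and |ΔIncLevel| drawn Uniform(0.1, 0.5) with a
  fixed sign (clear of the 5% boundary) in exactly `ceiling(f·n)` samples,
  with retained introns predominantly gaining inclusion, over a background
  of sample-specific random events about half of which fail the filter.
* `gen_transcripts()`: codon-structured CDS with a frame-aligned retained
  intron containing exactly the planted number of in-frame stops.
* `gen_tf_fixture()`: gene pairs driven by a shared latent factor in the
  datasets they are planted in (20 samples per dataset — rank correlations
  at the 0.7/FDR threshold need that many observations to be stable), and
  TFs with promoter peaks at both members of their pair.

All generators are deterministic given their seed.  What they do *not*
emulate: probe-level microarray artifacts, batch and lab effects,
correlated genes within pathways, heavy-tailed noise, read-level splicing
quantification noise, or annotation ambiguity.  Passing recovery tests on
these fixtures therefore demonstrates that the statistics do what they
claim under their own assumptions — not that real accession-level results
are reproduced, which would require the original raw data and external
aligners/callers.

# Statistical power at small sample sizes

One property of the default study conditions deserves emphasis.  With
3 datasets of 3 + 3 samples, unit log2 noise and a −1 log2 planted shift,
the per-dataset mean difference has standard error
$\sqrt{2/3} \approx 0.82$, so a planted gene goes the right way in one
dataset with probability $\Phi(1/\sqrt{2/3}) \approx 0.89$ and in *all
three* with probability $\approx 0.70$ — the exclusive-direction filter
alone caps recall near 70% no matter how the p-values are handled, and the
FDR cut lowers it drastically further (the package measures recall near
zero at these settings, with a false-positive rate of zero).  This is a
fact about two-fold changes in small noisy studies, not an implementation
artifact: recovery rises to ~92% at a −3 log2 shift with the same sample
sizes and to 100% at −2 with 8 + 8 samples.  Detecting subtle concerted
shifts is exactly why the original design combined *many* (up to nine)
datasets per condition rather than three.  Users simulating their own
designs should treat `gen_expression_multiset()` plus
`aggregate_datasets()` as a power calculator.

Similarly, two time-course clusters whose centers sit four per-coordinate
noise standard deviations apart are at the classical two-sigma-per-side
decision boundary: about 2.3% of genes fall on the wrong side of the
midplane, so the adjusted Rand index of hard assignments hovers around
0.89 by construction and clean recovery (ARI ≈ 1) requires either larger
separation or lower noise.  Flat templates deserve a special note: after
row z-scoring a flat noisy profile becomes a random direction on the
sphere, so "no-change" genes are intrinsically unassignable and drag down
any global clustering agreement metric — the package's own summaries
report agreement both over all genes and restricted to trended genes.

# Problem sizes and runtime

The shipped tests and the acceptance script use deliberately desk-scale
sizes chosen to make every statistical check stable yet quick: 2000-gene
expression matrices over 3 datasets (20 seeds for recovery claims),
10,000-gene uniformity checks for the combination rule, 5000-gene null
calibration of the moderated test, 100 random event tables (up to ~500
events) against a brute-force recurrence matcher, 1000 random transcripts
against an independent codon-walk oracle, and full enumeration of Fisher
tables up to N = 12.  A complete orchestrated run (`run_pipeline()`)
takes a few seconds on one CPU.

# Known limitations

* No effect-size meta-analysis (no pooled log2FC, no random-effects
  heterogeneity modeling) — combined p-values and directions only.
* Two-group designs only; no covariates, pairing or multi-factor layouts.
* The intron scan does not model NMD rules (e.g. the 50-nt boundary
  rule), translation efficiency, or genome-to-transcript liftover; it
  answers only whether the annotated frame acquires premature stops.
* One canonical TSS per gene; TF→context matching is the user's input.
* Enrichment runs against user-supplied GMT files; no live database
  queries, so database-version-specific p-values are out of scope.
* Raw array/read preprocessing (RMA, bead-array variance stabilization,
  aligner/caller execution) is upstream of the package by design.
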