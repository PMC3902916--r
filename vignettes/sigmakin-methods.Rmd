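---
title: "Kinetic inference of sigma-factor regulatory networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic inference of sigma-factor regulatory networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

During germination, a dormant bacterial spore reactivates its transcriptome
within hours. In *Streptomyces coelicolor* this transition is orchestrated
largely by sigma factors — subunits that direct RNA polymerase to specific
promoter classes — and a dense expression time series over germination
carries enough kinetic information to ask, for every sigma factor and every
gene (or group of co-expressed genes), whether the sigma factor's own
expression profile can *kinetically explain* the target's profile.

`sigmakin` implements that inference chain as a reusable pipeline:

1. per-array normalization of two-channel Log2Ratio values,
2. replicate outlier rejection and profile inference,
3. expression-level and replicate-variance gene filters,
4. consensus kinetic clustering with core profiles,
5. a sigmoid ODE model of transcription control fitted by simulated
   annealing,
6. correlation-thresholded network construction with prior-knowledge
   integration, and
7. Fisher-exact functional enrichment of the kinetic clusters.

Because the original microarray study data is an external download, the
package ships a synthetic-data generator that reproduces the *structure* of
such an experiment with known ground truth; every claim the test suite
makes is a claim about recovery of planted structure.

# The kinetic model

Transcript concentration $y_i(t)$ of a target gene $i$ under control of a
regulator with expression profile $R_j(t)$ follows

$$\frac{dy_i}{dt} = \frac{k_1}{1 + e^{-(w\,R_j(t) + b)}} - k_2\, y_i,$$

with maximal production rate $k_1$ (expression units/h), first-order
degradation rate $k_2$ (1/h), regulator weight $w$ (dimensionless) and
offset $b$ (a reaction delay in sigmoid units). $k_1$, $k_2$ and $w$ are
constrained non-negative; $b$ is free. The sigmoid captures promoter
saturation: below a regulator level set by $-b/w$ the gene is quiet, above
it production approaches $k_1$.

The regulator profile enters as a piecewise-linear interpolant of its 13
sampled values, clamped at the boundaries. Integration uses an adaptive
Dormand–Prince 5(4) pair with dense output. The default output tolerances
(`rtol = 1e-8`, `atol = 1e-10`) are chosen so that global error is far
below measurement noise — the relaxation closed form at $w = 0$ is
reproduced to better than $10^{-6}$ absolute over the full grid, which a
looser `1e-6` relative tolerance does not guarantee for profiles of
magnitude ~10. Inside the annealing loop a looser tolerance
(`sa_rtol = 1e-5`) is used — integration error there is orders of magnitude
below the correlation objective's sensitivity — and the winning parameter
set is re-simulated at the tight tolerances.

## Fitting

Parameters are estimated by minimizing $F = 1 - c$, where $c$ is the
Pearson correlation between the measured and simulated target profile; a
constant simulated profile scores the worst case $F = 2$ so annealing
chains survive degenerate proposals. Minimization runs 15 independent
simulated-annealing chains (`fit_config()`): uniform initial draws
($k_1, k_2 \in (0, 10]$, $w \in (0, 50]$, $b \in [-10, 10]$), Gaussian
proposals with per-parameter scales shrinking as $\sqrt{T}$, Metropolis
acceptance, geometric cooling ($T_0 = 1$, $\alpha = 0.95$, 200 proposals
per temperature, stop at $T \le 10^{-3}$). The restart with the lowest $F$
wins.

The proposal walk is reflected into $k_1, k_2 \le 20$, $w \le 100$,
$|b| \le 20$. Beyond those bounds the objective is flat: a degradation
rate much faster than the 30-min sampling interval makes the transcript
track its production term exactly, and a saturated sigmoid no longer
responds to the regulator — both regions are unidentifiable from 13
samples, and excluding them roughly halves runtime without constraining
any identifiable optimum.

Network screening evaluates thousands of candidate pairs. Because the
Pearson objective is invariant to the scale of the simulated profile, the
effective search space is small, and a reduced budget
(`screening_config()`: 6 restarts, 50 proposals per temperature,
$\alpha = 0.93$, stop at $2\times 10^{-3}$) reaches the same optima; this
was verified on single-pair fits before any recovery study was run.

# Preprocessing and filters

*Normalization.* Each array's Log2Ratio distribution is centered by
subtracting its median and dividing by its (unscaled) median absolute
deviation, so every array has median 0 and MAD 1 exactly; the 2% most
extreme values in each tail are masked (linear-interpolation quantile
convention throughout); centered values are exponentiated back to the
ratio scale.

*Profile inference.* Replicates at a time point are screened with the
Dixon Q test (3–9 values, 95% two-sided critical values) or Peirce's
criterion (10 or more; Gould's iterative solution), then averaged. Fewer
than 3 replicates are averaged untested — the tests are undefined there.
Ten replicates route to Peirce, closing the gap between the two rules'
classical ranges. A missing value flanked by present neighbours is
linearly interpolated in time; leading/trailing gaps mark a profile
incomplete. Missingness is an explicit mask, never the number zero.

*Gene selection.* A gene's overall expression level is the median of its
sample-channel intensities across all arrays. Genes below the first
quartile of these levels (category I) are dropped unless rescued by a
significant peak; the rescue rule — the gene's maximal per-time-point
sample-channel value reaches the global median level — is a documented
stand-in, since "significant peak" admits many formalizations, and is
scale-free in the quantities already computed. Peak detection applies the
same outlier rejection as profile averaging, so a single gross outlier
cannot manufacture a rescue. The variance gate keeps genes whose replicate
coefficient of variation (sd/mean of retained normalized ratios) stays
below 0.47 at eight or more of the 13 time points; undefined CVs do not
count toward the quota.

# Consensus clustering

Profiles are clustered by k-means under Spearman correlation distance
($1 - \rho$, average ranks): assignment to the nearest centroid in rank
space, centroid update as the per-time-point mean of members, empty
clusters re-seeded with the farthest profile whose donor keeps a member.
The run ensemble (default 500, study-scale; 100 in the validation studies)
is condensed into *cores*: the run with median J (within-cluster sum of
point-to-centroid distances) serves as reference, every other run's
clusters are matched to it by greedy maximal member overlap, and a gene is
a core member where it co-occurs in at least 50% of runs. Ties in the
modal cluster break toward the lower core id.

The cluster count comes from a jackknife scan: for each candidate n the
clustering is repeated with 1.5% of profiles omitted at random and J
recorded (mean ± sd). Each scan repeat keeps the best of several random
initializations (default 5) so the curve approximates the optimal J(n)
rather than local-minimum noise — single-init curves are too rough for
elbow detection. The elbow is the candidate with the largest discrete
second difference of J(n); a curve whose largest second difference falls
below 5% of the J range carries no elbow and the configured default (the
study value 42) is returned with a warning.

Post-hoc assignment attaches every (highly expressed, complete) gene to
the core with maximal Pearson correlation to its core profile when that
maximum reaches 0.8. Pearson is used here — matching the model-fit
criterion — although the clustering distance is Spearman; the choice is a
configuration knob (`method = "spearman"` is available).

# Network construction

Every requested (regulator, target) pair is fitted; a relation is accepted
when $c > 0.8$, or $c > 0.65$ when a ChIP or literature prior supports the
pair (strict inequalities, following the source thresholds' wording; the
cluster-assignment gate is $\ge 0.8$). Multiple accepted regulators of one
target are alternatives and are never merged or pruned. A relation is
*trivial* when the measured regulator and target profiles themselves
correlate at 0.9 or above — the kinetic delay is too small to orient the
edge. In the sigma–sigma screen, a pair accepted in both directions with
both directions trivial is flagged *mutual*; a prior supporting exactly
one direction marks it preferred, and both edges are retained. Networks
are exported as GEXF for Gephi with the fitted weight w as edge weight
(arrow thickness), plus correlation, trivial flag and prior source as
attributes.

# Enrichment

For each cluster (core members plus assigned genes) and each functional
class, a one-sided Fisher exact test on the 2×2 table against the highly
expressed universe gives the over-representation P; the fold change is the
class frequency in the cluster over its frequency in the universe. A class
is significant at P < 0.05, fold change > 2 and more than 7 class genes in
the cluster (strictly greater, i.e. $k \ge 8$). No multiple-testing
correction enters the flag, following the raw-P convention of the method;
a Benjamini–Hochberg column is emitted alongside for reference. Genes
without annotation form an implicit "unclassified" class; multi-class
genes count once per gene–class pair. Sigma factors are associated with a
class when they hold an accepted edge to a cluster in which the class is
significant; all alternatives are kept.

# The synthetic study

`synthetic_spec()` describes the generated data set; its defaults *are*
the study conditions of the validation suite and were fixed as follows.

**Design.** 13 time points at 30-min spacing; 6 replicate values per time
point, emulating 3 biological replicates with 2 replicate spots per gene
and array — the pooled replicate set the averaging step works on. (With
only 3 values the Dixon Q test has essentially no power: its n = 3
critical value is 0.970, so a single 10-fold outlier survives and corrupts
a time point. The original design's replicate spots are what give the test
its teeth.) Five regulators drive 20 targets each; 150 background genes
emulate the unregulated majority.

**Regulators.** Each regulator profile is a baseline plus a primary gamma
pulse and a secondary gamma component (a smaller pulse or a transient dip)
— biphasic activity profiles whose temporal fine structure survives the
model's monotone sigmoid warp and keeps regulators mutually
distinguishable. Candidate sets are drawn as a pool and a subset selected
by minimizing pairwise *kinetic confusability*: the best correlation any
coarse (w, b, k2) warp of one regulator achieves against the canonical
response of another, combined with the rank correlation of the canonical
responses themselves. Pairwise Spearman stays below 0.7 (the smooth
13-point shape family supports separation down to roughly 0.45). Profiles
are redrawn until they span at least a 4-fold dynamic range so their
measured versions are signal- rather than noise-dominated.

**Targets.** Targets of one regulator share base kinetic parameters with
10% relative jitter, so each regulon forms a planted kinetic group. Base
parameters are redrawn until the driven profile (i) spans at least a
4-fold dynamic range — germination induces transcription from near-dormant
levels, and an undriven gene is not a regulon member in any meaningful
sense; (ii) is distinguishable from an unregulated first-order relaxation,
which the model emits with $w \approx 0$ under *every* regulator and which
therefore carries no attribution signal; (iii) keeps Spearman correlation
below 0.4 to all previously drawn group shapes, since distinct regulators
can still drive convergent kinetics; and (iv) carries an attribution
margin — among candidates satisfying the other conditions, the one least
reproducible by any *other* regulator's model warps (probed on a dense
grid of normalized drive and degradation values) is kept, so a planted
edge is attributable to its own regulator with margin below the 0.8
acceptance bar. The drive (w, b)
is sampled in normalized units — input swing per quarter of the
regulator's range, midpoint anchored at the regulator's mid-level — so
the sigmoid operates in its responsive regime whatever the regulator's
absolute scale; degradation rates span 0.8–3/h (mRNA half-lives of 14–50
min), fast enough that a transcript tracks its production window instead
of integrating it into a featureless rising step. The realized parameters
are recorded in the ground truth.

**Background.** Decoys are cubic-smoothed seeded noise (df 10), redrawn
when they fall inside the $w = 0$ relaxation family (such shapes are
model-indistinguishable from unregulated genes, hence not true negatives).
They are dim (15% of typical target brightness) and noisy (replicate CV
1.2 versus 0.1 for regulated genes) — the intensity-variance funnel of
real arrays — so the pipeline's own quartile and CV gates remove most of
them, exactly as those gates are meant to.

**Arrays.** Replicate values are the true value times unit-mean lognormal
noise; with probability 1% a value is multiplied 10-fold (a gross
outlier). The two-channel emulation uses a per-gene reference equal to the
gene's mean across all samples — a pooled-reference design — scaled by a
per-gene channel bias (log2 sd 0.5 for regulated genes, 2 for the dim
background) that represents dye/probe response differences. The bias is
constant per gene, so it rescales profiles without touching their shapes,
while giving the array-wide Log2Ratio distribution the realistic spread
(MAD near 1) that the median/MAD normalization presupposes; without it the
division by a small MAD raises all ratios to a large power and visibly
distorts profile shapes.

**What the fixture does not emulate.** Probe-level physics (LOWESS
residuals, spatial artifacts), background/flag filtering (upstream of this
pipeline's input), operon structure, and any protein-level delay between
a sigma factor's transcript and its activity. Passing recovery tests on
this fixture shows the chain of methods is implemented coherently and can
recover kinetic structure of the planted kind at realistic noise; it does
not certify discovery performance on real arrays, where regulator activity
and transcript abundance can decouple.

# Validation studies and their scales

The test suite and `scripts/acceptance.R` rerun, at fixed seeds:

- the $w = 0$ closed form over 100 parameter draws (error < 1e-6);
- recovery of 50 independent regulator–target pairs with parameters from
  the annealing init ranges, noise-free and at 10% multiplicative noise
  (a pair's target must span a 2-fold dynamic range — the customary
  differential-expression floor — for "recovery" to be defined at all);
- a planted network screen (5 regulators × 40 targets + 100 decoys, 5%
  noise) at the 0.8/0.65 thresholds, reporting recall and precision and
  checking that the 0.8-edge set nests inside the 0.65-edge set;
- consensus clustering of 6 planted groups × 60 genes (within-group
  Spearman ≥ 0.95, between-group ≤ 0.3) with a 100-run consensus and a
  jackknife elbow scan over n = 2…10;
- exhaustive and randomized agreement of the Fisher p-value with a
  binomial-coefficient hypergeometric tail sum;
- outlier-rejection behavior at n = 5 (Dixon) and n = 12 (Peirce);
- the full pipeline on the default fixture, checking runtime, determinism
  and recovery of planted clusters, edges and enrichments. Two evaluation
  conventions matter here. Edge recall is evaluated among targets that
  survive the expression and variance filters: the screen can only be
  asked about genes the pipeline's own gates hand to it, and the gates are
  validated separately. And the validation clusters at a fixed count
  (n = 7: the five planted regulons plus headroom for background genes
  that slip the gates), mirroring how a real analysis fixes its cluster
  count once from the inspected J curve — automatic elbow selection is
  validated on the dedicated clustering fixture, where the curve is
  unambiguous, and remains the `run_pipeline()` default. Recovery
  additionally requires every planted regulon to dominate some consensus
  core; with too few clusters a compact background mini-cluster can steal
  a slot and push a whole regulon below the 50% consensus, which the
  adjusted Rand index over core members alone would not notice.

These scales (100 consensus runs instead of 500, 13-point grids, hundreds
rather than thousands of genes) are the package's chosen study sizes for
routine validation; all of them are configuration parameters and scale up
unchanged.

# Known limitations

- The correlation screen is permissive for smooth unimodal profiles;
  without temporal fine structure in the regulators, alternative
  regulators of the same target are intrinsically hard to distinguish
  (the trivial/mutual flags exist precisely because of this).
- The elbow criterion (largest second difference of J) is a heuristic;
  soft cluster structure can produce ambiguous curves, which is why the
  scan reports mean ± sd and the default n stays user-overridable.
- Acceptance thresholds 0.8/0.65 carry no significance model; they are
  the method's fixed conventions, not calibrated error rates.
- The Dixon Q test at n = 3 has almost no power; designs without replicate
  spots should expect occasional surviving gross outliers.
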