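---
title: "Models and design choices in asbmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in asbmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`asbmotif` infers allele-specific transcription factor binding (ASB) from
ChIP-seq allelic counts at genotyped heterozygous SNPs and interprets the
calls through known and de novo binding motifs. This vignette records the
models, the tunable parameters, and the design decisions taken where the
problem left genuine freedom, so a maintainer can tell which behaviour is
principled and which is a documented convention.

## 1. The allelic imbalance model

At one SNP, replicate $j$ contributes $n_j$ reads of which $r_j$ carry the
REF allele. The latent quantity of interest is the allelic binding balance
$\beta \in (0,1)$ — the TF's relative preference for the REF allele,
$\beta = 0.5$ meaning none. Two nuisance effects move the observed REF
fraction away from $\beta$:

* the reference allele frequency (RAF), the fraction of genomic DNA copies
  carrying REF at the site (0.5 for a balanced diploid locus, deviating
  under copy-number aberration), and
* the reference-mapping bias $b$, the probability that a read from a
  balanced site maps to REF rather than ALT.

We compose the three on the odds scale:

$$\theta \;=\; \frac{\beta\,\mathrm{raf}\,b}
{\beta\,\mathrm{raf}\,b + (1-\beta)(1-\mathrm{raf})(1-b)}.$$

This form was chosen (over, say, additive corrections or folding RAF into
the prior) because it is symmetric under simultaneous complementation of
all three quantities, reduces to $\theta = \beta$ at
$\mathrm{raf} = b = 0.5$, and makes RAF and $b$ pure multipliers of the
binding odds — so CAR stays interpretable as a *corrected* allelic ratio.
The phrase "used as a prior" for RAF in the upstream literature is
ambiguous; we deliberately keep a flat $\mathrm{Beta}(1,1)$ prior on
$\beta$ and put RAF in the likelihood transform instead. This is a
reconstruction of the cited hierarchical model's intent, not a claim of
bit-compatibility with it.

Replicate likelihood: $r_j \sim \mathrm{BetaBin}(n_j, \theta, \phi)$ with
overdispersion $\phi \in [0,1)$ parameterised so the Beta mixing shapes
are $\theta(1-\phi)/\phi$ and $(1-\theta)(1-\phi)/\phi$; $\phi = 0$
degenerates to the binomial. `estimate_dispersion()` gives a
method-of-moments $\hat\phi$ across replicates when at least three are
available; with fewer, the variance of REF fractions is uninformative and
$\phi = 0$ is used. $\phi$ is configurable in `model_config()`.

Sampling is a Gaussian random walk on $\mathrm{logit}(\beta)$
(step 0.3, 5,000 iterations, 1,000 burn-in, single chain, default seed
1234). The point estimate CAR is the posterior **median** — robust to the
skew that extreme counts induce — and the call rule is: ASB iff the
shortest (highest-density) interval containing 95% of the post-burn-in
draws excludes 0.5. The credible level is user-settable
(`hpd_level`). Chains whose acceptance rate leaves $[0.05, 0.8]$ are
flagged in the call record and via a warning, never silently; no further
convergence diagnostics are attempted (single short chains on a
one-parameter posterior).

Numerical notes: the HPD is the earliest of the shortest
$\lceil 0.95\,n\rceil$-sample windows (deterministic tie-break); at least
100 samples are required; a degenerate all-equal sample yields a
zero-width interval. `infer_asb_table()` derives one seed per SNP from the
config seed, so tables are reproducible element-wise.

The reference-mapping bias is estimated by `estimate_rm_bias()` as the
10%-trimmed mean of per-SNP pooled REF fractions over SNPs with ≥ 10
reads, falling back to 0.5 (with a warning) below 20 eligible SNPs. This
is simpler than the simulation-based estimator used upstream and is
documented as such; it is exact for the symmetric synthetic world and
adequate as a plug-in for $b$.

## 2. Motif scoring and the FPR threshold

SNP windows are ±25 bp of reference sequence with the central base forced
to REF or ALT. Scores are log₂-odds sums over motif columns against a
background distribution (uniform by default; configurable — the source
material says only "random background sequence"). Both strands are
scanned, but only placements overlapping the SNP position compete for the
best score: a distal match inside the 51-mer must not mask the variant's
effect. `N` bases score $-\infty$ and can never win. MSD = REF score −
ALT score, so swapping the allele labels flips its sign exactly.

A SNP *matches* a motif when **either** allele's best score reaches the
FPR threshold. OR rather than AND is deliberate: a fully disrupting
allele should not hide the pair from analysis. The threshold is the
empirical $1-\mathrm{fpr}$ quantile (inverse ECDF) of the best-score
distribution of random background windows — computed exactly by weighted
enumeration of all $4^w$ windows when feasible ($w \le 12$, motif length
≤ 8), otherwise by 100,000 seeded Monte-Carlo draws. Whether the original
toolchain applied its 5% FPR per position or per window is not stated;
per-window matches the scan actually performed here.

## 3. De novo k-mer discovery

Read 5′ starts are profiled around every genomic occurrence of every
canonical (strand-collapsed, lexicographic-minimum) 8-mer within ±200 bp;
strand collapse is justified by the strand symmetry of ChIP fragments
around binding sites. A k-mer is binding-consistent when its smoothed
central read density (|offset| ≤ 100) exceeds twice the flank density and
it occurs ≥ 50 times. The central-vs-flank ratio is the simplest statistic
matching the footprint description; the four constants (W = 200, central
half-width 100, ratio 2.0, 50 occurrences) are reconstructions exposed as
configuration, not published values.

Selected k-mers are assembled greedily in descending enrichment order.
A candidate joins the group where its **expected number of matching
bases** under the group's running column-frequency matrix is maximal,
requiring at least $k-2$ expected matches over at least $k-2$ overlapping
columns (for a one-member group this reduces to exact base matching
against the seed, either orientation, any ungapped offset). After the
pass, groups whose frequency profiles align (expected matches ≥
overlap − 2) are fused to a fixed point. The joint-frequency alignment
and the merge pass exist because pure seed-pairwise joining proved
order-sensitive: different 8-mer frames of one motif could be stranded in
separate groups below the 10-k-mer support floor. All steps are
deterministic. Motifs supported by fewer than 10 k-mers are discarded as
low-complexity, and emitted matrices are per-column frequencies of the
stacked members.

What a green discovery test establishes: that planted, well-separated,
high-coverage sites with a 12-column PWM carrying two 50/50 degenerate
columns are recovered above 0.7 similarity. The synthetic read geometry
(sites ≥ 300 bp apart, so occurrences see only their own site's reads plus
sparse background; fragment-length effects and GC bias absent) is far
cleaner than real libraries — the tests validate the machinery, not its
power on real data.

## 4. Motif similarity, trimming, clustering, classification

Similarity scores two motifs along a fixed order-7 de Bruijn sequence
(greedy prefer-largest construction, cached; length $4^7+6$) **and its
reverse complement**, pooling the two blocks before correlating. Pooling
makes the score exactly invariant to reverse-complementing both motifs —
with a single-strand substrate that invariance only holds approximately,
which is why the strand-symmetric variant was adopted. Pearson
correlations are taken over every offset with at least $4^7/2$ overlapping
positions per block (preventing spurious correlations at extreme offsets)
and against the reverse-complemented second motif; the maximum is the
similarity. Matrices are regularised by +0.01 pseudocount inside this
metric only, so one-hot motifs produce finite profiles; a zero-variance
profile defines similarity 0.

Edge trimming removes terminal columns with information content
$2 + \sum_b p_b \log_2 p_b < 0.25$ bits, never below 4 columns.
Clustering is single-linkage at similarity > 0.7; representatives are
position-wise means of members aligned to the cluster seed (alphabetically
first member name — this, plus name-ordered tie-breaks, makes clustering
invariant to input permutation), padded with the background distribution
where a member does not reach, renormalised, and named `Average_<n>` from
a deterministic counter (the upstream tool draws the number randomly;
determinism is preferred for testability). A discovered motif is
*redundant* if its best reference match exceeds 0.7 and belongs to the
ChIPped TF (then excluded downstream), *accessory* if it exceeds 0.7 only
for other TFs, else *de novo*.

## 5. Quality screening and ASB classification

The motif screen correlates CAR with MSD across SNPs that match the motif
and lie inside peaks (in-peak SNPs carry the strongest binding evidence,
and restricting the screen to them keeps it conservative). $\rho$ is the
Pearson correlation of mid-ranks; p-values are exact by full permutation
for $n \le 9$ (below $n = 5$ a two-sided permutation p cannot reach 0.05,
hence `min_snps = 5`) and a t-approximation above. "High quality" means
$\rho > 0$ *and* two-sided $p < 0.05$ — a one-directional requirement
tested two-sidedly, mirroring the published "significant, positive"
phrasing. No multiplicity correction is applied across motifs, matching
the published raw threshold.

ASBs (and only ASBs) are classified. Candidates are high-quality, matching
motifs with strictly concordant (CAR, MSD) — boundary values
CAR = 0.5 or MSD = 0 are *not* concordant. Attribution order is JASPAR →
accessory → de novo, then |MSD| descending, then name. The attributed
score's peak membership decides High vs Low; no candidate means
Unclassified. Cross-cell-line summaries count distinct (SNP, TF) pairs
once, a pair being High if High in any cell line — this reduction
reproduces the distinct-then-filter arithmetic used for published-style
summary counts; raw row counts are also emitted.

## 6. Comparator (non-ASB) statistics

The pool is every tested SNP never called ASB in any cell line or TF with
pooled coverage ≥ 100 reads (50 as the documented lenient alternative).
MAF matching is **relative**: candidates satisfy
$|\mathrm{maf}_c - \mathrm{maf}_t| \le 0.05\,\mathrm{maf}_t$ — the word
"relative" in the source is read literally; an absolute ±5-point window
would behave very differently at low MAF. Each of 1000 sets draws one
candidate per target uniformly with replacement; the median set takes,
per target, the draw whose MAF is the lower median (ties broken by SNP
id). Empirical p-values use the positively biased $(1+r)/(1+n)$
estimator, consistent with published values of the corresponding
quantities at $n = 1000$. Conservation counts use strict > 0.95 / < 0.05
thresholds with missing scores tracked separately. The rank-sum test uses
mid-ranks with an exact, tie-aware null distribution computed by dynamic
programming over doubled ranks for groups of ≤ 20 each (full subset
enumeration is infeasible there; the DP is exact), and a tie-corrected
normal approximation beyond. For binding-allele analyses the binding
allele is REF if CAR > 0.5 else ALT, and rows lacking an ancestral-allele
annotation are excluded.

## 7. The synthetic world

`generate_fixture()` emits a random genome, planted motif instances inside
declared peaks, SNPs at the motif's highest-information column with ALT
chosen to maximise |MSD| (direction randomised), true
$\beta = \mathrm{logis}(0.6 \cdot \mathrm{MSD})$ for planted SNPs and 0.5
for nulls (placed outside peaks), RAF distortion on 30% of SNPs (0.25 or
0.75), and counts drawn from exactly the inference model's generative
form — 2 replicates at Poisson mean coverage 80. Defaults (200 SNPs, 30
planted) are the scales at which end-to-end recovery is asserted. The
optional read-level output plants 300 additional motif sites in a 100 kb
genome, spaced ≥ 300 bp so k-mer occurrence windows are not contaminated
by neighbouring sites' reads, with 40 reads per site and 2,000 uniform
background reads; the default planted PWM holds its two degenerate columns
at positions 5 and 8 so that every 8-mer window has four frequent
variants — the combinatorial floor for reaching 10 supporting k-mers at
realistic occurrence counts. All outputs are byte-identical given the
seed.

Because concordance is true *by construction*, green end-to-end tests
establish internal consistency (the pipeline recovers what the model
plants), not biological validity; features of real data the generator
deliberately omits include fragment-length structure, GC and mappability
bias, genotyping error, and correlated replicates.

## 8. Orchestration

`run_pipeline()` runs load → RM-bias estimation → inference → optional
discovery/classification → FPR thresholds → scoring → motif screen →
classification → summary, writing one TSV per stage plus `summary.json`
and a manifest (input MD5s, parameters, per-stage row counts). Reruns with
identical inputs reproduce identical artifacts. The run configuration is a
single JSON file (no YAML parser is assumed available); path validation
happens before any compute, and the CLI distinguishes validation (exit 2)
from runtime (exit 3) failures.

## Known limitations

* The inference contract is a documented reconstruction of the cited
  beta-binomial model, not a re-implementation of its code; CAR values are
  comparable in meaning but not bit-identical to the original tool's.
* RM-bias estimation is a trimmed mean, blind to allele-specific error
  structure.
* Discovery constants (window, ratio, occurrence floor) are conventions;
  on real libraries they would need tuning against fragment length.
* Indels, multi-allelic sites, joint inference across cell lines, and
  FDR control across motifs are out of scope.
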