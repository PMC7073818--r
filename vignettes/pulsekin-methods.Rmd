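---
title: "pulsekin: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pulsekin: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsekin)
```

## The turnover model

Pulsed-SILAC assumes cells at steady state: for every protein, synthesis and
loss balance, so the pool size is constant while the light (pre-existing)
fraction decays. For a precursor with light and heavy intensities $L_t$,
$H_t$ at labeling time $t$ (hours), the relative isotopic abundance
$\mathrm{RIA}_t = L_t/(L_t+H_t)$ follows

$$\mathrm{RIA}_t = \mathrm{RIA}_0 \, e^{-k_\mathrm{loss} t}, \qquad
\mathrm{RIA}_0 = 1,$$

since no heavy label exists at $t=0$. $k_\mathrm{loss}$ (per hour) is the
sum of true degradation $k_\mathrm{deg}$ and dilution by division
$k_\mathrm{cd}$; `kdeg_from_kloss()` subtracts a per-sample
$k_\mathrm{cd}$ (e.g. `kcd_from_doubling_time(23.1)` $\approx 0.03$/h), but
all cross-sample comparisons in the package use $\log_2 k_\mathrm{loss}$ as
the degradation proxy — subtracting noisy division-rate estimates and
ignoring label recycling would otherwise dominate small between-sample
differences.

### The two estimators

- **RIA** (`fit_kloss(..., method = "RIA")`): minimizes
  $\sum_t (\mathrm{RIA}_t - e^{-kt})^2$ with the intercept *fixed* at 1.
  Points at $t=0$ are excluded from the sum: the initial condition is an
  assumption, not an observation, and ratio measurements at early times are
  the least reliable.
- **NLI** (`method = "NLI"`): each run (sample × time × replicate) is
  rescaled so its grand total heavy+light signal equals the median run total
  of its sample, then the light channel alone is fitted as
  $L_t = L_0 e^{-kt}$ with $L_0$ free (profiled out in closed form, so the
  optimization stays one-dimensional). On exact steady-state data the two
  estimators coincide; their agreement on noisy data is a useful internal
  consistency check (see the acceptance tests).

Numerics: $k$ is bounded in $(10^{-6}, 100]$/h; RIA initialization is
$k_0 = -\ln(\max(\mathrm{RIA}_{last}, 10^{-6}))/t_{last}$, NLI uses the
log-linear regression slope; optimization is `stats::nlminb` with an
analytic gradient for the fixed-intercept model. Replicate points at the
same nominal time enter the same fit as separate observations.

### Profile filters

Before fitting, per-precursor profiles are dropped (and logged with a
reason) when they have fewer than two distinct positive time points
(`single_time_point`) or when labeling does not progress — the mean RIA at
the last observed time is not below that at the first
(`non_increasing_labeling`). The endpoint test, rather than strict
monotonicity, keeps noisy-but-decaying profiles; a `strict_monotonic`
switch is provided. Exclusion counts are the pipeline's primary debugging
surface and are always logged.

### Aggregation

Precursor rates are averaged to peptides by a weighted mean. The weights are
the profile's total L+H signal (intensity proxies measurement precision);
the weighting scheme is configurable because the original description leaves
it open. Only peptide rates present in **every** sample ("full profiles")
enter cross-sample analyses. Peptide $\log_2 k_\mathrm{loss}$ is summarized
per AS group and sample by the median (a mean is available — the source
methods mention both), requiring at least two peptides per group.

## Expression-filtered database and AS groups

Only protein-coding transcripts with per-sample mean FPKM strictly above 1
in at least three samples enter the protein database
(`build_filtered_db()`): single-shot MS cannot detect proteins from very
low-abundance transcripts, and restricting the search space materially
improves isoform-unique peptide yield. Replicates are averaged per sample
before thresholding (the replicate-vs-sample granularity was unstated; the
sample level is the conservative reading). Protein sequences are taken from
the annotation rather than translated from CDS — translation is upstream
annotation work.

`digest()` performs full tryptic digestion (cleave after K/R except before
P), default 2 missed cleavages and length bounds 7–30 (common DIA practice;
unstated in the source). Peptides hitting several genes are excluded
outright. Unique peptides form UQ groups keyed by their single transcript;
shared peptides with an *identical* transcript set form one SM group —
overlapping-but-unequal sets stay separate groups, which preserves the
original granularity without inventing merging rules. The SM representative
is the member with the highest FPKM averaged over all samples, ties broken
lexicographically (deterministic and order-independent).

## The joined matrices

`assemble_protein_matrix()` median-summarizes peptide log-intensities over
replicates (at least 2 of 3 quantified; the median is taken in linear
intensity space, so an even count yields the arithmetic midpoint), keeps
peptide full profiles, and collapses groups by summing **linear**
intensities before the log. The literal "log2 then collapse by summing"
reading would multiply intensities; summing linear signal is the physically
meaningful total and the default, with a `sum_log` switch for the literal
convention. `join_omics()` attaches each group's representative-transcript
FPKM (replicates averaged, $\log_2$, no pseudocount — FPKM 0 becomes
missing, which cannot occur for rows that passed the database filter).

## Correlation statistics

Per-group correlations use Spearman's $\rho$ over the per-sample pairs with
a two-sided p-value from $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df.
This convention is pinned by the printed significance cut: `critical_rho(12)`
$= 0.576$ at $\alpha = 0.05$. An exact permutation p-value is available for
$n \le 8$. *Absolute* correlation averages each layer over samples and
correlates across groups; *relative* correlation correlates per-layer log2
fold changes between the two conditions. CV quintiles split groups into five
equal-count segments by $\rho$ (stable tie-break on group id) and compare
the coefficient of variation of **linear-scale** protein intensities
(the measurement scale on which CV is conventionally defined; the source
does not state the scale) via Kruskal–Wallis and BH-corrected pairwise
Wilcoxon tests.

Differential tests: two-sided two-sample t-tests with BH correction
(`differential_test()`); for isoform groups of one gene,
`isoform_differential()` uses a t-test (2 groups) or one-way ANOVA plus
Tukey HSD (>2), calling a gene only when some pairwise comparison has
p < 0.05 **and** $|\Delta \log_2| \ge 0.32$. mRNA differential expression
uses the same generic two-group test — the original edgeR model is out of
scope by design.

## Rank-based enrichment

`enrich_1d()` tests each annotation term's member scores against
non-members with a two-sided Mann–Whitney test and locates the term by the
bounded score $s = 2(\bar r_\mathrm{in} - \bar r_\mathrm{out})/n \in
[-1, 1]$ (average ranks for ties), which is invariant under monotone score
transforms and reaches $\pm 1$ exactly when members occupy an extreme rank
block. `enrich_2d()` computes both axes on the shared key set and reports
the **maximum** of the per-axis p-values — conservative and simple, matching
how per-axis scores are reported; a genuinely bivariate rank test is not
attempted. Quadrant labels follow the mRNA-x / k_loss-y convention: "upper
right" (both up) marks buffering attempts. Default member floor: 10.

## Switch calling

`call_switches()` is a simplified dominance-based re-specification of
isoform-switch detection, not a port of any external tool. Transcripts pass
a prefilter (non-zero FPKM in all replicate columns, FPKM > 1 in at least
3); per condition the major isoform is the one with the highest mean FPKM;
a gene is eligible when its summed FPKM exceeds 1 in at least 50% of
columns and the major-to-second "dominance" ratio is at least 1 in both
conditions; an event is a change of major isoform, classified by the
ordered biotype pair (RI-to-coding, coding-to-RI, coding-to-coding, other).
Dominance of a single-isoform gene is infinite, but such genes can never
switch. `switch_consequences()` compares each class's matched protein and
k_loss fold changes against the coding-to-coding control with rank-sum
tests.

## The synthetic world

The generator's defaults are fixed once and state the simulated world:

- 12 samples in two conditions "A"/"B" (6 + 6), 3 replicate injections,
  label times 0/1/4.5/11 h — the deposited study's design.
- gene base FPKM lognormal (meanlog $\ln 20$, sdlog 1); per-sample
  gene-level log2 mRNA deviation sd 0.5; between-condition log2 FC sd 1.
- gene-level $k_\mathrm{loss}$ log-uniform on [0.02, 0.6]/h (half-lives
  ~1–35 h, the range typical of cultured human cells); independent
  per-sample log2 variation sd 0.2.
- `plant_buffering()` redraws the per-sample rates of a chosen gene
  fraction as $\alpha \cdot$ (mRNA deviation) + noise, $\alpha = 0.8$ —
  degradation tracking mRNA is exactly the "buffering attempt" signature
  the correlation analyses are meant to detect.
- measurement noise: independent multiplicative lognormal per channel,
  time point and replicate (CV 0.1), mean-1 parameterization; intensities
  dropped with probability 0.05; heavy intensity at $t=0$ is exactly 0
  (stored as missing, consistent with the 0-means-below-detection I/O
  convention).
- proteins of one gene share constitutive segments and carry
  isoform-specific segments, so shared and unique peptides arise from real
  sequence structure; K/R frequency is boosted to ~11% for realistic
  tryptic peptide lengths; retained-intron isoforms carry no protein.

What the generator does **not** emulate: amino-acid recycling (which biases
$k_\mathrm{loss}$ downward in real data but has no agreed simple model),
retention-time/charge-state chemistry, interference, batch effects, or
isoform-specific turnover within a gene. A green end-to-end test therefore
establishes that the estimators and filters recover the stated world — not
that real-data biases are corrected. `simulate_switch_dataset()` is a
separate clean generator for switch truth, since the main generator keeps
isoform proportions constant across conditions.

Determinism: every generator call seeds R's RNG explicitly
(Mersenne-Twister/Inversion/Rejection), and the pipeline derives per-stage
seeds from the global seed by a fixed affine map, so stages are individually
reproducible and identical configs give bit-identical outputs.

## Known limitations

- No hierarchical/Bayesian turnover model; each profile is fitted
  independently and aggregation is by robust summaries.
- The full-profile requirement is strict: one missing sample removes a
  peptide from all cross-sample analyses, trading coverage for
  comparability.
- The profile invariant "strictly increasing times" is relaxed to allow
  replicate points at the same nominal time; this follows the replicate
  design decision and is the only place the two stated contracts conflict.
- Annotation terms are taken as given (no ontology propagation); the
  pipeline's built-in demo terms are random gene sets for plumbing tests
  only.
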