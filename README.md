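# pulsekin

Isoform-resolved protein turnover analysis from pulsed-SILAC DIA data.

## The problem

In a pulsed-SILAC experiment, cells growing at steady state are switched to
medium with heavy lysine/arginine: pre-existing proteins stay light, newly
synthesized ones incorporate the heavy label. For each peptide precursor the
relative isotopic abundance

```
RIA_t = L / (L + H)
```

decays exponentially with labeling time,

```
RIA_t = RIA_0 * exp(-k_loss * t),   RIA_0 = 1,
```

because no heavy label is present at t = 0. The rate `k_loss` combines true
degradation and dilution by cell division (`k_loss = k_deg + k_cd`); its log2
is the standard cross-sample proxy for protein degradation. `pulsekin`
estimates `k_loss` per precursor by bounded nonlinear least squares (the RIA
method, intercept fixed at 1, or the NLI method, which fits the
run-normalized light-channel decay `L_t = L0 * exp(-k t)` with free
intercept), aggregates it to peptides (intensity-weighted mean) and to
protein AS groups (median of log2 values, at least two peptides).

Because bottom-up proteomics rarely resolves splicing isoforms directly,
quantities are resolved to *AS groups*: peptides unique to one isoform form
UQ groups; peptides shared by an identical isoform set form SM groups
represented by the most mRNA-abundant (major) member transcript. The search
space itself is restricted to protein-coding transcripts with FPKM > 1 in at
least three samples. On the joined per-(group, sample) matrices of log2
protein intensity, log2 k_loss and log2 FPKM, the package computes absolute,
relative (fold-change) and per-group Spearman correlations — with the
t-approximation significance cut (|rho| > 0.576 at n = 12, two-sided
alpha = 0.05) — CV quintile summaries, rank-based 1D/2D annotation
enrichment, two-group and ANOVA/Tukey isoform differential tests (log2 FC
gate 0.32), and a dominance-based splicing-switch caller with
retained-intron/coding classification.

A seeded synthetic-data module generates transcriptomes with shared and
isoform-specific protein segments, two-condition FPKM matrices, and
pulsed-SILAC quantity tables from known ground truth, including a
programmable fraction of "buffered" genes whose per-sample k_loss tracks
their mRNA — so the whole pipeline is testable without external data.

## Worked example

```r
library(pulsekin)

cfg <- sim_config(n_genes = 60, buffered_fraction = 0.5, seed = 11)
sim <- simulate_transcriptome(cfg)
sim$truth <- plant_buffering(sim$truth, cfg)
prec <- simulate_psilac(sim$truth, cfg)$precursors

db     <- build_filtered_db(sim$transcripts, sim$expression)
groups <- assemble_as_groups(classify_peptides(digest_db(db$db), sim$transcripts),
                             sim$expression)
fit  <- fit_kloss(prec, method = "RIA")
agg  <- aggregate_kloss(fit$estimates, peptide_group_map(groups))
prot <- assemble_protein_matrix(peptide_intensity_table(prec),
                                peptide_group_map(groups))
om   <- join_omics(prot$matrix, agg$group, sim$expression, groups)

pg  <- per_group_correlation(om, "mRNA_kloss")
rel <- relative_correlation(om, sim$truth$condition, "mRNA_kloss")
```

This prints:

```
omics_matrix: 70 AS groups x 12 samples (70 complete rows)
critical |rho| at n = 12: 0.576
significant positive groups: 35 of 70
median rho (buffered genes):   0.87
median rho (unbuffered genes): -0.19
relative mRNA-k_loss rho: 0.64 (p = 2e-09, n = 70)
```

Half of the simulated genes were planted with degradation coupled to mRNA
(slope 0.8 in log2); those recover strong positive per-group mRNA–k_loss
correlations (median 0.87, above the 0.576 significance cut), while the
independent genes center near zero — the per-group correlation separates the
two populations, and the fold-change (relative) correlation across genes is
positive.

The same analysis runs end to end from one config via `run_pipeline()`, or
from a shell through `inst/cli/pulsekin.R` (subcommands `simulate`,
`build-db`, `map-peptides`, `fit-kloss`, `assemble`, `call-switches`,
`pipeline`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline on a seeded 150-gene two-condition simulation
(database filtering, peptide mapping, RIA k_loss fitting, matrix assembly,
correlation, enrichment, switch calling) and writes the JSON report to
`--out`. Dataset-level headline numbers depend on the original deposited
HeLa data and are not reproducible at desk scale; the quantitative
acceptance checks (decay identities, the 0.576 critical rho, parameter
recovery, RIA/NLI concordance, filter/mapping correctness against
brute-force oracles, buffering recovery, enrichment calibration, switch
precision/recall, BH/Spearman plumbing) live in
`tests/testthat/test-acceptance.R`.
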