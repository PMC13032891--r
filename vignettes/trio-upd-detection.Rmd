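---
title: "Detecting uniparental disomy in trios: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting uniparental disomy in trios: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triodisomy)
```

## The inheritance model

`triodisomy` treats UPD detection as decoding a hidden inheritance process
along each chromosome. The observed data at a biallelic SNV are the three
alternate-allele dosages of father, mother and proband, packed into one of
27 genotype combinations. The hidden state is the inheritance mode of the
proband's chromosome pair at that position:

* **normal** — one allele transmitted from each parent (Mendelian);
* **father/mother isodisomy** — both proband homologs are copies of a
  single parental homolog, so the proband is homozygous for one allele of
  the contributing parent;
* **father/mother heterodisomy** — the proband carries both homologs of one
  parent, so its genotype equals that parent's genotype.

This uses every variant site, not only "informative" ones: sites where the
states predict the same proband genotype simply contribute no contrast.
Because the model never looks at homozygosity per se, long runs of
homozygosity from consanguinity do not by themselves mimic heterodisomy,
and iso- versus heterodisomy are distinguished by their different emission
signatures rather than by post-hoc rules. Mixed events appear as adjacent
blocks of the two UPD states of one parent; no sixth "mixed" state is
defined.

### Emissions

Emissions are *conditional on the parental genotypes*:

$$P(g_P \mid g_F, g_M, S) \;=\; (1-\varepsilon)\, d_S(g_P \mid g_F, g_M)
\;+\; \varepsilon/3 .$$

For the normal state $d_S$ is the transmission law
$g_P \sim \mathrm{Bern}(g_F/2) + \mathrm{Bern}(g_M/2)$; for isodisomy it
duplicates one uniformly chosen allele of the contributing parent
(het parent → hom-ref or hom-alt child, probability ½ each); for
heterodisomy it is a point mass on the contributing parent's genotype. The
non-contributing parent never enters $d_S$.

Two deliberate choices live here:

* **The parental prior is omitted.** The full observation is the triple
  $(g_F, g_M, g_P)$, but $P(g_F, g_M)$ is identical under every state, so
  it cancels in Viterbi path comparisons and in the event likelihood
  ratio. Omitting it makes the model free of population allele
  frequencies — nothing needs to be estimated from a cohort.
* **ε-smoothing** (default `epsilon = 0.05`, configurable in
  `build_hmm()`) mixes each state's law with a uniform distribution over
  the three proband genotypes. Every observation then has positive
  probability under every state, so a single genotyping error cannot force
  a state switch; it takes a *run* of discordant sites to move the path.
  0.05 is intentionally far above typical short-read error rates: it costs
  little contrast at true-signal sites but buys robustness at artifact
  sites.

### Transitions and initial distribution

Transitions are per *variant site*, not per base pair: stay with
$1 - 4\tau$, switch to each other state with $\tau$ (default
`tau = 1e-6`). No genetic-map or physical-distance scaling is applied —
with roughly uniform variant density the two parameterizations are close,
and a distance model would add a parameter the data here cannot calibrate.
The switch penalty $\log\tau \approx -13.8$ sets the effective minimum
event size: a block is called only when its cumulative per-site emission
advantage over the normal state exceeds two switch penalties, i.e. on the
order of 30–60 informative sites at typical contrasts. The initial
distribution gives each UPD state `1e-6`, so whole-chromosome events that
start at the first variant pay one penalty, like any other boundary.

### Decoding

The most likely joint path is computed with the Viterbi algorithm in log
space (small C++ kernel; identical results to an exhaustive path
enumeration on short sequences, which the test suite checks on 200 random
models). Ties break toward the lower state index, i.e. toward the normal
state, making calls conservative; the practical case is a parent-symmetric
observation stretch, which resolves to the paternal label and is otherwise
reported identically. Decoding is deterministic. Only the single best path
is used — no forward–backward posteriors and no parameter re-estimation:
the model is fixed and auditable, not trained.

## From path to events

Maximal runs of a non-normal state become events with coordinates
`[position of first variant, position of last variant]` — the conservative
convention (the true breakpoint lies between the flanking variants; we do
not interpolate midpoints). Each event carries:

* `n_snps` — sites in the block;
* `n_mendelian_errors` — sites whose proband genotype has probability
  exactly zero under Mendelian transmission (before smoothing), e.g.
  hom-ref × hom-ref parents with an alt allele in the child. True
  heterodisomies accumulate these wherever the non-contributing parent is
  opposite-homozygous; large events with *few* errors are the classic
  signature of poorly captured regions or consanguinity rather than UPD;
* `log_likelihood_ratio` and `p_value` — the emission log-likelihood of the
  block under its state minus that under normal, tested against
  $\chi^2_1$ at $2\,\mathrm{LLR}$ (Wilks). Transition terms are identical
  under both hypotheses up to boundary terms of order $\log\tau$ and are
  omitted, which keeps the statistic additive over sub-blocks. The
  reference distribution is a standard default, not a claim about the
  exact null here — the raw LLR is reported so users can recalibrate.
  P-values are per event and uncorrected; with many events apply
  `p.adjust()` downstream;
* three depth ratios — median read depth inside the block over the median
  across all retained sites *outside* the block, genome-wide, per sample.
  Medians resist coverage spikes; the genome-wide baseline keeps the
  denominator stable for whole-chromosome events (a same-chromosome
  baseline would then be empty). A zero denominator yields `NA`, flagged
  rather than thrown.

Quality control (`apply_qc()`) retains sites where **all six** values pass
`GQ > 20` and `DP > 30` strictly. Requiring all three samples (rather than
the proband only) is a deliberate choice: a low-quality parental genotype
corrupts the observation triple just as much as a low-quality proband one.
Sex chromosomes are excluded by default because hemizygous genotypes
violate the diploid emission alphabet; there is no haploid model. Blocks
are reported down to a single SNP — filtering is a separate, explicit step
so that calling thresholds and cohort-level exclusions never mix.

## Cohort post-processing

`collapse_events()` merges same-type, same-chromosome calls of a sample
into one spanning event (sums of counts and LLR, p-value recomputed from
the summed LLR). Depth ratios over the merged span need per-site depths,
so they are recomputed only when the trio table is passed; otherwise they
are `NA` rather than a misleading average of fragment ratios.

`identify_recurrent_regions()` sweeps event endpoints per chromosome and
returns maximal intervals where at least `min_samples` *distinct* samples
have an overlapping event — recurrence across unrelated samples indicates
systematic artifacts, so a sample with two overlapping fragments counts
once. The default threshold `max(2, 1%` of samples`)` is a pragmatic
choice exposed as a parameter. `mark_recurrent_regions()` flags events
touching such regions (≥ 1 bp, inclusive coordinates), and
`filter_events()` drops flagged events plus likely CNVs — any trio member's
depth ratio outside `[0.75, 1.25]` by default. Those bounds are a
conventional copy-neutral band, not a calibrated constant; widen them for
high-dispersion coverage.

## The simulator: what it emulates and what it does not

`simulate_trio()` builds trios generatively so the benchmark needs no
external data: allele frequencies from Beta(0.5, 0.5) (U-shaped, rich in
both rare and common variants), parents by Hardy–Weinberg sampling, proband
by Mendelian transmission, then the implanted override (isodisomy picks the
duplicated parental allele independently per site — at genotype resolution
this is indistinguishable from a phased haplotype copy; heterodisomy copies
the parent's genotype), then symmetric genotyping error (default 0.002),
then Poisson depth (mean 60) and quality (mean 80, capped at 99) so that
default QC retains most sites. "Genome" mode spreads 1 variant/kb
uniformly; "exome" mode clusters variants into gene-like blocks covering
2% of the chromosome.

The generator reproduces the *information structure* the caller relies on
— genotype-combination frequencies, informative-site density, error
contamination — but not linkage disequilibrium, realistic allele-frequency
spectra, mapping artifacts, segmental duplications, CNVs or mosaicism.
Passing benchmarks therefore demonstrates correctness of decoding,
aggregation and scoring under the stated noise model, not field
performance on cohort VCFs; on real data the recurrent-region and
depth-ratio filters do the work the clean simulation never exercises.

Every simulation is reproducible from its integer seed, and the benchmark
derives per-replicate seeds deterministically from one base seed.

## Benchmark design

`benchmark_sensitivity()` implants one event per simulated trio at a seeded
random location on a chromosome twice the implant's size (at least 10 Mb),
runs the full caller at default parameters and scores with `score_run()`.
Detection for the sensitivity metric requires chromosome, UPD type (iso vs
hetero) *and* parental origin to match; the classification field
additionally distinguishes *right* (all overlapping calls match), *wrong*
(none) and *uncertain* (both types called). Coordinate accuracy is the
fraction of the truth interval covered by the union of matching calls,
with inclusive 1-based base counting throughout.

The package's standard grid — implant sizes {0.5, 1, 2, 5, 10, 25} Mb ×
four UPD types × 20 replicates at 1 variant/kb and error 0.002 — straddles
the megabase range where trio callers historically lose sensitivity, while
keeping a full run around a minute on a single core. The acceptance script
(`scripts/acceptance.R`) recomputes the two headline quantities on exactly
this design.

## Degenerate inputs and numerical notes

* Empty observation sequences decode to an empty path with log-joint 0;
  chromosomes with no retained sites produce no events and no error.
* All probability arithmetic is in natural-log space; ε-smoothing
  guarantees finite emissions, so no special-casing of $-\infty$ exists
  anywhere.
* `event_llr()` clamps to p = 1 whenever LLR ≤ 0; an equal-likelihood
  block is evidence of nothing.
* Duplicate VCF positions keep the first record (with a warning);
  coordinate-unsorted input is refused rather than silently sorted.
* Model I/O (`write_hmm()`/`read_hmm()`) serialises at full double
  precision, so a reloaded model decodes identically.

## Known limitations

Trio-only (no duo mode), diploid autosomes only, biallelic SNVs only, no
mosaic-fraction estimation, and no CNV calling — depth ratios annotate,
they do not segment. The HMM parameters are fixed defaults chosen for
robustness, not fitted to a cohort; `epsilon` and `tau` are exposed
precisely because sequencing platforms differ in error structure and
variant density.
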