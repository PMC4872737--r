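---
title: "Mitochondrial variant dynamics in relapsing tumors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mitochondrial variant dynamics in relapsing tumors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtrelapse)
```

## The problem

The mitochondrial (mt) genome is small, circular, intronless, present in
high copy number and replicated by its own machinery. In a tumor sample a
mt variant is rarely all-or-nothing: it is *heteroplasmic*, present in some
fraction of the mtDNA copies, and that fraction (the alt-allele fraction of
the variant call) is the natural quantitative readout. `mtrelapse`
analyses how the mt variant repertoire changes across matched sample
triplets — normal tissue, primary (diagnostic) tumor, and one or more
relapse tumors per patient — the setting in which relapsing
neuroblastoma has been studied. Four questions structure the package:

1. Which variants are **tumor-specific** and which are **germline**, per
   patient (`classify_patient()`)?
2. Do tumor-specific variants increase, and germline variants decrease,
   from primary to relapse (`mc_difference_test()`, `mc_slope_test()`)?
3. In a patient with several relapses, what is the **phylogeny** of the
   tumor samples implied by their mt variant profiles
   (`neighbor_joining()`, `bootstrap_support()`)?
4. Does the **mutation spectrum** — the distribution of substitutions over
   their trinucleotide contexts — differ between primary and relapse
   disease (`mutation_spectrum()`, `compare_spectra()`)?

The package consumes per-sample variant tables (position, ref, alt,
alt-allele fraction, depth) as produced by mitochondrial variant screens of
exome data; alignment and variant calling are out of scope.

## Filtering and classification

Three thresholds govern everything downstream, collected in
`filter_config()`:

| parameter            | default | meaning |
|----------------------|---------|---------|
| `min_depth`          | 50      | read depth must **exceed** this (the bound is exclusive: 51 passes, 50 does not) |
| `abundance_classify` | 0.02    | minimum heteroplasmy fraction to call a variant present when classifying germline vs tumor-specific |
| `abundance_dynamics` | 0.01    | minimum fraction when following variants across stages (trend statistics, phylogeny site selection) |

A variant key (position, ref, alt) observed anywhere in a patient is
assigned exactly one category. *Germline*: present in the normal sample at
or above `abundance_classify` with passing depth. *Tumor-specific*: below
threshold or absent in normal (with adequate normal coverage) and present
in at least one tumor sample. *Uninformative*: the normal sample lacks
passing depth at the position, so germline status cannot be decided — a
deliberately conservative rule; such variants are reported separately and
counted in neither category.

Call tables usually list only the variants detected in a sample, so
"absent in normal" often means "no row in the normal table". The package
then assumes the position was adequately covered in the normal sample,
unless the caller supplies a per-position depth lookup (`normal_depth`) or
the table carries explicit `af = 0` rows. With exome-derived mt data at a
mean coverage around 212x this assumption is usually safe, but it is an
assumption, and the `normal_depth` hook exists precisely for callers who
have per-base coverage available.

Indels are classified and counted like SNVs but excluded from the spectrum
and from phylogenetic distances, which are defined on single-base states.

## Trend statistics and their Monte Carlo null

Per patient, two scalar statistics summarize the dynamics:

* the **paired difference** `r_count - p_count` of tumor-specific variant
  counts between relapse and primary;
* the **slope** of an ordinary least-squares line through the germline
  counts at normal, primary, relapse, with stages coded 0, 1, 2. For three
  equally spaced points the slope is `(r - n) / 2`; `fit_trend()` uses the
  general covariance formula and the suite checks it against `lm()`.
  Because the slope is only identified up to the stage coding, coefficient
  magnitudes are comparable across studies only under equal spacing.

The cohort-level parameter is the mean of the per-patient statistics. The
null hypothesis — no systematic gain or loss, counts "randomly
distributed" — is materialized by simulation: each iteration draws
surrogate per-sample counts as continuous uniform values on the range of
the observed counts (pooled over roles by default; `range_mode =
"per_role"` uses each role's own range), rebuilds every patient's
statistic and takes the mean. With 10,000 iterations (the default) the
p-value is estimated with the add-one correction
`(1 + #{|null| >= |observed|}) / (1 + iterations)`, which can never be
exactly zero. Sidedness defaults to two-sided on the absolute mean and is
configurable; the direction of an effect is read from the observed mean.

Two numerical points deserve honesty. First, the null's uniform range is
estimated from the data, which makes the test mildly **anti-conservative**:
the suite's calibration check (1,000 null cohorts at the published count
scale, nominal level 0.05) measures a rejection rate in the upper half of
the 5 ± 2 percentage-point band. For cohorts of ~16 patients the test is
therefore best read as approximate; effects with p-values near 0.05 should
not be over-interpreted. Second, when normal-tissue counts are not
available but per-patient slopes are (as when re-analysing a published
coefficient table), `mc_slope_test(observed = ..., range = ...)` runs the
same null against externally supplied statistics; the surrogate range must
then be given explicitly, and we use the pooled range of the available
primary and relapse counts.

## Phylogeny of multi-relapse patients

For a patient with a primary tumor and `k >= 2` relapses, each tumor
sample is encoded as a pseudo-sequence over the variant sites: all SNV keys
passing the 1% dynamics threshold in at least one sample, each sample
contributing the alt base where present and the ref base otherwise. This
binarizes heteroplasmy: fractions are not weighted into the distance,
because a fraction-weighted evolutionary distance has no agreed model and
published mt relapse phylogenies were built from variant sets, not
fractions. A site where every sample carries the alt allele is kept (it
separates the samples from the reference) but cannot affect the topology.

Pairwise distances are Jukes–Cantor corrections of the proportion `p` of
differing sites, `d = -(3/4) ln(1 - 4p/3)`, optionally with gamma-
distributed rate variation among sites,
`d = (3a/4) [ (1 - 4p/3)^{-1/a} - 1 ]`, with shape `a = 0.75` by default.
`p >= 3/4` saturates the model and raises an error rather than returning
infinity. The denominator of `p` is the number of complete site columns in
the matrix.

Trees are built with classic Saitou–Nei Neighbor-Joining. Two behaviors are
pinned down because they otherwise vary silently between implementations:
ties in the Q criterion are broken by the lowest (row, column) index pair,
making the output deterministic; and negative branch lengths (which NJ can
produce on non-additive matrices) are clamped to zero with the deficit
moved to the sibling branch, preserving the distance between the joined
pair — the unclamped lengths are available via `clamp_negative = FALSE`.
On additive matrices the reconstruction is exact, which the suite verifies
to 1e-9 on random 5–8 taxon trees against path-length and `ape::nj`
oracles.

Branch confidence is plain **site-bootstrap bipartition support**: sites
are resampled with replacement, distances and the NJ tree are rebuilt, and
each interior branch of the full-data tree is annotated with the
percentage of replicate trees containing the same leaf bipartition
(1,000 replicates by default). This is deliberately the standard bootstrap
rather than the interior-branch confidence probability that some desktop
phylogenetics suites report under a similar name; the two statistics are
not interchangeable, and outputs are labelled as bootstrap support.
Replicates that saturate the distance model are skipped and counted, with
a warning beyond 10%.

Branch lengths are in substitutions per variant site, not per genome
position: the same topology built from variant-site-only pseudo-sequences
has branch lengths a factor `genome length / site count` larger than one
built from full-length sequences. Comparisons of branch-length scales
across studies must account for this choice.

## The 96-context mutation spectrum

Each tumor-specific SNV is assigned to one of 96 categories: the six
pyrimidine-framed substitution classes (C>A, C>G, C>T, T>A, T>C, T>G)
within the 16 combinations of 5' and 3' flanking bases. A purine-reference
substitution is reverse-complemented into the pyrimidine frame, the
convention of the COSMIC signature literature; the mt genome's two strands
are thereby pooled, since no strand convention is implied by a variant
table. Flanks are read from the reference genome, treated as **circular**
(position 1's 5' neighbour is the last base) — the molecule is circular,
so a context is well defined everywhere; contexts containing an N are
excluded and counted.

Raw bin counts are divided by the frequency of the corresponding reference
trinucleotide (both strands pooled: the pyrimidine-frame 3-mer plus its
reverse complement, each counted once per circular genome position) and
rescaled to percentages summing to 100. Division by context frequency is
the standard opportunity normalization for signatures; the package does
not subtract log-frequencies or fit signature decompositions. Group
profiles pool variants across patients by default ("primary" = present in
the primary tumor, "relapse" = present in any relapse; a variant in both
contributes to both), and `compare_spectra()` reports cosine similarity
and the per-class aggregation with no hypothesis test attached — with a
handful of variants per patient, a formal test of 96-bin profiles would
suggest more precision than the data carry.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage of the pipeline can be
exercised, with known ground truth, without patient data. Its defaults are
the study conditions of a published 16-patient relapsed-neuroblastoma
cohort and are not tuned per analysis:

* 16 patients, one relapse each (`simulate_multirelapse()` plants a
  5-relapse patient with two lineages carrying mutually exclusive private
  variants);
* germline variants Poisson with mean 112 per patient, lost independently
  with probability 0.12 at each stage transition (a Markov chain along
  normal → primary → relapse, emulating drift/loss);
* tumor-specific variants Poisson with mean 3 gained in the primary and 6
  per relapse, persisting onward with probability 0.8 — so relapses gain
  variants, the published direction of travel;
* heteroplasmy fractions uniform on [0.30, 1.00] for germline and
  [0.05, 0.35] for tumor-specific variants (germline high, tumor-specific
  low), with ±10% per-sample jitter — both ranges clear the 2%
  classification threshold with margin, which is what makes ≥99%
  ground-truth recovery a meaningful expectation rather than a coin flip;
* depth normal with mean 212 and sd 40 (truncated at 1), matching the
  published mean mt coverage;
* substitutions drawn from transition-enriched
  (`replication_spectrum_weights()`: C>T and T>C at 0.40 each) 96-bin
  weights. A bin is drawn first and a position then drawn uniformly among
  reference positions carrying that context, so the generated spectrum
  converges to the weights by construction (verified by a chi-square
  goodness-of-fit at n ≈ 10,000).

The generator emulates counts, fractions, depths and contexts. It does
**not** emulate mapping artefacts, nuclear-mitochondrial segments (NUMTs),
strand-specific damage, position hotspots, or correlated loss across
variants — passing tests on synthetic cohorts therefore demonstrates the
pipeline's correctness, not robustness to those real-data pathologies.
The reference it uses is a generated sequence with mtDNA-like base
composition (`simulate_reference()`), 16,569 bp by default and labelled
synthetic; analyses of real data should load the actual reference the
variants were called against.

## Reproducibility and problem sizes

Every stochastic step takes a seed and records it in its result; pipeline
reports are timestamp-free JSON, so a run with the same configuration and
seed is byte-identical (log lines, which do carry timestamps, go to
stderr). The configuration is echoed into every report together with a
stable fingerprint that covers the scientific settings but not the output
location.

The test suite and the acceptance script run the Monte Carlo tests at
10,000 iterations (2,000 within the 1,000-repetition calibration), NJ
recovery on 100 random 5–8 taxon trees, and bootstrap support at 1,000
replicates on a 6-sample patient — sizes chosen to hold Monte Carlo error
well below the tolerances being asserted while keeping a full run in the
tens of seconds.

## Known limitations

* The classification of a variant absent from the normal table leans on
  the assumed-covered rule described above unless depth data are supplied.
* The Monte Carlo trend test's data-dependent null range makes it mildly
  anti-conservative at cohort sizes around 16.
* Bootstrap support is reported for the full-data tree's bipartitions
  only; no consensus-tree or interior-branch test is offered.
* Branch lengths depend on the variant-site-only encoding (see above).
* The spectrum module assumes variants were called against the supplied
  reference and will error, by design, on any ref-allele disagreement.
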