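---
title: "Methods and design of the uvsomatic pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the uvsomatic pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical models, the tunable parameters,
the synthetic-data generator, and the numerical and design choices behind
`uvsomatic`. It is the companion to the function documentation: the *why*
rather than the *how to call*.

## The analysis setting

UV-driven skin tumors accumulate somatic mutations at the highest rates
seen in cancer, dominated by C>T transitions at dipyrimidine sites and by
CC>TT double substitutions from cyclobutane pyrimidine dimers. Exome
capture covers, besides coding sequence, the 5'UTRs, the proximal part of
3'UTRs, exon-adjacent intron sequence and short gene flanks. The pipeline
treats that whole captured territory as first-class: recurrence and
driver analyses are run separately for coding regions, 5'UTRs, 3'UTRs and
introns, because mutation rates, functional-score distributions and
selection pressures differ across them.

## Somatic call filtering

A call passes iff it has (i) at least `min_tumor_alt` = 5 alternate-
supporting tumor reads, (ii) tumor alternate-allele fraction at least
`min_tumor_af` = 0.05, and (iii) tumor allele fraction at least
`min_tn_ratio` = 5 times the normal allele fraction. All thresholds are
inclusive ("at least"). Allele fractions are computed from the `AD`
FORMAT field with depth = `sum(AD)`, never from `DP`, so fractions are
self-consistent.

Two decisions here were genuinely open:

* **Zero normal allele fraction passes the ratio rule** (including a
  normal with zero depth). The ratio criterion exists to catch
  contamination and shared artifacts; a normal sample with *no* alternate
  support is the strongest somatic evidence available, so rejecting such
  calls would invert the criterion's intent.
* **Rejected calls carry only the first failing criterion** in the fixed
  order `low_support`, `low_af`, `low_ratio`, so reason codes are
  deterministic and countable.

Germline and panel-of-normals site lists are applied before filtering by
exact (chrom, pos, ref, alt) key; flagged calls are excluded from all
downstream counting. The package takes these as precomputed site lists —
a population-frequency cutoff for "present in a germline database" is a
resource-level decision outside the pipeline's scope.

## Region classification

Every position gets exactly one class, with priority
`CODING > SPLICE_SITE > UTR5 > UTR3 > INTRON > INTRON_DEEP > INTERGENIC`
across overlapping genes. Splice sites are intronic positions within
`splice_window` = 2 nt of an exon boundary and are counted as coding in
every downstream tally. Intronic positions within
`intron_prox_window` = 100 nt of a boundary are `INTRON`; deeper ones are
`INTRON_DEEP` and excluded from all tallies, because exome capture does
not reach them — keeping them would dilute per-territory rates with
territory that was never sequenced.

The full annotated 3'UTR is classified `UTR3`, with no hard distance
cutoff: the proximal-window character of captured 3'UTR sequence
("roughly the first hundred bases") is a property of the *data*, not of
the annotation, and a recurrently mutated position ~140 nt past a stop
codon must still count as 3'UTR. The simulator therefore enforces capture
windows (see below) while the classifier does not.

Only the canonical transcript per gene (longest valid CDS, ties broken by
transcript id) anchors classification, effect prediction and HGVS labels;
which transcript real annotation pipelines use is tool-specific, so the
choice is explicit and overridable by editing the models. Everything not
assigned to a gene is `INTERGENIC`; no distance bound is imposed there.

Internally the classifier builds a per-position index over each contig
(region code, gene, transcript coordinate, nearest-exon anchor and
distance) so cohort-scale annotation is vectorized lookups; the index is
cached on the `GeneModelSet`.

## Mutation typing and HGVS labels

Merging of adjacent same-sample substitutions into double substitutions
(DBS) happens **after** filtering, so DBS counts sit next to post-filter
totals; merging is transitive, and runs of three or more adjacent
substitutions become a single multi-nucleotide delins record typed
outside the DBS category (and reported), keeping the substitution / DBS /
indel taxonomy clean. CC>TT and its reverse-strand reading GG>AA are
flagged as the UV hallmark. Indels shorter than 4 nt are "short"; longer
ones are retained but flagged.

Labels follow coding-DNA conventions on the canonical transcript:
`c.-N` upstream of the start codon, `c.*N` past the stop, `c.N` in CDS,
`c.N+M`/`c.N-M` in introns anchored to the nearest exon boundary, and
`delins` for multi-base substitutions, with positions and alleles on the
coding strand. This is deliberately not a full HGVS grammar (no
inversions, no 3'-shifting normalization of indels, protein change only
as a simple `Ser24Phe`-style descriptor).

## Trinucleotide contexts and signature refitting

Substitutions are assigned to the standard 96 channels (six
pyrimidine-reference substitution classes × 4 × 4 flanks, indices 1–96 in
the fixed lexicographic order). Per sample, the channel counts are
frequency-normalized and decomposed against predefined signature rows by
nonnegative least squares (Lawson–Hanson, via `pracma::lsqnonneg`), and
the coefficients renormalized to sum to one are the signature
contributions (SC). NNLS on frequencies was chosen because it is
deterministic, standard for signature refitting, and exactly recovers any
profile that truly is a nonnegative combination of the signature rows;
cosine distance between observed and reconstructed profile is reported as
the fit diagnostic.

Samples with fewer than `min_mutations` = 30 substitutions are excluded:
with a 96-bin profile, fits on fewer counts are dominated by sampling
noise. The threshold is configurable since the appropriate value depends
on how distinct the signature set is.

The built-in fixture matrix has three rows: a UV-like signature (C>T
restricted to dipyrimidine contexts, weighted toward TpC), an
alkylation-like signature (C>T at purine-5' contexts) and a flat row.
The two C>T signatures are deliberately disjoint in context so mixtures
are identifiable and recovery tests have an exact ground truth; real
signature matrices load from TSV.

## Hotspots and frequently mutated genes

A hotspot is a mutated position, or a transitively merged run of
directly adjacent mutated positions (`merge_distance` = 1), whose union
of **distinct** carrier samples reaches `hotspot_min_samples` = 3; a
sample counts once per hotspot however many mutations it carries there,
and a double substitution contributes its full two-base span.

Frequently-mutated-gene thresholds are per region: nonsynonymous coding
mutations (splice sites included as coding) in ≥5 samples, any 5'UTR or
3'UTR mutation in ≥4, and intronic mutations within
`intron_recurrence_window` = 40 nt of an exon boundary in ≥5. A
hypermutated-gene exclusion list is applied before thresholding; the
package ships no curated list — it is cohort- and genome-specific input.

## The FM-bias driver test

The test asks whether a gene region's mutations sit at unusually
functional positions. The observed statistic is the arithmetic mean
("amean") over the region's mutations of per-variant functional scores
(a CADD-like track, one nonnegative score per position and alternate
allele): SNVs contribute their exact (position, alt) score, double
substitutions the maximum over their two positions, and indels the
maximum over `max_consecutive` = 7 positions from the indel start (the
"max" method).

The null distribution resamples, `n_iterations` = 1000 times, the same
number of (position, alt) pairs from the region **without replacement**,
with probability proportional to the cohort-wide frequency of each
pair's trinucleotide channel (channels collapsed to the pyrimidine
reference, i.e. counting both strands). Sampling without replacement
reflects that a position mutates once per resampled cohort; the weighted
successive-sampling law is exactly that of R's `sample(prob = )`,
implemented over a Fenwick tree in compiled code (the R sampler is kept
as the independent distributional oracle in the tests). The empirical
p-value uses the +1 pseudocount, `p = (1 + #{null ≥ obs}) / (1 + N)`,
with the inclusive tie rule — conservative by construction and never
zero. q-values are Benjamini–Hochberg **within each region class** (CDS,
5'UTR, 3'UTR, intron are separate analyses), and tiers follow
`q_significant` = 0.025 and `q_highly` = 0.01.

Three properties of this construction deserve explicit statement:

* **Statistical resolution.** The smallest attainable p is `1/(N+1)`;
  after BH over `m` regions the smallest attainable q for `r` tied
  top regions is `m/(r (N+1))`. With 1000 iterations and several hundred
  regions per class, a *handful* of true drivers cannot reach q < 0.025
  regardless of effect size. The driver-recovery benchmark
  (`fm_driver_benchmark()`) therefore uses a compact genome (60 genes,
  8 planted 5'UTR drivers with 6 carriers each) where the arithmetic
  permits recovery; on the default 400-gene cohort the FM-bias stage
  reports scores and p-values but planted drivers plateau at the q floor.
  Real exome-scale analyses escape this only by adaptively increasing
  iterations for promising regions.
* **Indel/DBS max inflation.** The max-over-window observed contribution
  is stochastically larger than the single-pair null draws, so regions
  rich in indels are tested anti-conservatively. This mirrors the known
  behavior of max-method indel handling in FM-bias tools; the null
  calibration test is run on SNV-like draws where the construction is
  exactly matched.
* **Placement-law nuance.** The simulator places SNVs by drawing a
  channel from the signature mixture and then a uniform position within
  that channel's context class (so realized spectra match the signature,
  as signature matrices are defined on realized mutation-type
  frequencies). The null instead weights each pair by its channel
  probability without dividing by class size — the convention of
  signature-aware FM-bias tools. The two laws differ by class-size
  factors; since track scores are i.i.d. and independent of context this
  does not bias the mean, and the calibration benchmark
  (`fm_null_calibration()`) draws observed sets by the *same* law as the
  null, where p-values are exactly uniform up to the `1/(N+1)` grid.

## Cohort summary and enrichment statistics

The summary table mirrors a standard mutation-distribution layout: rows
for all / coding / noncoding / introns / 3'UTR / 5'UTR / intergenic,
with counts, percentages of the cohort total, the unweighted mean
sequencing depth at mutated positions, the mutation-weighted mean
alternate-allele fraction, and counts and within-region percentages of
substitutions, double substitutions and short indels. Percentages are
rounded **half-up** to one decimal, matching how such tables are printed
(R's `round()` is round-half-even). The mean allele fraction is
mutation-weighted rather than sample-weighted — the natural reading of a
per-region average over mutations; per-sample burden is the coding
mutation count divided by a user-supplied coding territory in Mbp, since
capture territory is a property of the kit, not of the calls.

Fisher's exact test is computed by direct hypergeometric-tail summation:
the two-sided p sums the probabilities of all tables (at the observed
margins) at most as probable as the observed one, probabilities within a
1e-7 relative tolerance of the observed counting as ties. The odds ratio
reported is the sample odds ratio `ad/bc`. The tests verify agreement
with an independent log-binomial enumeration to 1e-12 over all margins
up to 30, and cross-check against `stats::fisher.test`.

## MLPA relative copy number

Per probe: tumor and normal signals are each divided by the geometric
mean of their run's control-probe signals (canceling run-to-run scale —
the result is provably invariant to rescaling either channel), then the
ratio of normalized tumor to normalized normal is multiplied by 2, so a
diploid probe reads 2.0. Calls use `loss ≤ 1.6` and `gain ≥ 2.4` —
±20% of the midpoints toward single-copy states (1.0 and 3.0), a
conventional bar-plot reading; the thresholds are explicit parameters,
not claims about any particular assay. Nonpositive control signals abort
the sample rather than being silently dropped: a dead control probe
invalidates the whole normalization.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; they are chosen once
and the tests are run under them, not the other way around:

* 27 tumor/normal samples; per-sample mutation counts lognormal
  (meanlog = log 1900, sdlog = 0.5, ≈50,000 cohort-wide); samples 14 and
  21 near-empty (Poisson mean 8, emulating the low-burden samples real
  cohorts exclude from signature analysis); sample 22
  alkylation-dominant (weights 0.3/0.6/0.1 vs the usual 0.7/0.2/0.1
  UV/alkylation/flat, jittered per sample).
* Mutation-type fractions 0.945 substitutions / 0.037 double
  substitutions / 0.018 short indels. UV-component SNVs land only at
  dipyrimidine C>T contexts; CC>TT events are emitted as two adjacent
  calls at covered CpC (or GpG) sites, exactly what the merger should
  reconstruct; indels of 1–3 nt arise at homopolymer runs (≥3), where
  polymerase slippage concentrates them in real data.
* Read support: depth = 30 + NB(mean 150, size 12), i.e. ≈180x with a
  floor that keeps every site genuinely covered; tumor allele fraction
  Beta(3.5, 6.5) (mean 0.35); normal alternate reads 0 for true
  somatic calls. Spiked artifacts are constructed to fail exactly one
  criterion each (`low_support`, `low_af`, `low_ratio`), and
  germline/panel-of-normals spikes pass read-support filtering but
  appear on the site lists — so flagging, not filtering, must catch
  them.
* Covered territory: exons, ±2 splice windows, 100 nt intron-proximal
  windows, the first 150 nt of each 3'UTR, and 100 nt gene flanks. The
  3'UTR window is deliberately wider than the nominal "~100 bp" so that
  the planted 3'UTR hotspot at +142/143 — emulating the real situation
  of a recurrently mutated position well past the nominal window yet
  clearly captured — lies inside covered territory.
* Planted structure with truth tables: a 2-position 3'UTR hotspot
  (8 carriers), a 5'UTR hotspot at c.-5/-4 (5 carriers), a coding
  hotspot at c.71/72 (3 carriers), each with one double-substitution
  carrier; 11 driver regions (3 CDS / 6 5'UTR / 2 3'UTR, 6 carriers
  each) whose mutation sites receive functional scores drawn from
  Uniform(25, 35) against a Gamma(2, 2) background (a CADD-like scale);
  and MLPA arm CNAs (9 samples with a 9q single-copy loss, 5 with a 9p
  gain, multiplicative lognormal signal noise σ = 0.05).
* Genome: 400 genes, 2–4 introns each, CDS of 100–400 codons starting
  ATG, free of internal stops, divisible by 3, on alternating strands;
  ≈1.2 Mb total. 400 genes keeps the per-position mutation density
  around 0.05–0.08 so recurrence structure is sparse enough for planted
  hotspots to stand out, while the whole pipeline (including 1000-
  iteration FM-bias over every gene region) finishes in well under a
  minute.

**What the simulator does not emulate**, and hence what passing tests do
*not* establish about real data: real human sequence composition and
context abundances; regional mutation-rate heterogeneity (replication
timing, expression, chromatin); subclonality and copy-number-driven
allele fractions; alignment and calling artifacts beyond the simple
spiked classes; multi-transcript gene structure; and — most importantly —
the ~50-fold larger territory of a real exome, which makes per-gene and
per-position recurrence counts here systematically *higher* than a real
cohort's at the same burden. Hotspot counts and frequently-mutated-gene
lists on the default fixture are therefore validation surfaces for the
algorithms, not realistic cohort estimates.

## Problem sizes and numerical choices

The test suite runs a compact world (15 genes, 8 samples, ≈1,400 calls)
for module tests; the end-to-end checks run the default fixture
(27 samples, ≈50,000 mutations) twice for byte-identical determinism,
the FM-bias calibration at 200 regions × 1000 iterations, the driver
benchmark at 60 genes × 8 planted drivers, signature recovery at 10,000
sampled mutations, and the Fisher enumeration sweep over all margins up
to 30. Degenerate inputs are defined, not patched around: empty call
sets produce header-only tables; a region whose scoreable pairs are
fewer than its mutation count is skipped with a warning; all-zero
resampling weights, all-zero contingency tables, zero tumor depth, and
nonpositive control probes are hard errors. All randomness flows from a
single seed through fixed per-stage offsets, so every product — files
included — is reproducible byte for byte.

## Known limitations

* FM-bias q-values on large region universes are floor-limited by the
  iteration count (see above); no adaptive iteration scheme is
  implemented.
* The indel "max" contribution inflates observed means relative to the
  SNV-pair null.
* HGVS output is a pragmatic subset (no normalization/3'-shifting, no
  protein-level grammar).
* Effect prediction uses one canonical transcript per gene.
* The intergenic class is unbounded: anything unassigned is intergenic,
  which matches captured gene flanks in the simulator but would label
  far-from-gene calls in real whole-genome input as intergenic too.
* Double substitutions spanning an exon/intron boundary take the
  higher-priority region of their two bases and get no coding effect.
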