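---
title: "The sigma-I promoter model: scanning, profiles, and regulon assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sigma-I promoter model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigiscan)
```

## The biological model

Cellulolytic clostridia regulate the enzymatic composition of their
cellulosome through a family of paralogous alternative sigma factors
(sigma-I factors), each paired with a membrane anti-sigma factor that senses
an extracellular polysaccharide. The promoters these factors recognize share
a distinctive bipartite anatomy:

* a **homopolymeric A-tract** at the 3' end of the -35 element -- the
  general hallmark of sigma-I recognition (the -35 element is read by the
  family's unusual C-terminal domain);
* a **variable spacer** of 12-15 nt;
* a short, highly conserved **-10 core** (a CGAA-type tetrad, with a
  conserved AT dyad three nucleotides further downstream in most promoters);
* immediately 5' of the A-tract, a divergent **region of specificity** that
  differentiates the regulons of the individual paralogues -- for example a
  CTC triad immediately upstream of the tract for one factor versus a CCC
  triad two nucleotides upstream for another.

`sigiscan` turns this anatomy into an executable pipeline: a degenerate
bipartite scanner, per-factor positional profiles, declarative
region-of-specificity rules, cross-talk-aware regulon assignment,
cross-species transfer, in-silico mutagenesis, and reporter-assay
quantification -- all testable end to end on seeded synthetic genomes with
planted promoters.

## The scanner

`scan_bipartite()` reports every pair (maximal A-run, -10 core match)
compatible with a `motif_spec()`. Two choices deserve comment.

**Maximal-run deduplication.** The default -35 core is the `AAA` triad used
for genome-wide searches, while curated alignments show an AAAA-tract
consensus. The scanner reconciles the two by extending every core match to
the *maximal* run of A containing it and reporting one match per (run, -10
site) pair. One biological site on a long A-run therefore yields one report,
not one per AAA placement.

**Spacer measurement.** The spacer is measured from the 3' end of the
maximal A-tract to the 5' start of the -10 core. The alternative
(start-to-start) convention can be emulated by adjusting the spacer bounds;
the element-edge convention is used throughout because both anchors are
observable sequence boundaries.

`N` never matches a concrete pattern base, so assembly gaps suppress matches
rather than inventing them; IUPAC codes other than N in input genomes are
degraded to N on reading.

### The background rate

Under an i.i.d. background with base frequencies $f$,
`background_hit_rate()` returns the per-position, per-strand expectation

$$\lambda_0 = n_\text{spacer} \prod_j f(\text{-35}_j) \prod_k f(\text{-10}_k),$$

the plain product over both cores summed over allowed spacer lengths. With
maximal-run semantics this is an upper bound: a reported A-tract must *end*
where its spacer begins, i.e. the following base is not A, which contributes
an exact factor $(1 - f_A)$ (`maximal_runs = TRUE`):

$$\lambda = n_\text{spacer}\, f_A^{3}\, (1 - f_A) \prod_k f(\text{-10}_k).$$

Both forms are exposed; the calibration tests compare observed deduplicated
counts to $\lambda$, and the agreement is within 3 Poisson standard
deviations across GC contents from 30% to 70%.

## The profile model

`promoter_profile()` is the package's central fitted object. Curated
promoters are stacked into **two contiguous fixed-width windows anchored on
the element boundaries**:

* an *upstream block* of `specificity_window + atract_width` nt (default
  6 + 4 = 10) ending at the A-tract 3' end, right-aligned;
* a *-10 block* of core + `downstream_window` nt (default 4 + 6 = 10)
  starting at the -10 core 5' start, left-aligned.

The variable spacer is excluded from the columns and kept as a separate
length distribution. Rows shorter than a window (short tracts, sequence
edges) are padded with a gap symbol that is ignored in the counts.

Why contiguous windows rather than separately gap-aligned specificity and
tract blocks? Three reasons. First, a genomic candidate is contiguous DNA:
scoring it against contiguous columns is well defined with no alignment
ambiguity. Second, decomposing a sampled window at its trailing A-run and
re-stacking reassembles the identical row, which makes parameter-recovery
arguments exact. Third, tract-length variation then shows up *in the
columns*: promoters with 4-5 A tracts contribute A at the position
immediately 5' of a 3-A tract, reproducing the A-enrichment upstream of the
minimal triad that the curated alignments show -- and that single fact
explains why extending the tract by mutating the base immediately upstream
of it *increases* predicted activity (see the mutagenesis section).

Column frequencies use a pseudocount (default 0.5, Laplace-half): curated
sets hold only 3-6 promoters per factor, so zero counts are the norm, and a
half-count keeps log-odds finite without drowning the signal. The
information content per column is the relative entropy against the
background (uniform by default; pass the scanned sequence composition for
genome work), so it lies in [0, 2] bits under a uniform background. The
small-sample logo correction is deliberately omitted: profiles are used for
scoring, not for publication-grade logos, and the correction would interact
with the pseudocount.

`consensus_string()` reports, per column, the majority base at a threshold
(default 0.8), falling back to the minimal IUPAC code covering all bases
above 1/4, then to N.

Candidate scores are plain log-odds sums
$\sum_j \log_2 f(b_j, j) / \text{bg}(b_j)$ over the two windows, with
missing edge positions, gaps and N contributing 0.

## Regulon rules and assignment

The qualitative finding that each factor reads a characteristic region of
specificity is operationalized as a `specificity_rule()`: a 3-nt triad that
must match with its 3' end 0-2 nt upstream of the A-tract 5' start
(instantiated per factor: CTC at offset 0, CCC at offsets 0-2), a -10
tetrad pattern, and an optional dyad checked 3 nt after the tetrad. The
tetrad/dyad slots capture the observation that an otherwise identical
promoter can be privatized by a CGTA-for-CGAA substitution and a GT-for-AT
dyad. A count-based alternative (at least 3 C in the 5 nt immediately
upstream of the tract) is available behind a flag for sensitivity analyses.

`classify_regulon()` assigns a candidate to *every* label whose rule passes
and whose profile score reaches `min_score` (default 0 bits: better than
background; the pipeline is rule-based, so no multiple-testing machinery is
attached to the score). Multi-assignment is preserved rather than
arg-maxed: promoters carrying the shared CCCCTCAAA / CGAA configuration are
genuinely recognized by more than one factor, and that cross-talk is a
result, not an error. `crosstalk_matrix()` tabulates it.

5'-UTR distances are measured from the -10 core 3' end to the first codon.
The curated distance columns do not pin down the promoter-side endpoint;
the core 3' end is used because it is the last scanner-defined position,
and the choice only shifts all distances by a constant.

The upstream search window defaults to 600 nt (covering the longest
curated 5'-UTR classes with margin) and is a configurable knob, not a
constant. Because a genome-wide candidate count depends strongly on whether
the scan is restricted to gene-upstream regions and on how many strands are
searched, both `upstream_only` and `whole_genome` scopes are first-class,
letting real-genome counts be bracketed between the two.

## In-silico mutagenesis

`mutagenesis_report()` rebuilds the transversion-library experiment
computationally. Effects mix two regimes, and the implementation keeps them
decoupled:

* **core integrity** (hard): the mutant window is re-scanned; if no
  bipartite match survives at the wild-type anchors (A-tract 3' end and
  -10 start), the mutant is `ablated` -- the analogue of "not detected"
  reporter activity. A 5'-extension of the tract keeps the anchors and is
  *not* ablation.
* **graded score** (soft): otherwise the effect is the log-odds difference
  at the wild-type anchors, banded into increased / neutral / reduced with
  a 0.5-bit neutral band. The band reflects that the experimental readout
  is qualitative apart from a single quantified outlier, so classification
  is banded rather than regressed.

For a sigma-I3-style analysis the spec should carry the factor-specific
core (`motif_spec(minus10_core = "CGAA")`): under the generic CGHH search
core, tetrad A-to-T transversions still match and would not read as
ablated. With that spec, saturation transversion of a canonical promoter
yields ablation at every A-tract and tetrad position, neutrality at
unscored spacer and flank positions, and a *positive* score shift for the
tract-extending T-to-A change -- the profile's A-enriched pre-tract column
does that work, as described above.

## Reporter quantification

`delta_fu()` implements the assay arithmetic: delta-FU = induced minus
uninduced fluorescence at OD600 = 1, with not-detected (ND) assigned when
delta-FU <= 0 (both listed cases, negative and zero, hence the inclusive
comparison) or when the replicate standard deviation exceeds delta-FU. The
SD is interpreted as the SD of delta-FU across independent experiments,
which is the quantity the ND rule compares. ND is a sentinel: it propagates
through `relative_activity()` (percent of a non-ND, positive wild type)
without arithmetic ever being performed on it. Relative activity is the
ratio of per-condition means; per-replicate ratios are not available in the
data model.

## The synthetic-data generator

The generator defines the package's study conditions:

* background: i.i.d. bases at 38% GC (clostridial-like), configurable;
* plants: specificity window with the factor's triad written in (filler
  drawn from the background), A-tract of 3-5 nt centred on the 4-nt
  consensus, spacer of 12-15 nt, realized -10 core, 6 nt of downstream
  context. Each plant is rejection-screened until it scans to exactly one
  bipartite match at its intended coordinates (spacers that start with A or
  that spawn accidental matches are redrawn), so truth tables are exact;
* genes: one 300-nt synthetic gene per plant at a 5'-UTR distance drawn
  uniformly from 30-300 nt (the range spanned by the curated distance
  columns), plus optional promoter-free decoys;
* layout: one slot per plant, so plants never overlap; strands are sampled.

Background outside the plants is left untouched, so background matches are
*expected*; recall is therefore measured at truth coordinates, never as a
total count. Everything is driven by one mandatory seed, and identical
specifications give byte-identical FASTA/GFF3/truth outputs.

What the generator does *not* emulate: real gene content, codon structure,
operons, UP-element-like context effects outside the modelled windows, and
the correlated (non-i.i.d.) composition of real intergenic DNA. Passing the
planted-recovery and calibration suites therefore demonstrates correctness
of the machinery under the declared statistical model, not discovery
performance on real genomes.

## Validation design and problem sizes

The test and acceptance suites use sizes chosen to make their statistical
claims sharp while remaining quick to run:

* scanner-oracle equivalence on 100 random 10-kb sequences spanning
  30-70% GC, against an independent brute-force enumerator (exact set
  equality);
* background calibration on 100-kb contigs at GC 30/50/70%, within
  3 Poisson SDs of the closed form above;
* planted recovery and classification on 500 plants across 5 factors with
  pairwise-distinct offset-0 triads: recall is structurally 100% (plants
  are screened at generation), and misassignment is structurally 0 because
  a disjoint triad cannot satisfy a foreign rule at a fixed offset -- the
  suite verifies both;
* profile recovery at n = 200 samples from a near-unanimous generating
  profile: with column frequencies near 0.985 the binomial standard error
  is about 0.009, so the 0.05 L-infinity band sits more than 5 SDs out --
  the check is high-powered by design rather than seed-lucky.

## Known limitations

* The scanner is exact-degenerate: no PWM-threshold scanning of the cores
  and no mismatch tolerance. Promoters with a degraded core ("mix and
  match" compensation) are invisible by construction.
* The shipped curated-set fixtures are synthetic stand-ins that realize the
  documented motif anatomy (their filenames and headers say so); analyses
  of real regulons should load the user's own curated TSVs.
* Orthology between factors of different species is user-supplied;
  cross-species transfer only moves a profile and a rule, it does not
  discover which factor corresponds to which.
* Fluorescence magnitudes are not predicted; the mutagenesis module
  predicts ablation and the sign of graded effects only.
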