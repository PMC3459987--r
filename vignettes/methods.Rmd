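---
title: "Models and methods behind tetherscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tetherscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the conventions, the default
parameter values and their rationale, the scope of the synthetic data
generator, and the known limitations of the package. It makes no empirical
claims beyond what the test suite and `scripts/acceptance.R` actually
compute.

## The biological model

The package targets ChIP experiments on a fusion protein whose
piggyBac-transposase domain binds transposon-derived repeat elements. Three
sequence features define the element model (`element_model()`):

* a 4-bp `TTAA` target-site duplication (TSD) flanking the element;
* 13-bp terminal inverted repeats (TIRs), `CCCTAGAAAGATA` at the 5' end and
  its reverse complement at the 3' end;
* a 16-bp internal palindrome `GTTCCATTATTGGAAC` beginning 20 bp from the
  element start. Its 6-bp arms (`GTTCCA` / `TGGAAC`) are a perfect inverted
  repeat separated by a 4-bp loop, while the full 16-mer differs from its
  own reverse complement at exactly 2 positions — so it is an *imperfect*
  palindrome, and `find_imperfect_palindromes()` reports both distances
  separately.

The reference MER85 layout is 140 bp: TSD `[0,4)`, 5' TIR `[4,17)`, a 3-bp
spacer, palindrome `[20,36)`, internal sequence, 3' TIR `[127,140)`.
Full-length PGBD3-like elements use the same terminal structure around a
2.5-kb body. A recurrent C>T substitution at the final palindrome base
(`TGGAAC` → `TGGAAT`) is flagged separately
(`detect_palindrome_variant()`) because it creates a TEAD1-like site.

## Coordinate and data conventions

All tables are tibbles. Genomic intervals are 0-based, half-open
`[start, end)` throughout the package; conversion to 1-based coordinates
happens only at file-format boundaries (wiggle, SAM) and when calling into
IRanges. Sequences are handled as Biostrings objects or plain named
character vectors interchangeably. Enrichment results implement
broom-style `tidy()` and `glance()`.

## Coverage, clusters, summits

Fragment coverage is the number of ChIP *fragments* (mate-pair spans, not
reads) overlapping each base, stored as sparse constant-count runs. A
cluster is a maximal region with at least `min_fragments = 5` overlapping
fragments whose mean coverage exceeds the input control `min_fold = 2`
times, with a pseudocount of 1 added to the input mean so that regions with
zero input coverage are still callable. Runs at or above the depth
threshold separated by zero-width gaps are merged before reporting.

The summit of a region is the centre of its deepest coverage run — for a
run `[s, e)` the position `s + (e - s - 1) %/% 2` — taking the leftmost
run on ties. The same rule is reused for meta-profile summits
(`profile_summit()`), so profile and peak summits are directly comparable.

Consensus peaks across callers are the transitive-overlap components of the
pooled intervals that contain at least one interval from *every* caller,
reported with outermost component boundaries. Overlap is strict
(half-open): abutting intervals do not chain.

## Element annotation and motif scanning

Element annotation works in element orientation (minus-strand elements are
reverse-complemented first). TIR detection first tests whether the two
element ends are mutual reverse complements within `max_tir_mismatch = 2`;
only if that fails is each end compared to the model consensus to decide
which side is broken. The palindrome is searched in the first 60 bp on the
plus strand with up to 3 mismatches. Completeness classes are `intact`,
`incomplete_5p`, `incomplete_3p`, `no_tirs`, plus `expanded` (more than
20 bp over the reference length) and `deleted` (shorter than the
reference).

IUPAC motif scanning (`scan_iupac()`) translates the consensus to a regular
expression wrapped in a lookahead so that *overlapping* matches are all
reported; both strands are scanned, and a self-reverse-complementary
pattern such as `TGANTCA` therefore yields a hit on each strand at the same
position. Ambiguous bases in the subject never match, and `hamming()`
counts any non-ACGT base as a mismatch — a deliberately conservative choice
so that masked or uncertain sequence cannot create spurious matches.

Peaks are assigned to categories via the ±50 bp window around their summit:
element overlap takes precedence (element peaks are excluded from the motif
analysis by construction), and a non-element peak belongs to every motif
category with a match fully inside its window, so multi-motif membership is
possible.

## Enrichment statistics

Regulatory domains follow the GREAT logic. In `"basal"` mode each start
site gets a strand-oriented basal region (5 kb upstream, 1 kb downstream by
default) and is then extended up to `max_extension` on each side without
invading a neighbour's basal region; in `"extension"` mode domains are
`± max_extension` truncated at midpoints between neighbouring sites. The
analyses use extensions of 100 kb, 250 kb and 1 Mb.

With `p` the fraction of the genome covered by the merged domain union and
`k` of `n` summits inside it, the P-value is the exact binomial upper tail
`pbinom(k - 1, n, p, lower.tail = FALSE)`. The empirical FDR draws
`n_sets = 100` random summit sets of size `n` (chromosome chosen
proportional to length, position uniform) and reports the fraction with a
P-value less than or equal to the observed one; zero hits are reported as
`"<1/R"` rather than 0, since 100 replicates cannot distinguish FDRs below
1/100. Because the binomial count is discrete and random sets frequently
tie, this estimator is conservative: the test suite's calibration block
measures the fraction of null summit sets reaching FDR < 0.01 over 1000
replicates and checks it stays at or below 0.02.

## Expression

Expression records carry signal log ratios (SLR, log2 treated/control).
Classification uses strict inequalities — `slr > 1` is up, `slr < -1` is
down, everything else (including exactly ±1) unchanged — and non-finite
SLRs are dropped and tallied rather than silently kept. `qpcr_slr()`
implements ΔΔCt with an assumed amplification efficiency of exactly 2 per
cycle, so `SLR = (Ct_target,ctrl − Ct_ref,ctrl) − (Ct_target,sample −
Ct_ref,sample)`; a shift common to target and reference genes cancels.

## The synthetic data generator

The generator exists to validate the pipeline, not to imitate real data.
`random_genome_spec()` places non-overlapping elements, motif sites and
gene TSSs on uniform-ACGT background sequence; `simulate_fragments()` draws
signal fragments around bound features and uniform background fragments;
`simulate_expression()` plants ±2 SLR effects on genes near bound TRE sites
and Normal(0, 0.3) noise everywhere. Truth labels (bound status, planted
coordinates, regulation direction) are returned so recovery can be checked
exactly. Everything is deterministic given the seed.

Defaults worth explaining:

* **`binding_offset = 25`** — signal fragments centre 25 bp from the
  element start, the middle of the internal palindrome, which is where the
  averaged profile should peak if the pipeline is correct.
* **`fragment_length_range = c(300, 600)`** — a typical sonicated
  paired-end library window. The knob exists because size selection varies
  between protocols.
* **`enrichment_sd = 100`** — fragment centres scatter Normal(site, sd),
  but an immunoprecipitated fragment must *contain* its crosslinked site,
  so centres are truncated to within half a fragment length of the site.
  The coverage summit is anchored exactly at the site only by fragments
  whose boundary lands on it (truncated draws); the expected number of
  such fragments per side scales with `Φ(−(len/2)/sd)`. With `sd = 50`
  that expectation is below one fragment per side at these depths and the
  summit wanders over the fragment-containment plateau; with `sd = 100`
  (two thirds of the minimum half fragment length of 150) roughly 2% of
  draws per side are truncated and the summit localizes to the planted
  offset. This is a property of the containment model, chosen before the
  acceptance expectations were frozen, not a tuning against them.
* **minimum feature spacing of 2 kb** in `random_genome_spec()` — wider
  than any fragment, so the pileup and the ±100/+239 bp profile window of
  one feature can never bleed into a neighbour's.

## Limitations

* The generator's background is uniform ACGT with uniform fragment
  placement: no GC bias, mappability structure, chromatin accessibility
  bias or duplicate reads. Null calibration results transfer to real data
  only to the extent that real input controls capture those biases.
* Element annotation assumes substitutions only (`with.indels = FALSE`
  everywhere); elements with internal insertions or deletions shift their
  palindrome position and may be misclassified rather than realigned.
* The binomial enrichment model assumes summits are exchangeable and
  uniform under the null; clustered summits (e.g. from tandem elements)
  violate this, which is why the empirical FDR, not the raw binomial
  P-value, is the headline statistic.
* Bound/unbound tabulations on real data depend on the peak caller's
  threshold choices; the package reports the counts it derives from the
  supplied peaks (its own derived totals can differ slightly from
  externally published tallies of the same data).
* `read_sam_pairs()` handles the minimal SAM subset needed here (FLAG bits
  for unmapped/strand/secondary, `RNEXT` consistency); it is not a general
  SAM parser.
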