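---
title: "Reconstructing paired-end alignments from de-identified cfDNA fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing paired-end alignments from de-identified cfDNA fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragbam)
```

## Motivation and model

Plasma cell-free DNA (cfDNA) is released mostly by dying cells as
nucleosome-protected fragments: a dominant mono-nucleosomal mode near
167 bp and a di-nucleosomal mode near 334 bp. Fragment lengths, end
positions, and local coverage carry clinically useful signal (tumour
burden, tissue of origin, inflammation) without any nucleotide-level
information. De-identified fragment tables — contig, 0-based half-open
interval, optionally MAPQ and strand — can therefore be shared openly
where raw reads cannot. The obstacle is purely practical: cfDNA analysis
software consumes BAM files.

`fragbam`'s reconstruction inverts the de-identification as far as the
information allows. Each fragment of length $L = \mathrm{end} -
\mathrm{start}$ becomes one proper read pair with $R = \min(r, L)$ bp
mates, where $r$ is the configured read length:

* the leftmost mate maps forward at `start` (1-based POS = start + 1) with
  CIGAR `RM` and sequence equal to the reference substring;
* the rightmost mate ends exactly at `end`, carries the reverse complement
  of the reference substring, and maps with the reverse flag;
* `TLEN` is $+L$ on the leftmost and $-L$ on the rightmost mate, so the
  template length — the quantity fragmentomics tools actually use — is
  preserved without loss;
* for `+` (or unknown `.`) strand the leftmost mate is first-in-pair
  (flags 99/147); for `-` strand the rightmost mate is (flags 163/83).

Because both mates are pure reference sequence, reconstruction is exact by
construction rather than approximate: there is no aligner in the loop, so
a fragment table, its reconstructed BAM, and the re-extracted table are
interchangeable representations of the same data. The test suite asserts
this as an identity, not a similarity.

### What is deliberately not modelled

Reconstruction is not read simulation. There are no mismatches, indels,
clipping, or quality decay; base qualities are a uniform printable
placeholder (`I`, Q40 — `*` is avoided because some tools reject missing
qualities). Mutations and true per-base qualities were removed by
de-identification and are unrecoverable in principle. Duplicate fragments
are all emitted under distinct read names; no duplicate marking is
attempted, since coordinate-identical fragments are indistinguishable from
genuine independent molecules in this representation.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `read_length` | 60 bp | synthetic mate length; mates overlap when $L < 2R$ and gap when $L > 2R$, but always delimit the fragment exactly |
| `base_quality_char` | `I` (Q40) | uniform QUAL fill, Phred+33 |
| `default_mapq` | 60 | MAPQ when the fragment record carries none |
| `min_mapq` (reconstruct) | 0 | drop fragments with *known* MAPQ below this |
| `min_mapq` (extract) | 30 | template filter on extraction, the conventional cfDNA pipeline setting |
| `threshold` (short ratio) | 150 bp | "short" means strictly `< 150` |
| `flank` / `bin` | 1000 / 10 bp | coverage-profile window and resolution |
| `center_frac` / `flank_frac` | 0.2 / 0.25 | dip-depth windows as profile fractions |
| `pseudocount` | 0.5 | frequency-scale smoothing in log2 enrichment |

The 60 bp default read length reflects typical short-read cfDNA
sequencing; because the original mate lengths are not recorded in fragment
tables, any choice is a convention, and $R = \min(r, L)$ guarantees the
convention never distorts fragment-level quantities.

## Coordinate and serialization conventions

All tabular formats (BED3, BEDPE, FinaleDB-style TSV) are read as 0-based
half-open; a `--one-based`/`one_based` switch accommodates deviant files.
BEDPE rows collapse to the outer span and must be intra-contig;
inter-contig rows are skipped and counted rather than aborting a cohort
conversion. On TSV output an unknown MAPQ is written as `0`, never a large
sentinel, so unknown quality can never accidentally pass a minimum-MAPQ
filter downstream. Unknown strand is `.` and is treated as `+` only for
first/second-in-pair assignment, which does not affect any fragment-level
coordinate.

Extraction (`bam_to_fragments`) emits one fragment per template from the
mate with positive TLEN — a single-pass rule that needs neither coordinate
sorting nor mate lookup and is single-emission by construction. The
fragment MAPQ is the minimum over both mates (reconstruction writes an
`MQ` tag so both qualities are available); templates with TLEN 0 on both
mates are ambiguous and are dropped with a count. Strand is the
orientation of the first-in-pair mate — the convention that makes
extraction invert reconstruction exactly.

## The dip statistic

Cell-type-specific open chromatin (e.g. DNase hypersensitivity sites)
leaves a local coverage dip in cfDNA from contributing tissues. The
package computes a transparent version of this signal: intervals are
anchored at their midpoints and extended by a fixed flank so all profiles
share a width; fragment-level coverage (whole fragments, not reads — the
quantity de-identified data defines) is binned, averaged over intervals,
and divided by the profile's own mean so sequencing depth cancels. Dip
depth is then mean flank coverage minus mean center coverage, and samples
are compared as z-scores against a healthy cohort (n−1 standard
deviation; leave-one-out when the sample itself is healthy).

This is intentionally a minimal statistic: no GC-bias or mappability
correction, no learned per-region bias model. It captures the definition
of a dip-depth z-score signature while remaining fully auditable; real
cfDNA footprint estimates are known to be sensitive to preprocessing, and
nothing here attempts to reproduce a specific published pipeline's values.
The 20%-center/25%-flank windows are a design choice (no published window
widths exist for the general definition) and are configurable.

## The synthetic cohort generator

The generator defines the study conditions for every test in the package:

* **Lengths**: Gaussian mixture, 70% at 167 ± 10 bp, 30% at 334 ± 20 bp,
  rounded and clipped to ≥ 1 bp — the mono-/di-nucleosomal structure of
  plasma cfDNA. The closed-form mixture CDF (`mixture_short_fraction`)
  provides the analytic oracle for the short-fragment ratio.
* **Placement**: contigs weighted by length, starts uniform over valid
  positions.
* **MAPQ**: 0.9 probability mass at 60, otherwise uniform on 0–59, so
  MAPQ-threshold filters have non-trivial content. **Strand**:
  Bernoulli(0.5).
* **Planted dips**: a fragment whose midpoint lands in a dip interval is
  rejected with the depletion probability and its position redrawn
  (redraw-until-accept). Rejection-resampling rather than thinning keeps
  per-sample fragment counts exact, which simplifies count-based
  assertions; the stationary midpoint density inside intervals is
  $p(1-d)/(1-pd)$ for interval mass $p$ and depletion $d$, and the tests
  check this closed form.
* **Determinism**: every sample draws from an RNG stream derived from
  `(seed, sample_id)` via a small string hash (kept below $2^{31}$), so
  cohorts are reproducible sample by sample and outputs are byte-identical
  across runs.

What the generator does not emulate: GC and mappability bias, sequencing
error, chromatin-dependent fragment-end preferences, or real genome
composition (contigs are i.i.d. uniform ACGT). Passing tests therefore
demonstrate the *fidelity and correctness of the transformations* — not
that biological conclusions from real cohorts transfer; on real data the
two-path identity still holds exactly (it is aligner-free), but absolute
dip depths and length ratios will reflect real biases.

## Numerical and scale choices

Reconstruction sorts records in memory; at the desk scales used throughout
(≤ 60k fragments per run, genomes ≤ 1 Mb) every operation completes in
seconds, and the documented path to larger cohorts is chunked external
sorting, deliberately out of scope here. Test and verification problem
sizes — 3 × 20k-fragment cohorts for round trips, 50k fragments for the
mixture CDF check (3σ binomial tolerance), 20 replicates of a
3-healthy + held-out + case design for dip recovery (30% depletion at 200
intervals of 400 bp on a 1 Mb contig, 20k fragments per sample) — were
chosen so that stochastic tolerances are comfortably separated from the
effect sizes being verified: at these settings the case z-score is ~15
against a healthy spread of ~1.

Degenerate inputs are handled explicitly: empty fragment sets produce a
valid header-only alignment file; an empty length distribution makes the
short-fragment ratio an error (not NaN); a healthy cohort with zero dip
variance makes the z-score an error rather than an infinity; profiles with
no overlapping fragments return all zeros with a warning. Sort ties
(records at the same position) are broken by read name and flag so output
is byte-deterministic.

## Known limitations

* BAM-scale streaming: extraction loads one BAM's records into memory;
  suitable for desk-scale and test data, not 60× whole genomes.
* The log2 length-enrichment baseline is the unweighted mean of per-sample
  frequencies (each sample counts once regardless of depth); pooled-count
  baselines would weight deep samples more and are not offered.
* No tabix random access on fragment TSVs; reading is streaming-only.
* No CRAM, no split/chimeric supplementary alignment handling.
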