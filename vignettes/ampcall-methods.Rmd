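---
title: "Calling variants from fully overlapping amplicon read pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling variants from fully overlapping amplicon read pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampcall)
```

## The setting

Highly multiplexed single-tube PCR panels amplify tens of targets at fixed
genomic coordinates, each amplicon designed to be no longer than one
sequencing read. Under paired-end sequencing both mates of a pair then span
the *entire* amplicon: every template base is read twice, once on each
strand, by the same physical fragment. `ampcall` exploits that geometry.
Its error model is deliberately minimal — no base-quality recalibration, no
local realignment — because the chemistry provides a stronger filter for
free: a true variant on a template molecule must appear at the same
position, with the same allele, in *both* mates of every read pair derived
from it, whereas a sequencing-chemistry error hits one mate at a time.

## The calling procedure

For each sample the pipeline:

1. **Forms read pairs.** Primary mapped alignment records are bucketed by
   query name; a bucket with exactly two records on one chromosome, one per
   mate, becomes a pair. Everything else is counted as an orphan and set
   aside. No duplicate marking is performed: in amplicon sequencing all
   pairs are PCR "duplicates" by construction, and discarding them would
   discard the data.
2. **Assigns each pair to one amplicon.** Because amplicon ends are fixed
   by the primers, a pair belongs to the amplicon whose (start, end) equal
   its fragment's outer alignment coordinates. The default tolerance is 0
   (exact); a positive tolerance is available for noisier aligners, with
   the smallest total coordinate discrepancy winning and ties broken by
   panel order so that assignment is deterministic.
3. **Masks primer bases.** The first `fwd_primer_len` and last
   `rev_primer_len` reference positions of each amplicon copy the primer
   oligo, not the template, so they can never show a real variant. These
   positions are *masked* — excluded from evidence — rather than trimmed,
   which keeps the read records intact for coverage accounting. The default
   of 20 bases per side matches the fixed per-end trim conventionally used
   when mapping these libraries.
4. **Extracts and normalizes observations.** Each mate's CIGAR is walked
   once against the reference: mismatches at unmasked positions become
   SNVs, `I`/`D` operations become insertions/deletions anchored at the
   preceding reference base and left-aligned so each physical edit has one
   canonical representation. Mismatches involving `N` are ignored;
   soft-clipped bases produce nothing; adjacent substitutions stay separate
   SNVs (no MNP merging).
5. **Applies pair concordance.** A pair's evidence is the intersection of
   its mates' observation sets. At per-base error rate $e$ a given false
   observation survives in a pair with probability about $(e/3)^2 \cdot e
   \cdot 3 \approx e^2/3$ per site instead of $\approx 2e$, a reduction of
   three orders of magnitude at typical $e \approx 10^{-3}$.
6. **Thresholds and genotypes.** For each amplicon, a variant with
   supporting pair count $s$ out of $t$ assigned pairs is called when $s
   \ge 2$ and $s/t \ge 0.15$; the genotype is homozygous when $s/t \ge
   0.85$, heterozygous otherwise. All three thresholds are inclusive and
   configurable (`caller_config()`). The denominator is **all pairs
   assigned to the amplicon**, not only pairs covering the position: with
   complete read-pair overlap these coincide everywhere outside the masked
   primer fringes, and the amplicon-level denominator matches how
   "percentage of read pairs" is naturally reported for this chemistry.
7. **Merges overlapping tiles and writes VCF 4.2.** A variant called from
   several overlapping amplicons collapses to one record, keeping the
   counts from the amplicon with the most pairs (ties by panel order) and
   the full provenance list. Output is byte-stable: identical input yields
   identical files, so replicate analyses can be compared with `diff`.

Proportions are reported as percentages rounded half away from zero to two
decimals (`35/94` prints as `37.23`).

### Interpreting the homozygosity rule

A "non-reference allele in at least 85% of pairs" rule is occasionally
phrased in terms of the *minor* allele; taken literally that is
self-contradictory (a minor allele cannot exceed 50%). We read it as the
variant-allele pair proportion, which is the only interpretation under
which heterozygous calls (clustered near 50%) and homozygous calls (near
100%) separate cleanly.

### Two alternate alleles at one site

Each allele is tallied and thresholded independently; two alleles at 45%
each both pass and produce two VCF records. No attempt is made to infer a
compound genotype.

## Coverage reporting

`amplicon_depths()` reports the read-pair count for every (sample,
amplicon) cell — zero-filled, so a 60-amplicon panel over 95 samples always
yields exactly 5,700 records. `coverage_summary()` pools all records and
reports the fraction at or above a depth threshold (default 10 pairs), the
pooled median, and the fraction within $k$-fold of the median for $k \in
\{5, 10, 20, 30\}$, where "within $k$-fold of median $m$" means $m/k \le d
\le m\,k$ — the symmetric band, which is the conventional reading when no
definition is printed. The bands are nested, so the within-fold fractions
are non-decreasing in $k$; the implementation asserts this on every run.
The read-level on-target percentage (any mapped read overlapping any panel
region by at least one base, out of all mapped reads) is computed
separately from pair-level assignment, mirroring how interval-overlap tools
compute it.

## The simulator

`simulate_cohort()` generates a uniform-random reference, tiles a panel of
equal-length amplicons with fixed ends across it, plants cohort genotypes,
and writes per-sample FASTQ, SAM and truth VCF. Because fragment positions
and planted edits are known exactly, the simulator writes its own correct
alignments (positions and CIGARs derived from the haplotype), so the whole
pipeline is testable hermetically, with no external aligner.

Defaults are the study conditions the package is validated against:

| parameter | default | meaning |
|---|---|---|
| `n_amplicons` | 60 | panel size |
| `amplicon_length` | 150 bp | equal to one read; mates fully overlap |
| `primer_len` | 20 bp | per side, masked in analysis |
| `n_samples` | 95 | cohort size |
| `depth_mean` | 50 pairs | mean read pairs per amplicon |
| `depth_dispersion` | 0.1 | negative-binomial overdispersion |
| `error_rate` | 0.001 | per-base substitution rate per mate |

The depth law is negative-binomial with variance $\mu + \phi\mu^2$;
$\phi = 0.1$ gives realistic between-amplicon spread (roughly $\pm$35% at
depth 50) without starving amplicons, reflecting the wide but rarely
catastrophic depth variation of multiplexed PCR panels. $\phi = 0$ gives
constant depth for exact-recovery tests. The error model is
substitution-only — the dominant short-read error mode; indel errors,
quality-score profiles, chimeric amplification and index hopping are *not*
simulated, so passing tests demonstrate correctness of the calling logic
under the stated error model, not robustness to every failure mode of real
instruments. Heterozygous carriers draw each pair's haplotype by fair
coin; homozygous carriers place the variant on every pair. Multiple
heterozygous variants of one sample in one amplicon are placed in cis on a
single alternate haplotype.

The packaged cohort preset (`table1_genotype_spec()`) plants 13 variants —
11 SNVs and two single-base insertions — across 95 samples: 53 heterozygous
plus 3 homozygous previously-identified carriers (56 calls over 11 distinct
variants) and 4 additional heterozygous calls, the carrier structure of the
blinded screen the method was validated on. Variant host amplicons and
insert offsets are fixed, spread across the panel; SNV alternate alleles
follow a deterministic base cycle, and planted indels are stored
left-normalized so truth and calls share one representation.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere internally (the VCF
  convention); BED's 0-based half-open coordinates are converted only at
  the file boundary, and writing a panel back to BED inverts the conversion
  exactly.
* Threshold comparisons subtract a $10^{-9}$ guard before `>=` so that the
  binary representation of decimal thresholds (0.15, 0.85) can never turn
  an exact boundary case (e.g. 3/20) into a miss; the guard is far below
  the $1/t$ resolution of any attainable proportion.
* An amplicon with zero assigned pairs produces no tally and no calls; an
  empty alignment file produces a header-only VCF and a zero-filled depth
  table, not an error. Zero mapped reads make the on-target percentage
  undefined; it is reported as `NA` with a warning.
* Insertions at the first aligned position of a read have no anchor base
  and are discarded; planted variants are validated to sit inside the
  unmasked insert, so the simulator can never produce that situation
  except deliberately.
* Base-quality filtering of SNV evidence exists (`min_base_quality`) but
  defaults to off: pair concordance is the error filter in this design.

## Problem sizes used in validation

The test suite exercises the full study geometry — one 60 × 95 cohort at
mean depth 50 and error 0.1% for end-to-end recovery (all 60 planted calls,
zero false positives), and a separate 100-amplicon single-sample run at
error 0.3% for the concordance-filter property (≥99% of single-mate
observations removed, no error-derived call). Unit tests use small
handcrafted panels where expected output can be enumerated by independent
oracles: brute-force pairing and assignment, exhaustive threshold sweeps,
left-shift enumeration for indel normalization, and haplotype
reconstruction round trips.

## Known limitations

* The caller assumes one sample per alignment file; demultiplexing happens
  upstream.
* Split reads, supplementary alignments and chimeric fragments are treated
  as orphans, never as evidence.
* No annotation, no joint calling, no phasing; the VCF reports sites.
* Exact coordinate matching (tolerance 0) is correct for aligners that
  preserve amplicon ends; aligners that soft-clip fragment ends need a
  nonzero `tolerance`, at some cost in discrimination between overlapping
  tiles.
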