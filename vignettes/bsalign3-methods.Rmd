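---
title: "Methods: three-letter bisulfite alignment and methylation calling"
author: "bsalign3 authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-letter bisulfite alignment and methylation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsalign3)
```

## The problem

Sodium bisulfite converts unmethylated cytosines to uracil, read as thymine
after PCR. A bisulfite read therefore differs from its genomic origin at
every unmethylated C, and a conventional aligner either rejects such reads
or biases mapping toward methylated molecules. The classical remedy is
*three-letter* alignment: convert every C to T in both the reads and the
reference before alignment, so conversion events become invisible, then
return to the original base space to count real mismatches and to call
methylation.

`bsalign3` implements this end to end: a single seed index over the
converted genome, seed-and-extend alignment with a banded edit-distance
kernel, a bisulfite-aware mismatch recount, per-cytosine CG/CHG/CHH
methylation calling to CGmap, post-alignment QC, and a read simulator with
a ground-truth ledger so mapping accuracy can be measured, not assumed.

## The single Watson+Crick index

A bisulfite read derives from either the Watson strand or the Crick strand
of the fragmented genome. Rather than maintaining two indexes and aligning
each read twice, the index concatenates, per chromosome, the C-to-T
converted Watson sequence and the C-to-T converted Crick sequence (the
reverse complement, converted in its own frame), all Watson blocks first
and then all Crick blocks. One C2T conversion of the read and one lookup
pass over this concatenation covers both strand origins; block arithmetic
maps any concatenated interval back to `(chrom, position, strand)`, and
intervals straddling a block boundary are rejected as chimeric.

Seeds are fixed-length k-mers (default `seed_len = 20`, configurable
8–32). Long seeds keep false-positive hits rare: in a uniform-random
genome a 20-mer has a vanishing chance of a spurious exact repeat, so most
reads nominate one or two candidate loci. Every k-mer position of the
concatenation is indexed except those containing N (assembly gaps would
otherwise produce meaningless hits); the index is stored as a sorted
(packed-seed, position) array queried by binary search, which is compact,
deterministic, and serializes to a plain-text manifest plus FASTA that
reload bit-identically. Seeds occurring more than `max_seed_hits` (default
1000) times stay in the index but are skipped at query time, keeping the
build deterministic while masking repeats.

## Seed-and-extend with a banded (Ukkonen) kernel

Each read contributes seeds at offsets `0, stride, 2·stride, …` plus one
flush-right seed (default `stride = seed_len`, so ~6 lookups per 100 bp
read). A hit at concatenated position `p` for the seed at read offset `o`
votes for the diagonal `p − o`; diagonals within the edit bound merge into
one candidate. Candidates are extended in vote order (ties broken by
position, at most 50 per read) by a banded semi-global alignment: the read
must align end to end, the target window is the candidate diagonal padded
by the edit bound on both sides, and the dynamic program only visits cells
within a band of half-width twice the edit bound around the implied
diagonal — the Ukkonen restriction that makes the check linear in the read
length. Evaluation stops early on a perfect (distance 0) hit.

The exported `banded_edit_distance()` is the same kernel in its global
form: it returns the exact unit-cost Levenshtein distance whenever that
distance is within the band, `Inf` otherwise, and a backtraced edit script
(M/X/I/D runs) for finite distances. The test suite checks it against an
unrestricted dynamic program (`utils::adist`) on random string pairs.

A read is reported `unique` only when the runner-up candidate is at least
`uniqueness_gap = 2` edits worse; otherwise it is `multiple` and excluded
from methylation calling, because letting ties break arbitrarily would
contaminate per-cytosine counts with reads of uncertain origin.

### The edit-distance bound

The default bound is `max(6, ceiling(0.07 × read_len))` — 7 for 100 bp
reads. This is sized from the error load the aligner is expected to
absorb: a library with a 2.5% per-base indel rate carries a
Binomial(100, 0.025) indel count per read (mean 2.5) plus roughly one
substitution visible in three-letter space, so a bound of 7 sits about
three standard deviations above the expected load and accepts the large
majority of reads even at the harshest error rate, while still rejecting
random placements (whose distances concentrate far higher). A tighter
bound of 4 would silently drop more than a tenth of the reads at that
indel rate, capping attainable accuracy well below what the method itself
supports.

## Bisulfite-aware recount in the original base space

Three-letter alignment deliberately ignores the difference between a
conversion and a genuine C/T polymorphism, so accepted alignments are
re-scored in the original base space, in the read's origin-strand frame:

* genome C, read T → conversion event (free);
* genome T, read C → true mismatch (bisulfite chemistry is one-way);
* any other inequality → mismatch; indel columns count one per base.

Mismatches on a wrong placement are spread across the alignment, so
positions are visited in a pseudo-random order with evaluation stopping as
soon as the count exceeds the bound — on average a bad alignment is
rejected after inspecting only a few positions. The visit order is seeded
from a stable hash of the read id (not from R's global RNG), which makes
the verdict and the accepted counts independent of chunking, thread count
and call order; for accepted reads the full count is order-independent by
construction. Reads failing the recount are demoted to unmapped rather
than rescued at a secondary candidate — rescue would require re-ranking
with a different objective than the one the candidates were selected
under, and affects a negligible fraction of reads at the default bound.

SAM output keeps the standard columns (FLAG 0/16, 1-based POS, CIGAR with
X folded into M) and carries the bisulfite bookkeeping in tags: `XO`
(origin strand `+W`/`-C`), `XM` (bisulfite-aware mismatches, indels
included — also used for `NM`), `XC` (conversion events), and `XR` (reason
a read is unmapped: `no_alignment`, `ambiguous`, `recount_fail`,
`discarded`).

## Methylation calling and contexts

For every aligned genome cytosine on the read's origin strand, a retained
read C is a methylated call and a read T an unmethylated call; other read
bases (sequencing errors) and indel-covered positions are ignored, the
latter because their reference correspondence is ambiguous. Context is
assigned from the reference, not the read (read Cs may be converted):
downstream on the cytosine's own strand, `CG`, `CHG` (H then G), or `CHH`
(H, H), with any N in the two-base window giving NA; NA-context sites are
dropped from output. Sites are keyed by `(chrom, Watson position,
strand)`, so the two cytosines of a palindromic CpG are separate sites.

CGmap output is the 8-column dialect consumed by MethGo-class tools:
chromosome, Watson nucleotide (C/G), 1-based position, context,
dinucleotide, level (two decimals), methylated count, total count. No
coverage filter is applied by default (`min_cov = 1`); downstream tools
filter at their own thresholds.

## QC and metagene profiles

* **Per-cycle mismatch profile** — true (bisulfite-aware) mismatches per
  sequencing cycle over unique reads; conversions are excluded, so a clean
  library is flat at the substitution error rate and adapter or quality
  problems appear as end-of-read ramps.
* **Conversion efficiency** — over all covered cytosines of an
  unmethylated spike-in chromosome (lambda phage DNA carries no
  methylation), the fraction of T calls estimates conversion efficiency.
  All contexts are pooled by default with a `ch_only` switch, since a
  spike-in is unmethylated in every context; CH-only mode guards against
  accidental CpG contamination in non-ideal spike-ins.
* **Genome windows** and **metagene profiles** — bin values are pooled
  count ratios (sum of methylated calls over sum of calls), not means of
  per-site levels: at low coverage a mean-of-levels gives every 1x site a
  weight of a 100x site and is dominated by sampling noise. Minus-strand
  features are mirrored by reflecting bin indices, which makes the
  strand-mirroring property exact rather than approximate. Defaults
  (60 body bins, 2 kb flanks in 20 bins) give the conventional metagene
  shape; plots are a thin layer over the tables and only the tables are
  tested.

## The simulator and what passing tests mean

The simulator draws read origins uniformly over non-N loci and both
strands, samples per-cytosine methylation states once per genome
(independent Bernoulli per context: `p_CG`, `p_CHG`, `p_CHH`), converts
unmethylated Cs with probability `conversion_rate`, then applies uniform
substitutions and single-base indels per base. The truth ledger records
each read's pre-error leftmost Watson coordinate; a read is scored correct
when uniquely mapped on the right chromosome and strand within 5 bp
(indels shift leftmost coordinates, so exact-coordinate scoring would
punish correct placements; 5 bp is small against the ~10 kb mean
inter-origin distance at these depths, so it cannot convert a wrong
placement into a correct one).

What the simulator does **not** model: position-dependent quality decay,
GC bias, PCR duplicates, repeat structure of real genomes, or
non-uniform methylation landscapes. Passing accuracy tests on uniform
random genomes therefore demonstrates the correctness of the machinery
(coordinate arithmetic, strand handling, conversion bookkeeping, error
tolerance), not performance on repeat-rich real genomes, where mapability
is genuinely lower and dominated by genome structure.

### Study conditions used by the checks

The accuracy evaluation uses a 1 Mb random genome and 100,000 directional
100 bp reads per indel rate in {0, 0.005, 0.01, 0.025}, with a 1%
substitution rate and 99% conversion — the top of that indel grid is the
hardest condition the method is expected to survive. Parameter-recovery
checks run at full conversion and zero sequencing error, because failed
conversion inflates apparent methylation by `0.01 × (1 − p)` and C/T
substitutions add a comparable distortion: both are properties of the
estimand, not of the caller, and at the depths used here either bias
exceeds the sampling noise the check measures against. With full
conversion every call at a site repeats that site's Bernoulli state, so
the sampling error of a pooled level uses the effective number of
independent sites, `(Σc)² / Σc²` for site coverages `c`, rather than the
raw call count. Smaller fixtures (50 kb–200 kb genomes, 10³–10⁴ reads)
back the per-module tests; they were chosen to make binomial error bars a
few tenths of a percent, tight enough to catch systematic defects.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; SAM and CGmap writers
  convert to 1-based at the boundary.
* Candidate ordering (votes desc, position asc), traceback preference
  (diagonal, then D, then I) and final-column tie-break (smallest target
  end) are all fixed, so alignment output is deterministic.
* Chromosomes shorter than the seed length are skipped with a warning;
  an all-N chromosome indexes no seeds; reads shorter than the seed
  length or made of Ns are unmapped; an empty feature set is an error
  rather than an empty profile.
* Seeds containing C never match (the converted genome contains none) —
  a converted read cannot contain C either, so this is unreachable in the
  pipeline and simply returns no hits when queried directly.

## Known limitations

Single-end directional libraries are the primary target; non-directional
mode is supported by also querying each read's reverse complement in C2T
space and flipping winners into the origin-strand frame, but paired-end
mates, soft-clipped local alignment, spliced alignment, RRBS mode and
base-quality-aware scoring are out of scope. Multi-mapped reads are
reported unmapped-by-ambiguity and never rescued. The CGmap writer emits
the 8-column dialect only (no ATCGmap), and differential-methylation
statistics belong to downstream tools.
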