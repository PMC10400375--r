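---
title: "Counting guide RNAs from staggered reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting guide RNAs from staggered reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidecounter)
```

## The read model

A pooled-screen amplicon read has the structure

```
[stagger: 0-8 random nt][constant 5' flank][guide][constant 3' flank][...]
```

The stagger prefix is introduced by staggered amplification primers so that
the guide — the only variable stretch in an otherwise constant amplicon —
does not sit at a fixed sequencing cycle, which would starve the base
caller of diversity. Its length varies read by read within a small window;
the standard design uses up to eight nucleotides, and `stagger_cap = 8` is
the package default everywhere. Paired-end dual-guide samples repeat the
structure once per mate, with the second cassette typically read from the
opposite strand.

Everything the pipeline needs beyond the FASTQ and the library — the
orientation, the flanking anchors, the stagger window — is inferred from
the data, for two reasons: vector maps are frequently unavailable or stale,
and transcription/typing errors in user-supplied adapter sequences are a
classic silent failure mode of trimming pipelines.

## Context detection

Detection operates on a subsample: the **first** `subsample_n = 10000`
reads of the file, not a random sample. FASTQ order is effectively
arbitrary with respect to guide identity, so the head of the file is an
unbiased sample for this purpose, and using it keeps detection
deterministic with no seed to manage.

*Orientation.* Reads containing any library sequence as an exact substring
vote forward; reads containing any reverse-complemented library sequence
vote reverse; the majority wins. The library is used exactly as given — if
it contains both a guide and its reverse complement, each scores for its
own orientation. If fewer than `min_hit_frac = 0.05` of subsample reads
contain a guide in the winning orientation, detection fails loudly: the
library does not belong to the sample or the data are corrupt, and any
downstream numbers would be fiction.

*Anchors.* For each subsample read containing exactly one library guide
(reads with two or more distinct guide hits are skipped — their anchor
evidence is ambiguous), the bases before and after the guide are recorded.
The 5′ anchor is grown base by base away from the guide: at each step the
modal next base is accepted while the extended string remains a suffix of
at least `anchor_consensus_frac = 0.9` of all recorded prefixes. The 0.9
consensus tolerates sequencing errors in the subsample without letting
them terminate growth; growth stops naturally at the first stagger
position, where the modal base frequency drops to ~0.25. The 3′ anchor is
grown the same way along the suffixes and may be empty (reads that end at
the guide).

*Stagger window.* The consensus flank can be longer than the stored anchor
(`max_anchor_len = 20` bounds the search pattern; longer patterns add cost
but no specificity at these error rates). The stagger length of a read is
therefore measured against the *full* flank — prefix length minus flank
length — so the reported window is the true random-prefix range, clipped
to `[0, stagger_cap]`. The anchor kept for searching is the guide-proximal
20 nt of the flank, together with its offset inside the flank; trimming
compensates for the offset. A window whose raw span exceeds the cap aborts
with an error: that pattern indicates heterogeneous adapters (e.g. two
pooled amplicon designs), which staggered trimming cannot represent.

## Trimming

Trimming is anchored Hamming matching, deliberately gap-free: stagger
offsets already absorb positional shifts, so indel tolerance in the anchor
would only blur the offset definition, and guide-internal indels are
synthesis artefacts that should not be rescued into counts. For each read
(reverse-complemented first if the context says so), the 5′ anchor is
tested at every offset in `[stagger_min − slack, stagger_max + slack]`
(clipped at zero; `slack = 1` because the detection subsample may miss a
rare stagger length). Offsets with at most `max_anchor_mm = 2` mismatches
compete; minimal mismatches win, ties go to the smallest offset. `N`
counts as a mismatch. The candidate then runs to the leftmost 3′-anchor
match at least `min(guide length)` bases downstream — guides do not
contain the scaffold start, so the leftmost match is the cassette boundary
— or to `max(guide length)` bases when the 3′ anchor is absent or missing.
A read with no qualifying offset, or with fewer than the minimum guide
length remaining, is *untrimmed*: a status, never an error, and always
part of the conservation identity `trimmed + untrimmed = total`.

`max_anchor_mm = 2` over a ≥ 6 nt anchor is the package's own default,
exposed as a parameter: with 20 nt anchors it admits realistic anchor-error
reads while keeping the false-anchor probability negligible.

## Unique-first counting

Counting cost is decoupled from sequencing depth by tallying identical
trimmed sequences first and matching each distinct sequence exactly once.
On a typical screen, millions of reads collapse to a number of unique
sequences on the order of the library size plus its error halo, so this is
the step that makes deep samples cheap.

Matching is two-layered:

- an exact hash lookup answers error-free candidates with zero mismatches;
- otherwise a **pigeonhole index** nominates candidates: every library
  sequence is split into `max_mm + 1` contiguous near-equal segments, each
  keyed by (segment ordinal, segment string, sequence length). A candidate
  within Hamming distance `max_mm` of a library sequence cannot have an
  error in every segment, so at least one of its own segments matches
  exactly, and looking up all of them retrieves a complete superset of the
  true neighbours. Nominees are verified by exact Hamming distance.

A single guide at the minimal distance is assigned; two or more tied
guides make the candidate *ambiguous*, excluded from per-guide counts and
reported in the totals — conservative counting never double-counts and
keeps `sum(counts) + placeholder + ambiguous + unaligned = trimmed` exact.
Candidates whose length matches no library length are unaligned without
search. Duplicated library sequences are grouped at load time and counted
under the first-in-file id, with the group surfaced in the QC output; this
preserves column-sum conservation while making the library defect visible.

The default `max_mm = 1` reflects the geometry of 20-mers: at one
mismatch, 60 neighbours per guide, collisions between well-designed guides
are rare and genuine sequencing errors are mostly single substitutions;
`max_mm = 2` is supported for noisier chemistry. Matching always runs in
the detected orientation only — never against both strands at once — which
is precisely what keeps a guide and its reverse complement in the same
library apart.

## Paired-end resolution

Both mates run the single-end machinery with independently detected
contexts (the second cassette usually reads from the opposite strand and
has its own flanks). One synchronized pass tallies unique *pairs* of
candidates (an untrimmed mate is a token, not a dropped read) alongside
the per-mate unique tables; each unique pair is then resolved once through
the per-mate assignment maps. Pairs are ordered — (R1 guide, R2 guide) —
because cassette positions are distinct constructs; `collapse_orientation`
folds them for libraries where order is meaningless. A pair with any
ambiguous mate is excluded entirely (a wrong pair is worse than a lost
pair when the downstream question is recombination), one unique mate makes
the pair *partial*, and the categories partition the total:
`both + partial + neither + ambiguous_involved = total pairs`. How pairs
with exactly one aligned mate should be booked is not standardised
anywhere; the explicit `partial` category is this package's accounting.

## Placeholder discovery

Libraries built by covalently-closed-circle synthesis (3Cs) derive from a
template vector whose placeholder insert can persist into the sequenced
pool. Given a vector map, the detected anchors are located on both strands
(wrapping the origin, since maps are circular), and the insert between
them is the placeholder if its length is within ±2 nt of the library guide
lengths — placeholders are guide-like inserts — and it is not itself a
library sequence; if it is one, the vector carries a real guide and there
is nothing to flag (`NULL`, not an error). The placeholder is indexed
under the reserved id `3Cs_placeholder` and its read share reported as
`placeholder_fraction`, a direct template-contamination readout.

## QC metrics

- `trim_rate = trimmed / total`; `align_rate` is reported against both
  trimmed and total reads, because both denominators are in common use and
  the headline phrase "alignment rate" is ambiguous between them.
- `observed_depth = assigned / library size`, directly comparable to the
  depth the experiment was designed for.
- `completeness = 1 − zero-count guides / library size`.
- `skew_ratio`: the P90/P10 ratio of the per-guide count distribution,
  zeros included, with nearest-rank percentiles (sorted element
  `ceil(0.9N)` over `ceil(0.1N)`). P90/P10 is the established screen-QC
  evenness convention, robust to single outliers, and is deliberately the
  *only* skew statistic emitted — one documented definition beats three
  half-documented ones. It is undefined (JSON `null`) when P10 = 0,
  i.e. when at least 10% of guides are unobserved; completeness already
  tells that story.
- Degenerate inputs never divide by zero: rates over empty samples are 0,
  and the report renders (zeroed panels) even for a 0-read file.

## The simulator

`simulate_single()` / `simulate_paired()` generate reads with exactly the
structure above: random stagger prefix (uniform over 0–7 nt by default),
constant flanks (defaults are the 3′ end of a human U6 promoter and the
SpCas9 scaffold start — the flanks a single-guide lentiviral amplicon
actually presents), a planted guide drawn from per-guide weights, uniform
per-base substitutions, optional wholly-random junk reads, optional
placeholder contamination, and optional R2 mate swapping to emulate
lentiviral template switching. All randomness flows from one integer seed;
identical seeds give byte-identical FASTQ. The returned truth table is the
exact planted multiset, which is what makes end-to-end *equality* tests
possible: an error-free simulation must reproduce the truth bit for bit,
not approximately.

What the simulator does *not* emulate — and what passing tests therefore
do not certify — are indel errors, quality-score structure (constant
quality is emitted; the pipeline is quality-agnostic by design), PCR
duplicates, and position-dependent error profiles of real flow cells. The
simulator validates the algorithmic contracts; rates on real data will
differ with the error profile of the instrument.

## Verification strategy and problem sizes

The test suite checks every engine against an independent brute-force
oracle written in plain base R: exhaustive offset scanning for trimming,
all-against-all Hamming matching for assignment (including every
enumerated 1-mismatch neighbour of a 50-guide library), and per-read-pair
resolution for the combinatorial table — the unique-first results must be
*identical*, not close. Conservation identities are asserted on every
fixture, including empty, all-junk and all-placeholder files. Randomized
end-to-end designs (varying library size, guide length, adapters, stagger
windows and orientations, ~20 seeded replicates) must recover planted
counts exactly in the error-free regime. Determinism is checked by
byte-comparing all CSV/JSON outputs across repeated runs and thread
counts. Suite-level problem sizes (hundreds to a few thousand reads per
fixture, a 100,000-read simulated screen in the acceptance script) were
chosen so the whole suite exercises every path in well under a minute per
file on a laptop-class single core.

## Known limitations

- Hamming-only matching: a guide carrying an indel is unaligned by
  design, reported in the unaligned table rather than force-fitted.
- One cassette per read; UMIs are not modelled.
- Binary SnapGene maps are not parsed; export to GenBank or FASTA first.
- Sample-level parallelism only; a single huge sample uses one core.
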