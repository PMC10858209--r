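---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

This vignette documents the models, conventions and numerical choices
behind `mitocomp`, in the spirit of a methods section: what each statistic
assumes, which parameters matter, what the synthetic generator does and
does not emulate, and where the design was genuinely open.

## The annotation model

A mitogenome is a circular molecule with an ordered set of features
(13 protein-coding genes, 22 tRNAs, 2 rRNAs, a control region, and the
replication origins OL/OH in the canonical vertebrate plan).  Coordinates
are 1-based inclusive on the heavy-strand (H) frame throughout — the
GenBank convention — and light-strand (L) features keep H-frame
coordinates; only sequence extraction reverse-complements.  A feature may
span the circular origin (`wraps_origin`), in which case its length is
`(L - start + 1) + end`.

Annotation spellings are wildly inconsistent across published tables
(`ND5` / `NAD5` / `NADH-5`, `COI` / `COX1`, `D-loop` / `control region`,
duplicate suffixes like `NADH5_0`).  All I/O funnels through a
normalization layer that maps spellings onto 40 canonical tokens; unknown
names pass through flagged rather than erroring, because comparative
tables routinely contain one-off oddities.

Container annotations are real: a D-loop may wholly contain an OH
annotation.  Both are stored; each downstream module decides which
participates (see spacers below).

## Composition and skew

AT-skew `(A−T)/(A+T)` and GC-skew `(G−C)/(G+C)` are scale-free, so the
same function accepts counts or percentages.  When the input is a
percentage vector (sum within 0.5 of 100), AT% and GC% are reported as the
literal sums without renormalization — that is how published tables print
them, and renormalizing by a 99.98 rounding artifact would shift the last
digit.

Per-region rows concatenate the H-strand reading of same-class features in
genomic order.  L-strand genes are *not* reverse-complemented here:
region-level skews are conventionally reported on a single reference
strand, and flipping the eight L-strand tRNAs would make the tRNA-class
skew incomparable with published values.  Overlapping same-class features
contribute their bases once per feature (concatenation, not union), which
matches how per-gene size totals are published.  Report rounding: 2
decimals for percentages, 3 for skews.

## Codon usage

The genetic code is NCBI translation table 2 (vertebrate mitochondrial),
obtained from Biostrings, never hard-coded; under it AGA/AGG are stops and
Trp/Met are 2-fold.  Degeneracy families are derived programmatically from
the code table; amino acids encoded from more than one codon box are split
into the conventional subfamilies (Leu1 = CUN 4-fold, Leu2 = UUR 2-fold;
Ser1 = AGY 2-fold, Ser2 = UCN 4-fold).

Incomplete stop codons — completed to UAA by post-transcriptional
polyadenylation — are *detected from the sequence*: trailing length
`len mod 3` of 1 or 2 classifies the stop as `T--` or `TA-`.  Annotation
strings never override the sequence; disagreement (a trailing base that is
not T/TA, a terminal 3-mer that is not a stop, a GTG or other alternative
start) is reported as a flag.  RSCU for a family with zero observations is
0 for all members, flagged, rather than NaN.

## Spacers and overlaps

The signed gap between chain neighbours is `start(next) − end(prev) − 1`;
the wrap pair closes the circle.  Gaps of 0 are neither spacer nor
overlap.  Two chain policies exist:

- `exclude-container` (default): a control-class feature wholly containing
  another feature is dropped from the chain.  This removes a D-loop that
  contains an OH annotation while keeping the OH, which is exactly how
  published intergenic columns are tallied (the long pre-OH spacer and the
  wrap spacer after OH both appear; the D-loop row shows no gap).
- `keep-all`: every feature participates; used by the property tests
  against a per-position occupancy oracle.

Ties for the longest spacer break by genomic order and are flagged as
ties.  The overlap total is recomputed from the negative gaps (the
packaged reference annotation yields 25 bp; a published text total of
24 bp for the same table does not match its own rows, and the recomputed
value is reported).

## Tandem repeats in the control region

Only the forward (5'→3') orientation is scanned, and substitutions only
are modelled — no indels — so the period is exact and fractional copy
numbers are well-defined.  Defaults: period 10–400 bp, minimum 1.8 copies,
maximum copy-to-copy divergence 0.1; chosen so that biologically reported
motifs (on the order of 131 bp × 2.4 up to ×5) are comfortably detectable
while microsatellite noise is suppressed.  All are overridable.

Detection, per candidate period `p`:

1. self-match vector `m[i] = (s[i] == s[i+p])`;
2. exact runs of at least `min(p, 12)` matches seed candidates;
3. score-based extension: match +1, mismatch −(1−d)/d for divergence
   budget `d`, extended to the argmax of the cumulative score each way.
   An array diverged at exactly `d` breaks even; random flanking sequence
   (75% expected mismatch) scores steeply negative, so the boundary sits
   at the array edge and never stalls on a mismatch cluster inside the
   array;
4. consensus polish: the self-match vector double-counts point mutations
   (a mutated base mismatches both neighbours at lag `p`), which can trim
   a genuine tail.  Each boundary is re-extended against the majority
   consensus in phase, absorbing up to `p−1` positions while the extension
   keeps at most `floor(2·d·t)` consensus mismatches over length `t`, ends
   on a match, and tolerates a single leading mismatch.  The factor 2
   reflects that copy-vs-consensus error is about half the copy-vs-copy
   divergence;
5. overlapping candidates (harmonics included) resolve by longest span,
   then smallest period, so a 5-copy array is reported at `p`, not `2p`.

Copy number is span/period, reported to 1 decimal.  Copy identity cuts
copies at period boundaries from the span start, compares ungapped, and
compares the final partial copy over its own length.  The planted
`divergence` in the generator is the expected *copy-to-copy* mismatch
fraction — the quantity the scanner measures — so each copy is mutated
from the motif at the rate `r` solving `2r − (4/3)r² = d` (≈ d/2).

The detector cannot, by construction, distinguish a genuine two-copy exact
microsatellite from chance: two identical adjacent 10-mers occur in an
i.i.d. kilobase with probability on the order of 10⁻³, and any faithful
scanner must flag them.  The null false-positive rate at defaults is held
under 1% by the exact-seed requirement, verified by simulation in the
suite.

## Gene order and duplications

Orders linearize from tRNA-Phe (the conventional start of vertebrate
mitogenome linearizations) after sorting by start, with strand as sign;
the token alphabet defaults to genes + control region (origins excluded),
matching how published gene-order figures draw genomes.  Breakpoint
distance reduces both genomes to their shared single-copy tokens first —
duplications are a separate observation, reported by the census — then
counts circular signed adjacencies present in one order but not the other.
It is a pseudometric (zero for rotations and reflections), verified
against a brute-force adjacency oracle.

## The synthetic generator: a stated world

The default plan mirrors a published mudskipper annotation end to end:
16,685 bp; the canonical 37-gene order; ND6 plus eight tRNAs on the
L-strand; the published start/stop classes (GTG start for COI, `T--` and
`TA-` incomplete stops where observed); the published signed gap plan,
including the −7 bp ATP8/ATP6 and ND4L/ND4 overlaps and the 495 bp
pre-OH spacer; an OH contained within the control region; and a default
base composition of A 0.30, C 0.28, G 0.155, T 0.265 (the published
whole-genome composition to the nearest half percent).  No control-region
repeat is planted by default, because the reference genome itself carries
none; family variants plant repeats, duplications, or plan edits.

Synthesis places every PCG's start/stop bases first (so overlapping
neighbours see each other's fixed bases as constraints — the ND5/ND6
overlap is only feasible because `TAA` and the reverse-complemented `TAG`
agree on their shared bases, as in the real genome), then fills PCG
interiors codon-by-codon with rejection sampling that avoids in-frame
stops, then fills RNA features, plants the repeat, and fills gaps.  An
infeasible plan (negative residual, stop-class/length disagreement, base
conflicts in overlaps, a repeat that does not fit the CR) fails validation
with a named error before any synthesis.

What the generator does *not* emulate — hence what a green test does not
establish: phylogenetically correlated sequence evolution, indels,
codon-usage bias beyond base composition, tRNA secondary structure, and
heteroplasmy.  Tests against it establish bookkeeping correctness and
detector calibration, not biological realism.

All randomness flows from the single config seed; the caller's RNG state
is saved and restored, so generation is reproducible and side-effect-free.
Members of a family inherit the base seed unless overridden, so zero-
override members are byte-identical by design.

## Numerical and edge-case choices

- Zero denominators in skews return NA with an `undefined` flag, not an
  error: a missing region class still gets a report row.
- Duplicate copy indices are assigned by ascending start, 0-based.
- Two features with identical spans abort chain building by name: that is
  always an annotation error.
- Feature tables with `from > to` require an explicit `wrap` flag, so a
  typo cannot silently become a wrap feature.
- The test suite's scale choices: 100-genome round-trip and 200-set
  occupancy properties run on small random annotation sets (seconds);
  full-genome syntheses are used where the plan itself is under test.

## Known limitations

- The GenBank writer/parser covers the flat-file subset that mitogenome
  records actually use (single spans, `complement`, origin-spanning
  `join`); it is not a general GenBank implementation.
- Repeat detection is substitution-only; an indel inside a CR array shifts
  the register and will fragment or shorten the reported span.
- Breakpoint distance is undefined below 3 shared single-copy tokens and
  deliberately ignores duplicated tokens.
- The comparative conserved-boundary count is adjacency-based and does not
  attempt rearrangement-scenario inference (TDRL/DMNL reconstruction is
  narrative in the literature, not algorithmic).
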