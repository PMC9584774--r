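---
title: "Detecting higher-order repeats with recurrence-distance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting higher-order repeats with recurrence-distance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmhor)
```

# The model

A *higher-order repeat* (HOR) is a two-level tandem structure: primary
repeat units (*monomers*) that diverge substantially from one another
(around 20% for the ~1.6-kb NBPF/Olduvai units, 20–40% for α satellite) are
grouped into blocks of *n* monomers, and whole blocks recur with much
smaller mutual divergence (often below 2%). The asymmetry is the signature:
divergence **between** HOR copies is an order of magnitude smaller than
divergence **within** a copy. It also dictates the efficient search order —
find the long, nearly identical HOR unit first, then derive the divergent
monomers from its internal structure.

`grmhor` realizes this in two workflows:

* **HOR-searching**: recurrence spectrum → repeat-length peak → copy
  segmentation → consensus → internal monomer structure;
* **monomer-searching**: locate known consensus monomers anywhere by
  edit-distance alignment, then assemble HOR copies and arrays from the
  hit stream.

## The recurrence-distance spectrum

For a chosen K, every window of K consecutive bases drawn from
`{A, C, G, T}` is indexed at its start position — the *complete* K-string
ensemble. Windows containing `N` are skipped (an `N` never matches
anything, here or in any alignment in the package), but their coordinates
are retained so that all reported positions remain assembly positions. For
each K-string with occurrence positions $p_1 < p_2 < \dots < p_m$, every
consecutive difference $p_{i+1} - p_i$ up to a cap contributes one count at
that distance. A tandem with unit length $L$ concentrates counts at exactly
$L$; substitutions in some copies shift individual K-strings' recurrences
to $2L, 3L, \dots$ (harmonics) rather than destroying the signal, and
indels smear the peak by a few bp, which the peak detector's smoothing
absorbs. This histogram over distances is the "frequency domain" in which
repeats are read off; no numerical transform of the sequence is involved.

Two choices here were genuinely open:

* *All pairs or consecutive pairs?* We count only consecutive occurrences
  of each K-string. This keeps the total count linear in the number of
  windows, makes an exact-tandem spectrum supported on $\{L\}$ alone, and
  gives the clean pair-census invariant that the test suite checks against
  a brute-force hash walk.
* *Which K?* The spectrum is parameter-light but K matters at the margins.
  The default K = 21 makes chance recurrence within the 20-kb cap
  negligible even at chromosome scale ($4^{21} \approx 4\times10^{12}$)
  while leaving most K-strings intact between HOR copies at ~1%
  divergence ($0.99^{21} \approx 0.81$ per copy). K is exposed as `--kmer`
  everywhere.

## Peaks, key strings, segmentation

Peak detection smooths the dense spectrum with a 5-bp moving average,
takes neighbourhood maxima (minimum separation 50 bp), and expands each
peak's window from the raw modal distance while raw counts stay above 10%
of the modal count; the peak's mass is the raw count inside the window.
None of these constants comes from a published criterion — the original
method reports peaks without stating one — so all are exposed
(`min_mass`, `smoothing_window`, `min_separation`, `window_frac`).

The *key string* of a peak is the K-string with the most
consecutive-occurrence pairs at the peak spacing, ties broken
lexicographically for determinism. Cutting the sequence at its occurrences
yields copy fragments; fragments are kept when their length lies within
[0.85, 1.15] × peak center. That tolerance, not the detected peak window,
bounds copy lengths: real monomer variants differ by ±3% and the detected
window (a 10%-of-mode expansion) is usually far narrower than the true
copy-length spread. Terminal partial fragments are discarded, which costs
one copy per array end and is the price of anchor-based segmentation.

## Consensus construction

The consensus is a star alignment: the medoid copy (minimum summed edit
distance to the others) seeds the template, every copy is globally aligned
to it with unit costs, and each template column takes a majority vote over
`{A, C, G, T, -}`. Columns with a strict gap majority are deleted;
insertions relative to the template survive only with a strict majority,
taking the most frequent inserted string. Ties among bases fall back to
the fixed order A < C < G < T; alignment traceback prefers
diagonal > deletion > insertion. Both rules exist purely so that identical
inputs give identical outputs. The vote iterates until the consensus is a
fixed point (at most `max_rounds = 5`; in practice one or two rounds).
With isolated errors the vote provably restores the original unit, which
the test suite checks by planting disjoint mutations.

## Internal structure and monomer discovery

Running the spectrum on a single ~4.8-kb consensus would truncate
periodicity at the sequence end, so the consensus is concatenated with
itself and the trivial full-length recurrence excluded. Two deliberate
deviations from the genome-scale defaults apply here:

* **K = 12** for the internal spectrum. Monomers within a HOR unit diverge
  by ~20%, so exact 21-mers shared between them are rare
  ($0.8^{21} \approx 0.9\%$ of positions) while 12-mers survive at
  $0.8^{12} \approx 7\%$; chance 12-mer recurrence in a doubled consensus
  of ~10 kb is still negligible ($4^{12} \approx 1.7\times10^{7}$).
* **Widened key-string window.** Monomer lengths inside one HOR unit differ
  by a few percent (1623/1593/1554 bp in the NBPF case), so the spacings of
  a K-string conserved across all monomers spread around the internal peak
  center. The key string is therefore selected over the same ±15% window
  used for copy segmentation.

If the smallest internal peak $p$ divides the consensus into
$n \approx L/p \ge 2$ parts, the consensus is cut at the internal key
string's occurrences. Because the key string sits at some homologous offset
inside the monomers, the reported monomers are a *rotation* of the
consensus; lengths and count are unaffected.

## Monomer scan

The scanner finds, for each consensus monomer, all locally optimal infix
(semi-global) alignments: a forward column dynamic program computes the
best edit distance of the full consensus against an infix ending at every
text position; ends under the divergence cutoff survive non-maximum
suppression (no two kept ends within half a consensus length), and a
reverse pass per surviving end recovers the start (ties prefer the shorter
infix, which keeps abutting tandem hits from overlapping). The scan is
exhaustive rather than seeded: at the package's target scale (hundreds of
kb against ~1.6-kb consensuses) the exact $O(mn)$ kernel runs in seconds,
and exactness makes the result set — the actual contract — trivially
well-defined. Overlapping hits from different consensuses are resolved
greedily by ascending divergence, keeping a hit when it overlaps no kept
hit by more than 10% of its own length.

`max_divergence` defaults to 25%: generous enough to pick up old dispersed
monomer relics, far below the ~40%+ divergence of random 1.6-kb matches.
The cutoff the original analyses used is not published; 25% is this
package's choice and is exposed on the command line.

## Divergence conventions

Edit (Levenshtein) distance with unit costs underlies every divergence in
the package; `N` matches nothing. Two normalizations coexist and are fixed
package-wide:

* **classification / scan hits**: 100 × distance / *consensus length* —
  the reference is the consensus, so its length is the natural scale;
* **pairwise copy or monomer comparisons**: 100 × distance / *max of the
  two lengths* — symmetric, and bounded by 100.

Inter-copy divergence of an array is the mean over all unordered copy
pairs on full HOR-copy sequences; intra-copy divergence is the mean over
copies of the mean pairwise divergence among that copy's monomers. The
distance kernel is a banded (Ukkonen) dynamic program whose band doubles
until the result is provably exact, so divergences are never
approximations.

## Canonical HOR calling

A HOR copy is three adjacent monomer hits following the cyclic label order
(any starting phase). It is *canonical* when (i) every monomer diverges
from its consensus by less than `div_threshold` (default 5%) and (ii) the
copy belongs to a tandem run of at least `min_tandem` such copies
(default 3: the copy plus two or more). Whether a doublet of two perfect
copies deserves canonical status is ambiguous in the source definition, so
it is a parameter rather than a hard-coded answer. Leftover hits are
reported as noncanonical copies with a reason — `above_threshold`,
`out_of_order`, `partial`, `isolated` — rather than silently dropped.
`max_gap` (default 100 bp) bounds both the hit-to-hit and copy-to-copy
gaps; true monomers in an array abut, and the slack only absorbs alignment
end jitter.

# The simulator: what it emulates, what it does not

`hor_sim_params()` defaults *are* the study conditions: monomer consensus
lengths 1623/1593/1554 bp, ~18% pairwise consensus divergence, HOR copies
mutated from the m1+m2+m3 unit at a 0.8% per-copy substitution rate (so
~1.6% expected pairwise copy divergence) plus single-base indels at
5×10⁻⁴ per base, and four tandem arrays of 19/13/11/7 copies — a 50-copy
census — in random flanks. Flank length (5 kb), inter-array gap (3 kb) and
GC content (0.42, roughly the chromosome-1 value) are this package's
choices where no value was stated.

The monomer consensuses are produced by mutating an ancestral sequence on
three independent branches and deleting down to the target lengths, with
the branch rate tuned by mutate-and-measure until the *measured* pairwise
divergences — measured exactly as the annotation module measures them —
land within 2 points of the target. Targeting the measurement rather than
the nominal rate is deliberate: the measurement is what downstream code
sees.

The generator does **not** model gene conversion, duplication phylogenies,
position-dependent mutation, large structural variants, soft-masking
artefacts, or assembly gaps. Passing the recovery tests therefore shows
that the pipeline is correct *under the stated statistical regime*; it
does not certify behaviour on, say, centromeric satellite with unsequenced
gaps. One systematic consequence worth knowing: monomers inside simulated
copies carry the copy mutations on top of the consensus divergence, so the
measured intra-copy divergence sits about 1–1.5 points above the 18%
consensus target — visible in the array statistics and entirely expected
from the model.

All randomness flows through the seed in the parameter object
(`withr::with_seed`; the assembly stage derives seed + 1), so a fixed seed
reproduces every output byte for byte — an invariant the test suite
asserts on file checksums.

# Validation strategy and problem sizes

The test suite validates each layer against an independent route:

* spectrum counts against a brute-force environment-hash census over 50
  mixed random sequences up to 10 kb at K ∈ {5, 8, 12, 21}, plus the
  closed-form exact-tandem case (10 × "ACGTT" at K = 5 gives a single
  count of 41 at distance 5);
* edit distances and classification against `utils::adist` on random and
  mutated pairs up to 2 kb;
* overlap resolution against an independently written greedy reference on
  randomized fixtures;
* end-to-end recovery on the default simulated genome (~257 kb): exactly
  50 canonical copies partitioned 19/13/11/7, every truth monomer
  recovered with its correct label, and the top spectrum peak window
  containing the realized HOR length;
* estimator consistency over 20 seeds of 10-copy arrays
  (substitution-only, since the 1.6% expectation is the substitution
  process): the mean inter-copy estimate within 3 standard errors of
  1.6% and intra-copy within 2 points of 18%.

These sizes keep the full suite around a minute on one core while leaving
every statistical check adequately powered; `scripts/acceptance.R` re-runs
the default-genome pipeline end to end and writes its principal numbers as
JSON.

# Known limitations

* The K-string index is an in-memory hash over all windows; desk-scale
  inputs (up to a few Mb) are comfortable, full chromosomes are not the
  design point. No compressed or suffix-automaton index is provided.
* Segmentation discards terminal partial fragments, so arrays contribute
  one fewer segmented copy than planted; consensus building is unaffected.
* The scanner reports plus-strand hits by default (`both_strands = TRUE`
  exists); no HMM/profile search, no protein-space search.
* Internal-structure discovery assumes the monomer count is small
  (`n ≈ L/p`); deeply nested multi-level HORs are visible as multiple
  internal peaks but only the smallest dividing period is segmented.
* Canonical calling depends on the supplied consensus set; with a poor
  consensus set the divergence threshold, not the algorithm, decides what
  survives.
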