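---
title: "Detecting viral integration sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting viral integration sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Integration of viral DNA into a host genome — hepatitis B virus into human
chromosomes being the canonical clinical example — leaves a characteristic
signature in whole-genome paired-end sequencing: *chimeric* read pairs whose
sequence spans both genomes, and *split reads* whose prefix aligns to one
genome and suffix to the other. The difficulty is that junction-covering
reads are few (the virus is a tiny fraction of the library), the viral
sequence may diverge substantially from any reference strain, and junctions
can fall in repetitive host regions that produce ambiguous placements.
`vintegrate` detects integration sites from such data and reports host and
virus breakpoint coordinates, support counts, and explicit exactness and
ambiguity flags.

# The procedure

The caller runs as a funnel of progressively more expensive, more specific
stages.

**1. Candidate screening (stage X1).** Starting from raw read pairs (or the
soft-clipped/unmapped-mate pairs pulled out of an existing host alignment by
`extract_candidate_pairs()`), every mate is scanned with k-mers sampled at
positions 1, 1+s, 1+2s, ... plus the final full k-mer, and a pair survives
when any sampled k-mer occurs in the virus database, on either strand,
within r mismatches (`screen_params()`: k = 18, r = 1, s = 5). The k = 18,
r = 1 setting is sensitive enough to pick up viral fragments down to the
scale of a single k-mer while the shift s = 5 keeps the scan cheap; the
final-k-mer rule exists so read tails are not blind spots. The screen is an
exact all-hits index lookup (hash of every database k-mer with neighbourhood
enumeration), so it has no mapper heuristics to miss diverged strains — any
read carrying one 18-mer within one mismatch of any strain passes.

**2. Alignment confirmation (stages X2, X_chimera).** Survivors are
re-examined with a sensitive seed-and-extend local aligner (`local_align()`):
exact 11-mer seeds are chained by diagonal, and each chain is extended by a
full affine-gap (Gotoh) local alignment inside its subject window, with
successive non-overlapping alignments per window recovered by masking
(Waterman–Eggert style) so tied placements of repeated sequence all surface.
Hits shorter than 25 aligned columns are not reported — that floor is the
practical sensitivity limit of local alignment here, and everything below it
is handled later by split-read rescue. Hits are scored with Karlin–Altschul
expect values, `e = K * m * n * exp(-lambda * score)`; the ungapped constants
(K = 0.41, lambda = 0.625) are applied to gapped scores, an approximation
that is immaterial because only the ordering of hits and a permissive cutoff
(`max_e = 1e-3`) feed the downstream logic. Pairs with a viral hit form X2;
pairs from X2 with a host hit form the chimeric set. Host hits are ranked
(rank N = number of hits with expect value at or below one's own) and pass
the retention rule: keep all ties at the best expect value, or — when the
best is unique — the best plus the runner-up, since a unique best may be
noise and keeping the runner-up preserves the true placement.

**3. Clustering.** Retained host hits are sorted per chromosome and chained
into clusters wherever consecutive hits lie within `d + 2*sigma` of each
other, d and sigma being the library insert-size mean and standard
deviation (`library_stats()`, estimable from a BAM with
`estimate_library_stats()`). Each cluster is partitioned by junction
geometry: a hit whose read prefix aligns on the host + strand, or suffix on
the − strand, witnesses a junction with host 5' of the virus (side C+); the
complementary configurations witness host 3' of the virus (C−); whole-read
alignments follow their strand. Prefix/suffix is judged on the forward-read
query span with a 3 bp edge tolerance absorbing aligner end-trimming, and
alignments internal to the read (fitting no junction geometry) are set aside
as noise.

**4. Refinement.** Three cleanups per cluster: (i) pairs in which any single
mate shows more than one host or more than one virus segment (for example
virus–host–virus) are discarded as complex; pairs with both mates
host-mapped must be same-chromosome and forward–reverse oriented; (ii)
identically aligned pairs are optionally collapsed to one copy (on by
default — identical chimeric fragments in a whole-genome library are almost
surely duplicates); (iii) a mate with a viral hit and at least 10 contiguous
unaligned bases, whose mate is host-anchored and not itself split, has its
unaligned portion Smith-Waterman-aligned against the `d + 2*sigma` host
window flanking the anchor on the junction-facing side. An alignment with
at least 90% identity over at least 10 bases rescues the read as a true
split read with an exact host coordinate; the 10 bp floor mirrors the
attempt threshold, and both are configurable.

**5. Breakpoint calling.** For each oriented sub-cluster: the host
breakpoint estimate is the junction-proximal alignment extremum — maximum
aligned end for C+, minimum aligned start for C−. The estimate uses the
host-*aligned* end of each read rather than its raw length so that unaligned
viral tails cannot push the estimate past the junction; without a
junction-spanning read it can undershoot by up to the maximum insert span.
The virus side is decided by a strand vote: the best viral hit of each read
and mate is assigned to V+ or V− by raw alignment strand, and a side must
outnumber the other by at least epsilon (= 2) reads to win, otherwise no
virus coordinate is reported. Because the mates lying deep inside the virus
dominate this vote, a C+ cluster over a forward-integrated virus is won by
V−, and the four host-side x winning-strand combinations map to integration
orientation and junction-proximal extremum as: C+/V− → orientation "+",
5'-most; C+/V+ → "−", 3'-most; C−/V+ → "+", 3'-most; C−/V− → "−", 5'-most.
(The last two follow from the first two by symmetry of the fragment
geometry.) When split reads exist, each witnesses the integration
orientation directly as the product of its host and virus alignment strands
— a quantity independent of which fragment strand was sequenced — and if one
orientation outnumbers the other by epsilon, the lower medians of the
winning split reads' host and viral junction coordinates become the
breakpoint, flagged exact. Clusters without a usable split-read majority
fall back to consensus assembly: member reads are greedily merged on
overlaps of at least 30 bp with identity above 75%, columns are called by
majority vote, and the consensus is realigned — a unique best host placement
followed by a viral hit on the remainder yields an exact call at the
boundary, while tied host placements yield one call each, marked ambiguous.
Finally, only clusters whose median host-hit rank is 1 (unambiguous
placements) enter the main call table; the rest are written to a separate
unreliable table that users can inspect for repeat-region candidates.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `screen.k` / `r` / `s` | 18 / 1 / 5 | bases / mismatches / bases | screening sensitivity vs. cost |
| `align.word` | 11 | bases | exact seed length |
| `align.min_len` | 25 | bases | shortest reportable alignment |
| `align.max_e` | 1e-3 | — | expect-value cutoff |
| match/mismatch/gap open/gap extend | +2/−3/−5/−2 | score | blastn-like scoring regime |
| `d`, `sigma` | data-dependent | bases | cluster window `d + 2*sigma`, rescue flank |
| `epsilon` | 2 | reads | strand-vote and split-promotion margin |
| `min_support` | 1 | pairs | reporting floor (4 is sensible for real libraries) |
| `refine.min_unaligned` / `min_span` / `min_identity` | 10 / 10 / 0.9 | bases / bases / fraction | split-read rescue thresholds |
| `correctness_window` | 300 | bases | evaluation-only match radius |

The scoring constants and word size are exposed in `align_params()` because
nothing downstream depends on their exact values — only on the presence and
relative ordering of hits — so any blastn-like regime behaves equivalently.

# The simulator, and what passing its tests does not show

`simulate_infected_genome()` reproduces the benchmark design at desk scale:
uniform-random host chromosomes (default four of 50 kb) each infected by its
own random virus strain (3 kb, the scale of an HBV genome), 100 planted
integrations of 500–1500 bp viral segments in random orientation, each
region extracted with 500 bp host flanks; `simulate_read_pairs()` draws
paired 100 bp reads at 20X with Gaussian inserts (d = 300, sigma = 30,
clamped to the feasible range), forward–reverse orientation, and independent
substitution errors at 1e-3; `downsample_pairs()` thins pairs independently
for the 50%/25% robustness replicates. All randomness flows from one seed,
and identical seeds give byte-identical FASTA/FASTQ output.

Two deliberate departures from real data must temper any conclusions drawn
from the simulation. First, uniform-random genomes contain no repeats, so
repeat-driven false positives and rank-ambiguous clusters are
under-represented: simulated false-positive fractions are lower bounds and
sensitivity figures upper bounds for real genomes. Second, junctions are
planted *homology-free*: the virus segment is redrawn until no local
alignment can profitably extend across any junction in either genome
(scored over a 12 bp window). Real integrations frequently show junction
microhomology, under which the breakpoint coordinate is intrinsically
ambiguous within the homology tract; planting clean junctions is what makes
"exact calls deviate by zero" a testable property rather than an undefined
one. The error model is substitution-only; indel-bearing junction reads are
exercised through the gapped aligner's own tests instead of the bulk
simulator.

`evaluate_calls()` scores a call as correct when it lies within 300 bp of an
unmatched planted junction with matching host side and integration
orientation, matching greedily one-to-one in order of increasing distance.
Each planted integration contributes two side-specific truth junctions (5'
and 3'), and sensitivity is counted over junctions; the false-positive
fraction is reported as fp / (tp + fp), i.e. the fraction of reported calls
that are wrong. `roc_table()` sweeps the support threshold to trace the
sensitivity / false-positive trade-off.

# Numerical and design choices

* **Coordinates** are 1-based and fully closed everywhere, the native
  convention of the R/Bioconductor containers this package builds on; call
  tables are therefore directly comparable with SAM/VCF-style coordinates.
  A C+ host breakpoint is the last host base before the virus; the C−
  breakpoint is the first host base after it.
* **Lower medians** are used wherever an even-sized set is summarised
  (cluster ranks, split-read junctions): deterministic, integer-valued, and
  conservative for the rank-1 filter.
* **Ties** are broken deterministically throughout — hits sort by expect
  value, then score, subject and position; duplicate collapsing keeps the
  lexicographically smallest read id; consensus columns tie toward the
  first-encountered base — so identical inputs give byte-identical outputs.
* **Overlap masking** removes a hit only when both its query span overlaps a
  better hit's span by more than half and the subject spans overlap: that
  deletes seed-ladder duplicates (the same placement re-found from adjacent
  windows) while keeping distinct placements of repeated sequence on one
  chromosome, which the ranking and ambiguity machinery need.
* **Degenerate inputs**: `N` bases match nothing anywhere (screen, aligner,
  overlap scoring); mates shorter than k simply contribute nothing to the
  screen; an empty chimeric set produces an empty, well-formed call table.
* **Split-read exactness** requires the epsilon majority. A single split
  read still refines the breakpoint *position* (`host_breakpoint()` exposes
  the median override directly) but one noisy alignment is not treated as
  proof, so the exact flag is only set when split reads corroborate each
  other.
* **Problem sizes**: the test suite runs the full caller end-to-end on
  replicas of 8–100 junctions (about 1,700–20,000 read pairs against a
  40–200 kb host); these sizes exercise every stage, including downsampling
  robustness, while keeping a complete run in minutes on one core. The same
  100-junction replica backs `scripts/acceptance.R`.
* **Threading**: the implementation is deterministic and single-threaded;
  the CLI accepts `--threads` for interface compatibility and ignores it,
  which makes the results trivially independent of thread count.

# Limitations

Uniform-random simulation cannot certify behaviour on segmental
duplications, satellite repeats or polymorphic hosts; the unreliable-cluster
table is the designed escape hatch there, not a solved problem. The caller
assumes forward–reverse short-insert libraries; mate-pair (RF) chemistry
would need the orientation table transposed. Viral strains more diverged
from the database than one mismatch per 18-mer can slip the screen; adding
strains to the FASTA database is the intended remedy, since nothing in the
pipeline assumes a single strain. CRAM input and BAM writing are out of
scope, as are clonality genotyping and allele-frequency quantification.
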