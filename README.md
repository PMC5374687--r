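# vintegrate

Detection of viral integration sites in a host genome from paired-end
sequencing reads.

Integrated viral DNA — hepatitis B virus in liver cancer being the textbook
case — betrays itself through *chimeric read pairs* that span the host/virus
junction and *split reads* whose prefix aligns to one genome and suffix to
the other. These reads are rare (the virus is a sliver of a whole-genome
library), the infecting strain may diverge from every reference, and
junctions can land in repeats. `vintegrate` is built around that reality:
a fast mismatch-tolerant k-mer screen finds candidate pairs without mapper
heuristics, a sensitive seed-and-extend local aligner confirms them, and a
clustering/refinement/assembly stack turns them into breakpoint calls with
explicit support counts, exactness and ambiguity flags.

## The method in brief

Reads flow through a narrowing funnel:

1. **Screen (X1)** — a pair survives when any k-mer sampled along either
   mate (k = 18, every 5 bp, plus the final k-mer) occurs in the virus
   database within r = 1 mismatch, on either strand (all-hits hash index).
2. **Confirm (X2, X_chimera)** — survivors are locally aligned
   (seed-and-extend, affine-gap Smith-Waterman extension, alignments ≥ 25 bp,
   Karlin-Altschul expect values `e = K·m·n·e^(−λS)`) first against the
   virus database, then against the host genome. Host hits are ranked by
   expect value and pass a retention rule (all best-e ties; or the unique
   best plus runner-up).
3. **Cluster** — retained host hits within `d + 2σ` of each other
   (insert-size mean and SD) chain into clusters, partitioned into C⁺
   (host 5′ of virus) and C⁻ (host 3′ of virus) by read orientation
   geometry.
4. **Refine** — complex layouts and mis-oriented host–host pairs are
   dropped, duplicates optionally collapsed, and reads with ≥ 10 unaligned
   bases next to a viral hit are rescued as split reads by targeted
   Smith-Waterman against the `d + 2σ` flank of their anchor mate.
5. **Call** — per oriented sub-cluster: host breakpoint = junction-proximal
   alignment extremum (`max(L + len)` for C⁺, `min(L)` for C⁻); virus
   breakpoint by an ε-majority strand vote (ε = 2) over V⁺/V⁻; split-read
   medians override both and set `exact = 1` when one orientation has an
   ε-majority; clusters without usable split reads fall back to
   overlap-consensus assembly (≥ 30 bp overlaps, > 75% identity) and
   realignment, with tied host placements reported as `ambiguous`. Only
   median-rank-1 clusters enter the main table; the rest go to a separate
   unreliable table.

A seeded simulator (`simulate_infected_genome()`, `simulate_read_pairs()`,
`downsample_pairs()`) reproduces the benchmark design — random host
chromosomes infected by several virus strains, regions extracted with
500 bp flanks, 20X Gaussian-insert paired reads, 50%/25% thinned replicates
— and `evaluate_calls()` / `roc_table()` score calls against the planted
truth (correct = within 300 bp, matching side and orientation).

See `vignettes/viral-integration-detection.Rmd` for the full model,
parameter table, and design rationale.

## Worked example

Simulate eight integrations on two 20 kb chromosomes, call them, and score
the calls:

```r
library(vintegrate)

sp  <- sim_params(host_len = 20000, n_chroms = 2, n_viruses = 2,
                  n_integrations = 8, seed = 7L)
sim <- simulate_infected_genome(sp)
pairs <- simulate_read_pairs(sim)

res <- detect_integrations(pairs, sim$host, sim$viruses,
                           library_stats(sp$d, sp$sigma), verbose = TRUE)
#> input      1698 pairs
#> X1         1275 pairs
#> X2         1258 pairs
#> X_chimera  492 pairs
#> clusters   8
#> split reads 218
#> calls      16 (+0 unreliable)

tidy(res)
#> # A tibble: 16 × 9
#>   host_chr host_pos host_side virus_id virus_pos virus_orient n_pairs n_split
#> 1 chr1         4307 5p_host   virus1        1253 +                 30      14
#> 2 chr1         4308 3p_host   virus1        2490 +                 34      10
#> 3 chr1         9266 5p_host   virus1        2116 -                 29      12
#> ...
```

Of the 1,698 simulated pairs, 1,275 carry a viral k-mer, 1,258 survive the
viral alignment check, and 492 also hit the host genome; they form 8
positional clusters, i.e. 16 oriented sub-clusters — one per junction side.
Each call row gives the host coordinate of the junction (`host_pos`,
1-based; `5p_host` means host lies 5′ of the virus there), the viral
coordinate joined at that junction with the integration orientation, the
number of supporting pairs and split reads, and flags. Scoring against the
planted truth:

```r
evaluate_calls(res$calls, sim$truth)
#> <vint_eval> tp = 16, fp = 0, fn = 0 | sensitivity = 100.0%,
#>             fp fraction = 0.0% (window 300 bp)

roc_table(res$calls, sim$truth)   # tp/fp swept over the support threshold
```

All 16 junction sides (two per integration) are recovered, every call is
split-read exact, and no false calls are made — expected on repeat-free
random genomes; see the vignette for why real genomes are harder.

A thin CLI with `call`, `sim`, `eval` and `roc` subcommands lives at
`inst/cli/vintegrate.R` for shell use; `call` accepts either a FASTQ pair or
a host BAM (pre-filtered via soft-clip/unmapped extraction).

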