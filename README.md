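# flowalign

Flow-space assisted local alignment for 454-style pyrosequencing reads.

## The problem

Pyrosequencing estimates each homopolymer's length from a single flowpeak
intensity, so its dominant read error is the homopolymer indel — an overcall
or undercall — rather than the substitution most aligners are tuned for.
Under standard Smith-Waterman-Gotoh scoring every miscalled homopolymer costs
a full affine gap, which truncates or misplaces alignments precisely where
the instrument was least certain.

`flowalign` implements a local aligner that can *re-call* a homopolymer while
aligning, at a price proportional to the flowpeak deviation that re-call
requires. For a peak `f` called as an `n`-mer, re-calling it as an `m`-mer is
penalized

    P = round(alpha * Dev_m / n),    alpha = G0 / k

where `Dev_m` is the distance from `f` to the rounding interval
`[m - 0.5, m + 0.5)`, `G0` is the minimum gap penalty, and `k` (default 0.25)
is the relative deviation at which a correction costs as much as a gap —
`k = 0` disables corrections and reverts exactly to Smith-Waterman-Gotoh.
Each DP cell takes `C = max(D, S)`, where `D` is the ordinary Gotoh score and
`S` applies a pre-tabulated down-call (query homopolymer bases against
database gaps) or up-call (inserted query bases consuming identical database
bases) of up to four bases. Corrected bases appear lower-case in the output
and carry no substitution score; penalties are kept only when strictly
cheaper than the equivalent ordinary gap.

The package is intended for people working with flowgram-based reads (454,
and by extension other flow-space chemistries) who need homopolymer-aware
local alignments, plus the surrounding tooling: SFF and FFASTA (flowgram
FASTA) readers/writers, an SSAHA-style k-tuple database index with a
diagonal seeding heuristic, a seeded noisy-flowgram read simulator, and
decoy-recovery / read-mapping evaluation harnesses.

## A worked example

A read called `TAAT` whose A-flow peaked at 2.40 — almost three A's — aligns
full-length to `TAAAT` through a one-base up-call:

```r
library(flowalign)
read <- call_flowgram(flowgram("r1", "TAT", c(1.0, 2.40, 1.0)))  # "TAAT"
flow_align("TAAAT", read)
#> <alignment_result> r1 vs db (flow, strand +)
#>  score 7, identity 0.800, db [0,5), query [0,4)
#>  corrections: up+1@3(-1)
#>
#> db         1 TAAAT 5
#>              ||| |
#> query      1 TAAaT 5
```

The up-call inserts a lower-case `a` (an extra A justified by the 2.40 peak)
at a penalty of `round(20 * 0.10 / 2) = 1`, for a score of 4 matches x 2 - 1
= 7. Plain Smith-Waterman-Gotoh on the same pair stops at the ungapped
3-mer:

```r
swg_align("TAAAT", read$sequence)
#> <alignment_result> query vs db (swg, strand +)
#>  score 6, identity 1.000, db [0,3), query [0,3)
#>
#> db         1 TAA 3
#>              |||
#> query      1 TAA 3
```

Against `TAACT` no correction is possible (the consumed database base `C` is
not an `A`), and `flow_align()` returns the plain alignment.

At scale, `build_index()` + `flow_search()` run the indexed two-strand
search, and `recovery_experiment()` / `mapping_experiment()` reproduce the
package's evaluation designs: decoy recovery among 100 decoys at 92%
identity, and per-nucleotide mapping accuracy of simulated noisy-flow reads
(see the methods vignette in `vignettes/`).

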