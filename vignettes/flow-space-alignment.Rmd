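---
title: "Flow-space assisted local alignment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-space assisted local alignment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowalign)
```

## The problem

454-style pyrosequencing reads a template by cycling nucleotide reagents
(T, A, C, G) over it and recording, per flow, a light intensity — the
*flowpeak* — approximately proportional to the length of the homopolymer
incorporated at that flow. Base calling rounds each peak to the nearest
integer: a peak of 2.60 calls `AAA`, one of 0.49 calls nothing. The dominant
error mode is therefore not the substitution but the homopolymer
*overcall*/*undercall*: an indel, which ordinary alignment scoring punishes
with a full affine gap. A single miscalled homopolymer needs several flanking
identities to outweigh a gap-open penalty, so alignments of pyrosequencing
reads terminate early or place gaps at the wrong position.

The remedy implemented here is to let the local aligner *re-call* a
homopolymer during alignment, at a price proportional to how implausible the
re-call is given the recorded flowpeak. A peak of 2.60 is cheap to re-call as
`AA` (it was nearly ambiguous) and expensive to re-call as `AAAAA`.

## Scoring model

`scoring_model()` holds the Smith-Waterman-Gotoh parameters — match and
mismatch scores, gap-open penalty $G_0$ (the cost of a length-1 gap) and
gap-extension penalty $G_e$ (each additional gap base) — plus the
flow-deviation parameter $k$. Defaults are match/mismatch $2/-3$, gaps $5/2$,
$k = 0.25$.

A flowpeak $f$ calls as $n = \lfloor f + 0.5 \rfloor$ bases (the $\geq 0.5$
boundary belongs to the positive flows). The deviation needed to call it as
$m$ bases instead is the distance from $f$ to the rounding interval
$[m - 0.5,\, m + 0.5)$:

$$\mathrm{Dev}_m(f) = \begin{cases}
0 & \lfloor f + 0.5\rfloor = m\\
f - (m + 0.5) & m < \lfloor f + 0.5\rfloor\\
(m - 0.5) - f & m > \lfloor f + 0.5\rfloor .
\end{cases}$$

The correction penalty is proportional to the *relative* deviation,

$$P = \alpha \,\mathrm{Dev}_m / n, \qquad \alpha = G_0 / k,$$

rounded half-up to the nearest integer. $k$ is dimensionless and
gap-agnostic: it is the relative flowpeak deviation at which a correction
costs exactly a minimum gap, hence the largest relative deviation the aligner
will effectively entertain. $k = 0$ makes $\alpha$ infinite and reverts the
aligner to plain Smith-Waterman-Gotoh (`flow_align()` then returns results
identical to `swg_align()`, which the test suite asserts over a seeded
sweep). With a minimum gap penalty of 7 and $k = 0.25$, $\alpha = 28$; with
the default $G_0 = 5$, $\alpha = 20$, so the canonical worked examples come
out as: peak 2.60 down-called by one base costs
$\mathrm{round}(20 \cdot 0.10 / 3) = 1$, and peak 3.47 up-called by one base
costs $\mathrm{round}(20 \cdot 0.03 / 3) = 0$.

```{r}
m <- scoring_model()
c(down = correction_penalty(2.60, 3, 2, m),
  up   = correction_penalty(3.47, 3, 4, m))
```

### Penalty tables

`build_penalty_tables()` pre-computes, per query position $j$, the down-call
penalties $Pd_{j,n}$ and up-call penalties $Pu_{j,n}$ for correction sizes
$n = 1..4$ (corrections are capped at four bases). Entries are finite only
when

* $j$ is the last base of a homopolymer run (each positive flow is one run),
* the rounded penalty is *strictly* smaller than the cost
  $G_0 + (n-1) G_e$ of an ordinary gap of the same length — otherwise the
  correction machinery could never beat a plain gap and is pointless, and
* for down-calls, $n$ does not exceed the called run length (a run may be
  shortened all the way to zero bases).

Because $\mathrm{Dev}$ grows with the correction size, penalties are
non-decreasing in $n$; once an entry is infinite all larger sizes at that
position are forced infinite too. Negative flows call no base, so there is no
query position to attach a correction to: undercalls of true homopolymers
that were read as zero-length cannot be recovered. This is a model
limitation, not an implementation accident.

Two numerical choices here were genuinely open and are fixed as follows.
Rounding ties ($.5$) round half-up, applied consistently in the penalty
arithmetic and the tests. The sub-gap-cost gate compares the *rounded*
penalty against the gap cost; gating before rounding would admit entries that
round up to exactly the gap cost and tie with ordinary gaps.

## The alignment recursion

`swg_align()` is standard Gotoh: cell score
$D_{i,j} = \max(0,\, C_{i-1,j-1} + s(d_i, q_j),\, E_{i,j},\, H_{i,j})$ with
affine gap states $E$ (gap in the query string) and $H$ (gap in the
database string). `flow_align()` replaces each cell with

$$C_{i,j} = \max(D_{i,j},\, S_{i,j}),$$

where $S$ ranges over homopolymer corrections ending at $(i,j)$:

* **down-call** of size $n$: $C_{i,\,j-n} - Pd_{j,n}$ — the last $n$ bases of
  the query run ending at $j$ are placed against database gaps (rendered
  lower-case against `-`), with no gap cost;
* **up-call** of size $n$: $C_{i-n,\,j} - Pu_{j,n}$, valid only when all $n$
  consumed database bases $d_{i-n+1}..d_i$ equal $q_j$ — the run is
  lengthened by $n$ inserted copies of $q_j$ (rendered lower-case against the
  database bases).

The gap and diagonal recursions reference $C$, so corrections compose with
ordinary gaps and with each other. Corrected columns contribute **no**
substitution score: the correction penalty is the entire cost of the event.
The alternative — granting match score to up-called bases — cannot be ruled
out from first principles, but it would let a zero-penalty correction (e.g.
the 3.47 peak above) *increase* the score of an alignment unboundedly at
points of mere ambiguity; the no-score convention keeps zero-penalty
corrections score-neutral and is adopted throughout. Likewise, the up-call
identity condition is enforced for *all* $n$ consumed database bases, not
just the last one: inserted copies of $q_j$ that consume non-$q_j$ database
bases would be substitutions in disguise.

Traceback ties prefer diagonal, then up-call, then down-call, then database
gap, then query gap; among equal-scoring end cells the smallest $(i, j)$ is
used. These choices only pick among co-optimal alignments; they exist so that
every run is byte-reproducible.

```{r}
read <- call_flowgram(flowgram("r", "TAT", c(1.0, 2.40, 1.0)))  # "TAAT"
flow_align("TAAAT", read)
```

The classic illustration: `TAAT` whose A-peak of 2.40 nearly called three
A's aligns full-length to `TAAAT` through a one-base up-call costing 1
(score 7, beating the plain local score 6), but not to `TAACT`, where the
consumed database base `C` fails the identity condition.

## Search heuristic

`build_index()` is an SSAHA-style direct index: every ACGT-only window of
length $k_{tuple}$ (default 11) is base-4 encoded (alphabet order T, A, C, G)
into an occurrence list `L` with a $4^{k_{tuple}}+1$ pointer list `P`.
`find_hits()` looks up every query window; `select_candidates()` keeps
maximal runs of at least $n = 2$ hits on the same *exact* diagonal with
consecutive query offsets spaced strictly less than $J = 50$ apart. Indels
inside a candidate region are recovered by the DP, not by the heuristic, so
no diagonal band tolerance is applied.

`flow_search()` scores the query against each candidate database window
(clipped to the candidate diagonal $\pm$ (query length $+ J$); the tests
validate clipped against unclipped scores), ranks candidates, and re-aligns
the `top_v` (default 1) best with full traceback. The minus strand is
searched by reverse-complementing the *called read* — per-base flowpeak
values travel with their mapped bases and the penalty tables are rebuilt —
because flowpeaks describe the read's own homopolymers, which are preserved
under reverse complement. The heuristic is a pure filter: it decides which
pairs are aligned, never what an alignment scores, and results are
deterministic and independent of any parallel execution.

## The read simulator

The simulator generates the study conditions for the two evaluation designs:

* `generate_reference()` / `mutate_to_identity()`: uniform ACGT references
  and SNP mutants with an exact mismatch count
  $\mathrm{round}((1-\mathrm{identity}) \cdot L)$;
* `sequence_to_flowgram()`: ideal flowgrams over the TACG cycle;
* `add_flow_noise()`: the high-noise model — negative flows drawn from
  $\mathrm{LogNormal}(-2.5, 0.2)$ (natural-log parameterization), positive
  flows of true length $n$ from $\mathrm{Normal}(n, 0.15\,n)$ truncated at
  zero. A single `scale` knob multiplies both spreads; `scale = 1` is the
  high-noise regime, smaller values emulate cleaner chemistry. The
  instrument-specific parameter sets of production simulators are *not*
  reproduced — `scale` is an approximation knob, and negative normal draws
  are truncated rather than re-drawn (the choice is essentially
  inconsequential at these spreads: a draw at 0 is a negative flow either
  way).

What the simulator deliberately does not emulate: quality scores, flow-signal
droop/CAFIE artifacts (upstream of the data this tool consumes), adapter and
chimera contamination, and read-length distributions beyond a fixed length.
Passing tests on these simulations therefore demonstrate the algorithmic
claims — that flowpeak-priced corrections recover homopolymer miscalls — not
end-to-end accuracy on any particular instrument's output.

Noise truncation note: because $\sigma = 0.15\,n$ grows faster than the fixed
$\pm 0.5$ calling window, longer homopolymers miscall more often, which the
property tests assert by simulation.

## Evaluation designs

**Decoy recovery.** A target (25/50/100 bp) plus 100 decoys mutated to 92%
identity form a 101-sequence database; queries are mutated copies of the
target at identities from 1.00 down to 0.72, either with ideal flowpeaks
("plain") or with high-noise flowgrams ("noisy"). A replicate succeeds when
the target is the *unique* top score — ties with a decoy count as failures,
avoiding optimistic bias. Queries are scored exhaustively against all 101
sequences rather than through the seeding heuristic: with 25–50 bp queries at
down to 72% identity, 11-mer seeding mostly measures seed sensitivity, and
the question here is the alignment model. Both $k$ values score identical
query sets, so the $k = 0$ vs $k = 0.25$ comparison is paired. The default
of 500 replicates per cell keeps the full grid to minutes of CPU while
leaving binomial standard errors near 2 percentage points; survey-scale
precision (10,000 replicates) is one configuration value away.

On plain data the flow-assisted aligner can only lose: ideal peaks still
leave cheap corrections on longer homopolymers (an ideal 3-mer peak
down-calls for $\mathrm{round}(20 \cdot 0.5/3) = 3 < 5$), occasionally
rewarding a spurious re-call, so plain Smith-Waterman-Gotoh is expected to be
marginally better there — and the tests assert exactly that direction, within
binomial confidence.

**Read mapping.** Reads simulated with truth coordinates are aligned back to
their genome and every called base is scored: correct iff it is an
upper-case aligned base placed at exactly its true coordinate. Bases in gap
columns, corrected (lower-case) columns, overcalled bases with no true
coordinate, and unaligned bases count in the denominator only. Strict
coordinate equality is the conservative reading — a base placed at a shifted
but homologous position counts as wrong. The acceptance-scale run uses 1,000
reads of 300 bp from a 100 kb synthetic genome at identity 1.0 and noise
scale 0.5, sizes chosen so the whole suite runs in minutes on one CPU while
the two aligners still separate clearly.

## Known limitations

* Corrections attach to called homopolymers only; a homopolymer entirely
  missed by a negative flow cannot be up-called from nothing.
* Penalties derive from single flowpeaks; no cross-flow error model
  (carry-forward/incomplete extension) is represented.
* The FFASTA format carries no flow order of record; a `# flow_order=`
  comment line (default TACG) is this implementation's convention.
* The index holds the database in memory; no on-disk or compressed index is
  provided.
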