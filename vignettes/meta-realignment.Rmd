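---
title: "Profile-based meta-realignment: model, parameters and design notes"
author: "ProfileRealign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-based meta-realignment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProfileRealign)
```

## The procedure

ProfileRealign refines an existing nucleotide multiple sequence alignment
rather than building one. One outer iteration does five things:

1. strip void (all-gap) columns from the current alignment;
2. compute the alignment's percent average pairwise sequence identity
   (APSI) and derive scoring parameters from it (unless the user supplies
   their own);
3. summarize the alignment into a count-weighted profile: position $i$
   holds the counts $C_a(i)$ of each residue $a$ observed in column $i$
   (gaps contribute nothing);
4. realign **every** ungapped sequence, independently, globally against
   the profile with a three-state affine-gap (Gotoh) dynamic program; if
   any optimal alignment inserts residues the profile cannot host, enlarge
   the profile (fine-tuning mode) and redo the whole pass;
5. merge the per-sequence alignments — one output column per profile
   position — and strip void columns again.

Iteration stops when two successive alignments are identical (exact
row-wise string equality, same row order) or after `maxIterations`
(default 5) iterations. Because every sequence gets to move in every
iteration, blocks frozen by a progressive aligner's "once a gap, always a
gap" policy can be released, which single-sequence iterative refinement
only partially achieves.

Two hard guarantees hold for every run: the output degaps to exactly the
input sequences, in input order (the method only ever rearranges gaps),
and the output contains no void column.

## The scoring model and its assumptions

The cell score for aligning sequence residue $b$ against profile position
$i$ is additive in the observed counts,
$$SS(i,b) \;=\; \sum_{a \in \{A,C,G,T\}} C_a(i)\, \mathrm{Sub}'(a,b),$$
not an average of frequencies: a column of $k$ identical residues scores
$k$ times a singleton column, so deep conserved columns dominate the
optimization. This is deliberate — the profile is a summary of evidence,
and more evidence should pull harder. A consequence is that every
substitution score must be strictly positive and much larger in magnitude
than the gap penalties, otherwise sequences prefer opening gaps to
tolerating mismatches and the profile balloons with weakly supported
positions during fine-tuning.

The four gap penalties distinguish where the gap lands:

| parameter | meaning | sign |
|---|---|---|
| HGOP / HGEP | open / extend a gap **in the profile** (sequence residues inserted between positions) | $\le 0$ |
| VGOP / VGEP | open / extend a gap **in the sequence** (a profile position skipped) | $\le 0$ |

with $|{\rm open}| \ge |{\rm extend}|$ on both sides and
$|\mathrm{HGOP}| \ge |\mathrm{VGOP}|$: the profile already has a position
for every residue of every sequence, so skipping a low-scoring position
must stay cheap while growing the profile is the costliest move. Terminal
gaps are never penalized (TGOP = TGEP = 0), realized as zero-cost
initialization of the gap states along the DP boundary and unpenalized
exit along the final row/column.

Two runtime modulations refine the penalties:

* **Length scaling.** Before a sequence of length $N$ is aligned (longest
  sequence in the set $M$), all four penalties are multiplied by
  $1 + \ln(M/N)$. This is the identity at $N = M$, grows smoothly as
  sequences get shorter, and penalizes gaps harder for short sequences so
  they do not scatter cheap gaps across the profile.
* **Position-specific openings.** Opening a gap against (or immediately
  after) profile position $i$ costs
  $\mathrm{GOP} - \mathrm{PCR}_i \cdot SS(i,b)$, where
  $\mathrm{PCR}_i = \max_a C_a(i) / \sum_a C_a(i) \in (0,1]$ is the
  profile conservation rate. The modulation is linear in the conservation
  rate, applies to openings only (extensions stay flat), and makes
  well-supported columns resist gaps in proportion to both their
  conservation and the score the gap forgoes.

## Default parameters

The substitution matrix is HOXD70, made strictly positive by
$\mathrm{Sub}' = \mathrm{coeff}\cdot\mathrm{Sub} + \mathrm{bonus}$. A flat
bonus alone would compress the relative margin between matches and
mismatches; the multiplicative coefficient ($\ge 1$, identity at 1)
stretches the raw scores first so that the margin survives the lift.

The defaults are derived from the APSI $p \in [0,100]$ of the current
alignment by the package's calibration, linear in $p$:

| parameter | default | at $p = 60$ |
|---|---|---|
| bonus | $200 + 2p$ | 320 |
| coeff | $1 + p/100$ | 1.6 |
| HGOP | $-(300 + 2p)$ | $-420$ |
| HGEP | $-(50 + p/2)$ | $-80$ |
| VGOP | $-(150 + p)$ | $-210$ |
| VGEP | $-(25 + p/4)$ | $-40$ |

The rationale: (i) every constraint of the model (positive scores,
non-positive penalties, $|{\rm open}|\ge|{\rm extend}|$,
$|\mathrm{HGOP}|\ge|\mathrm{VGOP}|$, scores $\gg$ penalties) holds
identically over the whole APSI range — the test suite sweeps all integer
APSI values; (ii) penalties stiffen with identity, because the more
similar the sequences, the better determined the gap structure already is
and the less the reformer should perturb it, whereas low-identity
alignments need freedom to move blocks; (iii) the magnitudes sit between
the single-count and typical multi-count scale of the additive scores, so
the conservation-modulated term $\mathrm{PCR}_i \cdot SS(i,b)$ — which
scales with alignment depth automatically — carries the position-specific
discrimination. Users can bypass the calibration entirely with
`makeScoringParams()` (or the CLI penalty flags); overrides are validated
against the same constraint system before the run starts.

APSI itself is the mean over all unordered row pairs of percent identity,
counting identical-residue columns over columns where *both* rows hold a
residue; single- and dual-gap columns are excluded from the denominator
(the convention of the standard RNA benchmark statistic). A pair sharing
no co-ungapped column contributes zero and logs a warning. The parameters
are recomputed from the current alignment at **every** outer iteration:
each iteration treats its input as a fresh starting alignment, and APSI
can change as the alignment reforms (the worked example in the README
shows it rising from 43 to 58 as corruption is repaired).

## Fine-tuning, merging and determinism

Most sequence–profile alignments need at most as many columns as the
profile has positions, but an optimal alignment may insert residues
between positions (this includes terminal overhangs). Insertions are
collected over the **whole** pass and applied in one batch, sorted by
junction; insertions of several sequences at the same junction are merged
left-anchored, per offset, with the junction receiving
$\max(\text{insertion lengths})$ new positions. New positions start with
weight 1 from the inserting sequence only; existing positions are not
re-tallied mid-pass (minimal perturbation keeps the restarted pass close
to the previous one). Batching makes the result independent of sequence
processing order — the per-sequence alignments are logically concurrent —
and, with the fixed tie-breaking below, the whole pipeline is
deterministic: identical inputs give byte-identical outputs.

A safeguard caps fine-tuning at `maxFinetuneRounds` (default 20) profile
enlargements per pass. In a well-parameterized run a second round is
already rare: insertions are only chosen when anchored matches on both
sides outweigh a conservation-modulated opening, and the enlarged profile
hosts them on the restart. Exhausting the cap indicates penalties rivaling
the substitution scores (violating the model's constraint) and raises an
error naming the offending sequences, rather than returning traces that
were never verified against the final profile.

## Numerical and degenerate-case conventions

* The DP is exact, in double precision, over the full
  $(P{+}1)\times(N{+}1)$ grid — no banding or heuristics. The engine is
  compiled (Rcpp); the test suite checks it against an exhaustive
  enumeration of all monotone alignments on small instances.
* Traceback ties break with fixed priority MATCH > sequence-gap >
  profile-insertion, biasing against profile growth.
* The position-specific opening for a sequence-gap at profile position $i$
  uses $SS(i, b_j)$ of the adjacent cell; for an insertion between
  positions the **left-adjacent** profile position is used. Which neighbor
  modulates an insertion is a genuinely open choice; left-adjacency is
  symmetric with the sequence-gap case and keeps the recursion local.
* A gap step is "terminal" (free) exactly when it lies before the first or
  after the last consumed position of the other side, decided by the DP
  coordinates; the enumeration oracle applies the same definition
  independently.
* Input handling: `-` and `.` are gaps on input, `-` on output; `U` is
  stored as `T` and restored per record on output; ambiguity codes are
  rejected outright rather than guessed at. Profile positions and
  junctions are 0-based half-open internally, 1-based in messages.
* Empty metric denominators (a reference with no co-ungapped pair) score 1
  only when the test states no pairs either, else 0, with a message.

## What the synthetic generator does and does not emulate

`simulateFamily()` generates a star topology: one random ancestor,
independent leaves, i.i.d. substitutions (uniform over the three
alternative residues), deletions of single sites and insertions of
geometric length split evenly from one indel rate. The star keeps the true
alignment exact and simple: ancestor sites are shared columns; every
insertion is leaf-private and never asserted homologous with another
leaf's insertion. `corruptAlignment()` then displaces random maximal gap
runs within rows — precisely the kind of block misplacement frozen
subalignments produce — without touching the sequences, so truth-based
scoring stays valid.

What this does **not** emulate: tree-shaped relatedness (no correlated
substitutions between sister leaves), rate heterogeneity across sites,
transition/transversion bias (HKY/GTR), RNA secondary-structure
covariation, and the length/identity mixtures of curated benchmarks.
Passing the recovery experiment therefore shows the mechanism works —
displaced gap blocks are pulled back by profile realignment at moderate
identity — not that any particular published benchmark improvement is
reproduced. Real-data behaviour additionally depends on the starting
aligner's error profile.

The validation scales are chosen to exercise the model while staying
desk-sized: the enumeration oracle runs at sequence/profile lengths up to
5 (where exhaustive search is exact and cheap), the conservation and
invariant fuzz at 5–15 sequences of 50–200 nt, and the recovery
experiment at 8 sequences × 100 sites with substitution rate 0.28 and
indel rate 0.06 — which yields families near 55% APSI, the regime where
gap displacement genuinely hurts and reform has room to act.

## Known limitations

* Nucleotides only ({A,C,G,T,U}); no ambiguity codes, no proteins.
* The method needs a starting alignment; it never improves the underlying
  homology *statements* a profile cannot express (e.g. it cannot split a
  column into two if the profile inherited a wrong merge supported by most
  rows).
* The profile never shrinks during a pass; positions abandoned by all
  sequences disappear only via void-column removal between passes.
* Memory is $O(P \cdot N)$ per sequence–profile alignment; very long
  alignments (say $>10^5$ columns) would need a banded or linear-memory
  variant, which is out of scope.
* The default calibration is a design choice validated by its constraint
  system and the package's own experiments, not a re-fit of any published
  parameter search.
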