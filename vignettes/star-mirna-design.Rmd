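---
title: "Designing exclusive overexpression constructs for star-strand miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing exclusive overexpression constructs for star-strand miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starmiR)
```

## The design problem

A miRNA precursor hairpin releases a ~22-nt duplex whose two strands are
loaded into RISC with a strong bias: the abundant *miRNA* strand accumulates,
the *star* strand (miRNA\*) is mostly degraded. Cloning the genomic precursor
therefore overexpresses the dominant arm, which makes stable gain-of-function
experiments on the star strand difficult. The approach implemented here
sidesteps precursor biogenesis entirely by borrowing the shRNA architecture:
an artificial stem-loop is transcribed from a Pol III shRNA vector with

* the mature miRNA\* sequence (the **guide** — the strand the user wants
  expressed) as the 3′ arm,
* its full Watson–Crick complement (the engineered **passenger**) as the 5′
  arm, and
* a 9-nt loop (`UUCAAGAGA`, the classic shRNA loop) between them.

Unlike the natural precursor, the stem is perfectly paired, so Dicer releases
a defined duplex containing the exact mature star sequence.

## Why the passenger needs engineering

The passenger is itself a small RNA that can be loaded and act like a miRNA.
Two hazards follow, and the package screens for both:

**Seed collision with the natural counterpart.** Because the star strand and
its natural partner come from one duplex, the passenger (complement of the
star) can share seed-region sequence with the natural counterpart miRNA. If
the two are identical across the collision window the construct would mimic
the counterpart — exactly what exclusive star-strand expression must avoid.
`detect_seed_collision()` compares the passenger and the counterpart
position-by-position over sites 3–8 (1-based from each 5′ end). That window,
rather than the canonical 2–8 seed, is what the collision check in the
original design used; the 2–8 window remains the default only for the
off-target scanner, and both are arguments. The default collision policy is
all-positions-identical; a softer count threshold is exposed via
`collision_threshold` but off by default, since a 6/6 collision is the only
case with an experimental precedent.

**Off-target seed activity.** Independently of the counterpart, the
passenger's own seed (positions 2–8) may match sites in transcripts of
interest, or coincide with an existing miRNA's seed. `scan_seed_matches()`
counts reverse-complement seed sites (and full-length siRNA-like matches) in
user-supplied 3′UTRs against a brute-force-verifiable overlapping count, and
`check_seed_novelty()` compares the seed against a reference mature set. The
package reports counts and leaves the accept/reject judgment to the user —
there is no established burden threshold to encode.

## The mutation engine

When a collision is found, `propose_seed_mutations()` places (by default) two
substitutions inside the window. The policy is a reconstruction calibrated on
the one experimentally validated design, for which the published
substitutions are A→G at passenger position 5 and C→U at position 7:

1. **Wobble-preserving candidates first.** A passenger A opposite a guide U
   can become G (leaving a G:U wobble in the stem); a passenger C opposite a
   guide G can become U (U:G). These transitions break seed identity with the
   counterpart while barely perturbing the hairpin stem, which must still
   fold and be processed. Positions admitting such a substitution form tier
   one; remaining transitions (G→A, U→C) and finally transversions are
   fallback tiers for unusual sequence contexts.
2. **Scan from the 3′ end of the window, skipping adjacency.** Candidates are
   taken from the window's 3′ end toward the 5′ end, never adjacent to an
   already chosen position, spreading the disruption across the seed. On the
   validated design this selects position 7 (C→U), skips 6, then position 5
   (A→G) — reproducing the published pair exactly.
3. **Constraints.** Every substitution must differ from the counterpart base
   at that position (otherwise it would *create* identity), must not sit
   inside a run of ≥4 T on the encoded DNA top strand (a premature Pol III
   terminator — only substitutions *to* U can create one; pre-existing runs
   elsewhere in the guide are the vector designer's concern and are flagged
   at emission as a warning), and, when a reference seed set is supplied, the
   mutated window must not equal any reference seed. If no assignment
   satisfies the constraints the engine fails loudly, listing what it tried.

The engine is fully deterministic: identical inputs give identical mutation
lists.

```{r mutation-example}
fx <- paper_mirnas()
anti <- build_passenger(fx[["hsa-miR-146b-3p"]])
propose_seed_mutations(anti, fx[["hsa-miR-146b-5p"]])
```

## Strand-loading thermodynamics

RISC prefers the strand whose 5′ end is less tightly paired. The package
scores this with the Watson–Crick RNA nearest-neighbor ΔG°37 stack table
(Xia et al. 1998), summed over the terminal 4 base pairs at each 5′ end of
the guide/passenger duplex (`window_bp` is an argument; 4 bp is common
siRNA-design practice). Three numerical choices matter:

* **Mismatches contribute zero.** Stacks flanked by a non-Watson–Crick
  position (seed-mutation mismatches, G:U) add 0 kcal/mol. This is a
  conservative simplification — real mismatches and wobbles have their own,
  mostly destabilizing, parameters — and it makes the monotonicity guarantee
  exact: unpairing a window position can never make the window more stable.
* **Initiation and terminal-AU terms are omitted.** Only the *difference*
  between the two end windows is interpreted, so terms common to both ends
  would cancel; per-end terminal corrections are below the advisory
  resolution of the score.
* **Ambiguity band.** `asymmetry = guide_5p_dG − passenger_5p_dG`; values
  within ±0.5 kcal/mol are called ambiguous. Positive asymmetry (guide end
  less stable) predicts guide loading.

The prediction is advisory — the score warns rather than blocks, because no
quantitative loading threshold is established for this construct family.
`destabilize_passenger_3prime()` implements the corresponding enhancement:
substitutions in the passenger's 3′-terminal 4 positions (the bases paired
with the guide's 5′ end) that strictly increase the asymmetry, found by
exhaustive search over the 4 positions × 3 alternative bases, greedily one at
a time, ties broken by fixed base order. For the validated design the score
is −1.34 kcal/mol (passenger-favoring) before and +5.34 after a single such
substitution.

## Oligo emission and vector profiles

A vector profile is a set of verbatim flank strings. For every profile:

```
top    = top_prefix + core_prefix + core + core_suffix
bottom = bottom_prefix + revcomp(core_prefix + core + core_suffix) + bottom_suffix
```

with `top_prefix`/`bottom_prefix` the single-stranded 5′ overhangs after
annealing. Built-ins (in `inst/extdata/vector_profiles.yaml`): `plvx-shRNA2`
(BamHI/EcoRI; `GATC` / `CCC` … `TTTTTA` / `AATT`), `psicheck` (XhoI/NotI) and
`pmir-report` (MluI/SacI, whose bottom strand carries a 3′ `AGCT` extension).
Enzyme names are documentation; no recognition-site inference happens at run
time. The emitted bottom strand is always the exact reverse complement of the
double-stranded region (*strict mode*), and `verify_duplex()` re-checks every
pair position-by-position. One printed reference oligo for the validated
146b-3p construct is *not* the exact complement of its top strand (it repeats
the forward arm instead of complementing the mutated one); the package keeps
that string as a verbatim regression fixture and surfaces the four mismatches
through `verify_duplex()` rather than reproducing them.

## Sensor design

Sensor inserts place two identical tandem target sites behind a luciferase
3′UTR, with fixed spacers (`ACC`, linker `GGTCAACAATC`, terminal `GGC`) taken
verbatim from the validated inserts and treated as constants without claimed
function. Site kinds:

* **perfect** — DNA reverse complement of the mature miRNA
  (slicing-competent; psiCHECK backbone);
* **bulged** — non-complementary at the positions opposite miRNA 10–12, the
  slicing register, forcing miRNA-like repression (pMIR backbone);
* **seed_mutant** — the bulged site additionally broken opposite the miRNA
  seed; the specificity control.

The substitution rule is deterministic: each edited site base is replaced by
its own Watson–Crick complement, which necessarily cannot pair with the
opposing miRNA base. The seed-mutant edits sit opposite miRNA positions
{first, ⌈median⌉, last} of the 2–7 seed window — i.e. 2, 5, 7 — three spaced
substitutions rather than a full seed wipe. Both the substitution rule and
the position pattern were reverse-engineered from the validated 146b-3p
sensor pair, which they reproduce byte-for-byte; for other miRNAs they are a
documented reconstruction, not an experimentally validated recipe. The
seed-mutant site retains 4 of 7 complementary positions opposite miRNA 2–8
(versus 7 of 7 for its bulged parent), enough disruption to abolish
repression in the validated case.

## The synthetic-pair generator

`generate_fixtures()` supports the property tests: it draws random 22-nt
guides (uniform over ACGU), derives the passenger, and builds a counterpart
whose collision window shares an exact, requested number of identical
positions with the passenger (a random subset of the window is copied, the
rest forced to differ). It emulates only the combinatorics of seed overlap —
not miRNA-like base composition, arm co-evolution, or 3′-overhang structure —
so passing property tests demonstrate the engine's contract (collision always
eliminated, determinism, no introduced T-runs) over the sequence space, not
biological efficacy on real precursors. Problem sizes in the shipped tests
(500 generated collision pairs, 1000 random sequences for the involution
properties) keep the whole suite under half a minute while exercising every
fallback tier of the mutation policy.

## Degenerate inputs and limitations

Empty sequences are legal at the primitive level; mature miRNAs are
constrained to 18–26 nt (warning outside 20–24). Loops shorter than 4 nt are
rejected (a hairpin cannot close). Guide/passenger duplexes must be equal
length — true by construction here; the thermodynamic module does not model
the 2-nt 3′ overhangs of natural duplexes. The package predicts nothing
about Drosha/Dicer cleavage registers, does not fold the full precursor, and
its loading prediction is a two-window heuristic, not a hybridization model.
Expression level and repression efficacy are wet-lab outcomes outside what
any of these scores can promise.
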