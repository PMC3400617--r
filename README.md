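# starmiR

Design toolkit for **exclusive overexpression of star-strand microRNAs
(miRNA\*)** from Pol III shRNA vectors.

Every miRNA precursor yields two mature strands; RISC loading is biased, so
the star strand is usually scarce and cloning the genomic precursor cannot
overexpress it selectively. starmiR designs the alternative reagent: an
artificial shRNA-style stem-loop with the mature miRNA\* as the 3′ arm
(guide), its seed-engineered full complement as the 5′ arm (passenger), and a
9-nt loop (`UUCAAGAGA`) in between, i.e.

```
5'-[passenger = mutated revcomp(guide)]-[UUCAAGAGA]-[guide = miRNA*]-3'
```

Around that core the package provides:

* **Seed-collision screening** — position-wise identity between the
  passenger and the natural counterpart miRNA over sites 3–8; collisions are
  destroyed by a deterministic mutation engine that prefers wobble-preserving
  transitions (A→G opposite U, C→U opposite G), scanned from the window's 3′
  end, with a Pol III T-run guard.
* **Strand-loading prediction** — Watson–Crick RNA nearest-neighbor ΔG°37
  sums over the terminal 4 bp at each 5′ end of the duplex; the strand with
  the less stable 5′ end is predicted to load. An optional pass
  (`destabilize_passenger_3prime()`) mutates the passenger's 3′ end to bias
  loading toward the guide.
* **Off-target screening** — overlapping counts of passenger seed
  (positions 2–8) reverse-complement sites in supplied 3′UTRs, full-length
  siRNA-like matches, and seed-novelty checks against a reference mature set.
* **Oligo emission** — annealing-ready top/bottom DNA oligos with
  vector-specific flanks and sticky ends (built-in profiles: `plvx-shRNA2`
  BamHI/EcoRI, `psicheck` XhoI/NotI, `pmir-report` MluI/SacI), plus duplex
  verification and a TSV ordering sheet.
* **Luciferase sensor design** — two-site tandem inserts: perfect
  (slicing), centrally bulged (miRNA-like repression), and seed-mutant
  (negative control) target sites.

## Worked example

```r
library(starmiR)
fx  <- paper_mirnas()                       # built-in worked-example miRNAs
res <- design_star_construct(fx[["hsa-miR-146b-3p"]],   # guide (miRNA*)
                             fx[["hsa-miR-146b-5p"]])   # natural counterpart
print(res)
```

```
== star-strand overexpression design ==
<hairpin_design> hsa-miR-146b-3p (53 nt precursor)
  5' arm (passenger): CCAGGAUUGAGUCCACAGGGCA
  loop              : UUCAAGAGA
  3' arm (guide)    : UGCCCUGUGGACUCAGUUCUGG
  passenger mutations: 5:A>G, 7:C>U
  pre-mutation : <seed_collision> sites 3-8: 6/6 identical (AGAACU vs AGAACU) -> COLLISION
  post-mutation: <seed_collision> sites 3-8: 4/6 identical (AGGAUU vs AGAACU) -> no collision
<duplex_end_stability> 4-bp windows (Xia-Turner WC RNA NN dG37)
  guide 5' dG -8.79 | passenger 5' dG -7.45 | asymmetry -1.34 kcal/mol -> passenger
<oligo_pair> plvx-hs-146b-3p (plvx-shRNA2; BamHI/EcoRI)
  top    5'-GATCCCCCCAGGATTGAGTCCACAGGGCATTCAAGAGATGCCCTGTGGACTCAGTTCTGGTTTTTA-3' (66 nt)
  bottom 5'-AATTTAAAAACCAGAACTGAGTCCACAGGGCATCTCTTGAATGCCCTGTGGACTCAATCCTGGGGG-3' (66 nt)
  warning: predicted loaded strand is 'passenger' (asymmetry -1.34 kcal/mol); ...
```

Reading the output: the passenger's sites 3–8 (`AGAACU`) were identical to
the counterpart miRNA's — a 6/6 seed collision that would let the construct
mimic hsa-miR-146b-5p — so the engine substituted A→G at passenger position 5
and C→U at position 7, leaving 4/6 identity (no collision) while the hairpin
stem keeps G:U wobbles at the mutated positions. The top oligo is the
synthesis-ready insert: BamHI overhang `GATC`, `CCC` flank, the 53-nt
hairpin template, and the Pol III terminator `TTTTTA`. The end-stability
score warns that this particular duplex still favors passenger loading
(asymmetry −1.34 kcal/mol); `destabilize_passenger_3prime(res$design)` lifts
it to +5.34 with a single passenger 3′-end substitution.

Sensor constructs work the same way:

```r
design_sensor_construct(fx[["hsa-miR-146b-3p"]], kind = "bulged")   # pMIR backbone
```

A thin command-line front end over the same functions is installed at
`inst/scripts/star-mir-design.R`.

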