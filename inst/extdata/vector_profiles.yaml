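# Built-in vector profiles. Strings are verbatim flank/overhang constants for
# each backbone; enzymes are documentation only (no runtime site inference).
#
# Emission rule for every profile:
#   top    = top_prefix + core_prefix + core + core_suffix
#   bottom = bottom_prefix + reverse_complement(core_prefix + core + core_suffix)
#            + bottom_suffix
# where `core` is the hairpin (overexpression) or sensor body (sensor) DNA.
# top_prefix / bottom_prefix are the 5' single-stranded overhangs after
# annealing; bottom_suffix (pMIR-Report) is a bottom-strand 3' extension that
# leaves a top-strand recessed end.
schema_version: 1
profiles:
  plvx-shRNA2:
    kind: overexpression
    top_prefix: GATC
    core_prefix: CCC
    core_suffix: TTTTTA
    bottom_prefix: AATT
    bottom_suffix: ""
    enzymes: [BamHI, EcoRI]
  psicheck:
    kind: sensor
    top_prefix: TCGA
    core_prefix: C
    core_suffix: ""
    bottom_prefix: GGCC
    bottom_suffix: ""
    enzymes: [XhoI, NotI]
  pmir-report:
    kind: sensor
    top_prefix: ""
    core_prefix: C
    core_suffix: ""
    bottom_prefix: CGCG
    bottom_suffix: AGCT
    enzymes: [MluI, SacI]
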