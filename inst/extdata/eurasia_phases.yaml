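# Four-phase Eurasian haplogroup scenario for the two X-linked pattern loci
# (A = the Europe/Asia pattern locus, B = the south-Asia pattern locus).
initial:
  Eurasia: [A2B2]
phases:
  - name: phase1_ancestral
    events: []
  - name: phase2_divergence
    events:
      - {type: split, pop: Eurasia, daughters: [Europe, Asia], time: 1.0}
      - {type: fix, pop: Europe, haplotypes: [A1B1]}
      - {type: fix, pop: Asia, haplotypes: [A2B2]}
  - name: phase3_admixture_selection
    events:
      - {type: split, pop: Asia, daughters: [SouthAsia, NorthAsia], time: 0.6}
      - {type: admix, source: Europe, target: NorthAsia, recombination: true}
      - {type: select, pop: NorthAsia, locus: A, allele: A1}
  - name: phase4_tibet
    events:
      - {type: split, pop: NorthAsia, daughters: [NorthAsia, Tibet], time: 0.2}
      - {type: fix, pop: Tibet, haplotypes: [A1B2]}
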