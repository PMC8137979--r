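# Default gene-content haplotype catalog for European-descent cohorts.
# Content vectors (which loci, how many copies) are the identity of each
# haplotype; gene order is display only. Interiors not fixed by copy-number
# arithmetic (e.g. cB03, tB02) follow the published literature and are
# user-editable configuration.
haplotypes:
  - name: cA01
    region: centromeric
    genes: [KIR3DL3, KIR2DL23, KIR2DP1, KIR2DL1, KIR3DP1]
  - name: cA03
    # cA01 lacking KIR3DP1
    region: centromeric
    genes: [KIR3DL3, KIR2DL23, KIR2DP1, KIR2DL1]
  - name: cB01
    region: centromeric
    genes: [KIR3DL3, KIR2DS2, KIR2DL23, KIR2DL5B, KIR2DS3, KIR2DP1, KIR2DL1, KIR3DP1]
  - name: cB02
    region: centromeric
    genes: [KIR3DL3, KIR2DS2, KIR2DL23, KIR3DP1]
  - name: cB02.2DL2dup
    # cB02 carrying a duplicated KIR2DL2 (locus KIR2DL23)
    region: centromeric
    genes: [KIR3DL3, KIR2DS2, KIR2DL23, KIR2DL23, KIR3DP1]
  - name: cB03
    region: centromeric
    genes: [KIR3DL3, KIR2DS2, KIR2DL23, KIR2DP1, KIR2DL1, KIR3DP1]
  - name: cB04
    # cB01 minus KIR2DS3~KIR2DP1~KIR2DL1~KIR3DP1 (centromeric part of the
    # seven-locus deletion that couples with tB03)
    region: centromeric
    genes: [KIR3DL3, KIR2DS2, KIR2DL23, KIR2DL5B]
  - name: cB06
    # cB01 lacking KIR2DP1
    region: centromeric
    genes: [KIR3DL3, KIR2DS2, KIR2DL23, KIR2DL5B, KIR2DS3, KIR2DL1, KIR3DP1]
  - name: tA01
    region: telomeric
    genes: [KIR2DL4, KIR3DL1S1, KIR2DS4, KIR3DL2]
  - name: tA02
    # tA01 lacking KIR2DS4
    region: telomeric
    genes: [KIR2DL4, KIR3DL1S1, KIR3DL2]
  - name: tB01
    region: telomeric
    genes: [KIR2DL4, KIR3DL1S1, KIR2DL5A, KIR2DS5, KIR2DS1, KIR3DL2]
  - name: tB02
    # deletion haplotype lacking KIR2DL4~KIR3DL1S1, KIR2DL5A retained
    region: telomeric
    genes: [KIR2DL5A, KIR2DS5, KIR2DS1, KIR3DL2]
  - name: tB03
    # tB01 minus KIR2DL4~KIR3DL1S1~KIR2DL5A (telomeric part of the
    # seven-locus deletion; always in phase with cB04)
    region: telomeric
    genes: [KIR2DS5, KIR2DS1, KIR3DL2]
  - name: t3DL2
    # only the KIR3DL2 framework gene in the telomeric region
    region: telomeric
    genes: [KIR3DL2]
  - name: new1
    # insertion of KIR3DP1~KIR2DL4~KIR3DS1 into tA01
    region: telomeric
    genes: [KIR2DL4, KIR3DL1S1, KIR3DP1, KIR2DL4, KIR3DL1S1, KIR2DS4, KIR3DL2]
  - name: new2
    # insertion of KIR2DS3~KIR2DP1~KIR2DL1~KIR3DP1~KIR2DL4~KIR3DS1~KIR2DL5A
    # into tA01 (the block deleted from cB01~tB01 to give cB04~tB03)
    region: telomeric
    genes: [KIR2DL4, KIR3DL1S1, KIR2DS3, KIR2DP1, KIR2DL1, KIR3DP1, KIR2DL4, KIR3DL1S1, KIR2DL5A, KIR2DS4, KIR3DL2]
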