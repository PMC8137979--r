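# Default synthetic cohort: a European-descent study population of 2,130
# individuals. Full haplotypes are sampled as (centromeric, telomeric)
# pairs so gametic-phase couplings (cB04 always with tB03, cA03 always
# with tB02) are built in. Allele tables are conditional on the haplotype;
# probabilities on one line sum to 1. Alleles of KIR2DL1 and KIR3DL1S1 are
# the synthetic allele-database entries so observed site vectors can be
# emitted for them.
n_individuals: 2130
seed: 1
haplotype_pairs:
  - {cen: cA01, tel: tA01, frequency: 0.58}
  - {cen: cB02, tel: tA01, frequency: 0.12}
  - {cen: cB01, tel: tB01, frequency: 0.103}
  - {cen: cA01, tel: tB01, frequency: 0.08}
  - {cen: cB02, tel: tB01, frequency: 0.04}
  - {cen: cB01, tel: tA01, frequency: 0.04}
  - {cen: cB04, tel: tB03, frequency: 0.01}
  - {cen: cA01, tel: new1, frequency: 0.009}
  - {cen: cA03, tel: tB02, frequency: 0.006}
  - {cen: cA01, tel: new2, frequency: 0.0045}
  - {cen: cB06, tel: tA01, frequency: 0.003}
  - {cen: cA01, tel: tA02, frequency: 0.002}
  - {cen: cB02.2DL2dup, tel: tA01, frequency: 0.002}
  - {cen: cA01, tel: t3DL2, frequency: 0.0005}
deterministic_counts: {}
allele_tables:
  cA01:
    KIR3DL3: {"KIR3DL3*00901": 0.35, "KIR3DL3*00101": 0.65}
    KIR2DL23: {"KIR2DL3*00101": 0.65, "KIR2DL3*00201": 0.35}
    KIR2DP1: {"KIR2DP1*00201": 1.0}
    KIR2DL1: {"KIR2DL1*00302": 0.65, "KIR2DL1*00201": 0.35}
    KIR3DP1: {"KIR3DP1*00301": 1.0}
  cA03:
    KIR3DL3: {"KIR3DL3*00101": 1.0}
    KIR2DL23: {"KIR2DL3*00101": 1.0}
    KIR2DP1: {"KIR2DP1*00102": 1.0}
    KIR2DL1: {"KIR2DL1*00101": 1.0}
  cB01:
    KIR3DL3: {"KIR3DL3*00301": 0.6, "KIR3DL3*00402": 0.4}
    KIR2DS2: {"KIR2DS2*00101": 1.0}
    KIR2DL23: {"KIR2DL2*00101": 1.0}
    KIR2DL5B: {"KIR2DL5B*00201": 1.0}
    KIR2DS3: {"KIR2DS3*00103": 1.0}
    KIR2DP1: {"KIR2DP1*00201": 1.0}
    KIR2DL1: {"KIR2DL1*00401": 1.0}
    KIR3DP1: {"KIR3DP1*00301": 1.0}
  cB02:
    KIR3DL3: {"KIR3DL3*00402": 0.5, "KIR3DL3*00301": 0.5}
    KIR2DS2: {"KIR2DS2*00101": 1.0}
    KIR2DL23: {"KIR2DL2*00301": 1.0}
    KIR3DP1: {"KIR3DP1*00301": 1.0}
  cB02.2DL2dup:
    KIR3DL3: {"KIR3DL3*00402": 1.0}
    KIR2DS2: {"KIR2DS2*00101": 1.0}
    KIR2DL23: {"KIR2DL2*00301": 1.0}
    KIR3DP1: {"KIR3DP1*00301": 1.0}
  cB04:
    KIR3DL3: {"KIR3DL3*00301": 1.0}
    KIR2DS2: {"KIR2DS2*00101": 1.0}
    KIR2DL23: {"KIR2DL2*00101": 1.0}
    KIR2DL5B: {"KIR2DL5B*00801": 1.0}
  cB06:
    KIR3DL3: {"KIR3DL3*00301": 1.0}
    KIR2DS2: {"KIR2DS2*00101": 1.0}
    KIR2DL23: {"KIR2DL2*00101": 1.0}
    KIR2DL5B: {"KIR2DL5B*00201": 1.0}
    KIR2DS3: {"KIR2DS3*00103": 1.0}
    KIR2DL1: {"KIR2DL1*00401": 1.0}
    KIR3DP1: {"KIR3DP1*00301": 1.0}
  tA01:
    KIR2DL4: {"KIR2DL4*00101": 0.5, "KIR2DL4*00801": 0.3, "KIR2DL4*00602": 0.2}
    KIR3DL1S1: {"KIR3DL1*00101": 0.4, "KIR3DL1*00501": 0.3, "KIR3DL1*00401": 0.2, "KIR3DL1*008": 0.1}
    KIR2DS4: {"KIR2DS4*00101": 0.8, "KIR2DS4*00301": 0.2}
    KIR3DL2: {"KIR3DL2*00103": 0.3, "KIR3DL2*00201": 0.3, "KIR3DL2*00501": 0.2, "KIR3DL2*00101": 0.2}
  tA02:
    KIR2DL4: {"KIR2DL4*00101": 1.0}
    KIR3DL1S1: {"KIR3DL1*00401": 1.0}
    KIR3DL2: {"KIR3DL2*00901": 1.0}
  tB01:
    KIR2DL4: {"KIR2DL4*00501": 0.994, "KIR2DL4*00103": 0.006}
    KIR3DL1S1: {"KIR3DS1*01301": 1.0}
    KIR2DL5A: {"KIR2DL5A*00101": 1.0}
    KIR2DS5: {"KIR2DS5*00201": 1.0}
    KIR2DS1: {"KIR2DS1*00201": 1.0}
    KIR3DL2: {"KIR3DL2*00701": 0.7, "KIR3DL2*018": 0.3}
  tB02:
    KIR2DL5A: {"KIR2DL5A*00501": 1.0}
    KIR2DS5: {"KIR2DS5*00202": 1.0}
    KIR2DS1: {"KIR2DS1*00201": 1.0}
    KIR3DL2: {"KIR3DL2*00301": 1.0}
  tB03:
    KIR2DS5: {"KIR2DS5*00201": 1.0}
    KIR2DS1: {"KIR2DS1*00201": 1.0}
    KIR3DL2: {"KIR3DL2*034": 0.2, "KIR3DL2*00801": 0.8}
  t3DL2:
    KIR3DL2: {"KIR3DL2*00902": 1.0}
  new1:
    KIR3DP1: {"KIR3DP1*00302": 1.0}
    KIR2DL4:
      - {"KIR2DL4*00101": 1.0}
      - {"KIR2DL4*01001": 1.0}
    KIR3DL1S1:
      - {"KIR3DL1*00101": 1.0}
      - {"KIR3DS1*01301": 1.0}
    KIR2DS4: {"KIR2DS4*00101": 1.0}
    KIR3DL2: {"KIR3DL2*00101": 1.0}
  new2:
    KIR2DS3: {"KIR2DS3*00103": 1.0}
    KIR2DP1: {"KIR2DP1*00201": 1.0}
    KIR2DL1: {"KIR2DL1*00401": 1.0}
    KIR3DP1: {"KIR3DP1*00301": 1.0}
    KIR2DL4:
      - {"KIR2DL4*00101": 1.0}
      - {"KIR2DL4*00501": 1.0}
    KIR3DL1S1:
      - {"KIR3DL1*00101": 1.0}
      - {"KIR3DS1*01301": 1.0}
    KIR2DL5A: {"KIR2DL5A*00501": 1.0}
    KIR2DS4: {"KIR2DS4*00101": 1.0}
    KIR3DL2: {"KIR3DL2*00101": 1.0}
novel_injection:
  - gene: KIR3DL1S1
    kind: recombinant
    base_allele: "KIR3DL1*00101"
    edits: {88: "T", 374: "A"}
    count: 142
  - gene: KIR3DL1S1
    kind: snv
    base_allele: "KIR3DL1*00101"
    edits: {800: "A"}
    count: 12
  - gene: KIR2DL1
    kind: snv
    base_allele: "KIR2DL1*00101"
    edits: {515: "G"}
    count: 8
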