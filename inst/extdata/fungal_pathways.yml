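# Fungal pathway catalog: nitrogen and sulfur metabolic potentials of
# sediment fungi, scored by the same engine as the prokaryote catalog
# (no fungal-specific code path).
- name: assim_nitrate_reduction
  category: "anaerobic:assim_nitrate_reduction"
  key_genes: [NR, NasAB, NIT-6]
  min_markers_present: 1
- name: dissim_nitrate_reduction
  category: "anaerobic:dissim_nitrate_reduction"
  key_genes: [NarGHI, NapAB, NirBD]
  min_markers_present: 1
- name: denitrification
  category: "anaerobic:denitrification"
  key_genes: [NirK, NorBC]
  min_markers_present: 1
- name: sulfate_reduction
  category: "anaerobic:sulfate_reduction"
  key_genes: [Sat, CysC, CysH, CysJ]
  min_markers_present: 1
- name: sulfide_oxidation
  category: "chemolithotrophy:sulfide_oxidation"
  key_genes: [DsrA, DsrB, soxC, SQOR]
  min_markers_present: 1
- name: organic_sulfur_assimilation
  category: "chemolithotrophy:organic_sulfur"
  key_genes: [tauD, ssuD]
  min_markers_present: 1
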