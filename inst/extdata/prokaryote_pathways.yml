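# Default prokaryote pathway/trait catalog.
#
# Each entry names a pathway, its category (grouped as
# <group>[:<subtype>]), its key marker genes, and how many of those
# markers must be detected before the pathway counts as present
# (min_markers_present, default 1).
#
# Marker labels for carbohydrate degradation are CAZyme class codes (GH,
# PL, CE, GT, AA, CBM); these match any annotated family with that prefix
# (e.g. GH5 matches GH). The marker sets for hydrocarbon and aromatic
# degradation, 3-HP, 3-HP/4-HB, methanogenesis, and H2 oxidation are
# editable defaults drawn from common usage; all other sets follow the
# marker genes this package's trait rules are anchored to.
#
# Note on sulfate reduction: the assimilatory entry lists sat/aprAB/dsrAB
# and the dissimilatory entry lists aprA/aprB, following the source
# labelling verbatim even though apr/dsr markers are conventionally
# dissimilatory; edit here if you prefer the conventional assignment.
#
# Name collision: "cox"-type labels are disambiguated by using coxA (et
# al.) for cytochrome c oxidase (aerobic respiration) and coxL for carbon
# monoxide dehydrogenase (CODH) in chemolithotrophic CO oxidation.
- name: carbohydrate_degradation
  category: carbohydrate_degradation
  key_genes: [GH, PL, CE, GT, AA, CBM]
  min_markers_present: 1
- name: hydrocarbon_degradation
  category: hydrocarbon_degradation
  key_genes: [alkB, ladA, almA, cyp153]
  min_markers_present: 1
- name: aromatic_degradation
  category: aromatic_degradation
  key_genes: [benA, catA, pcaG, boxB]
  min_markers_present: 1
- name: CBB
  category: "co2_fixation:CBB"
  key_genes: [rbcS, prkB]
  min_markers_present: 2
- name: rTCA
  category: "co2_fixation:rTCA"
  key_genes: [aclA, aclB]
  min_markers_present: 1
- name: WL
  category: "co2_fixation:WL"
  key_genes: [cdhD, acsB, cooS, cooF, acsE]
  min_markers_present: 1
- name: 3-HP
  category: "co2_fixation:3-HP"
  key_genes: [mcr, pcs]
  min_markers_present: 1
- name: 3-HP/4-HB
  category: "co2_fixation:3-HP/4-HB"
  key_genes: [ech_hcd]
  min_markers_present: 1
- name: methanogenesis
  category: "co2_fixation:methanogenesis"
  key_genes: [mcrA, comA, comB]
  min_markers_present: 1
- name: aerobic_respiration
  category: aerobic_respiration
  key_genes: [coxA, cydA, qoxA, ccoN, cyoA]
  min_markers_present: 1
- name: DNRA
  category: "anaerobic:DNRA"
  key_genes: [nirB, nirD]
  min_markers_present: 1
- name: denitrification
  category: "anaerobic:denitrification"
  key_genes: [nirK, norC]
  min_markers_present: 1
- name: assim_sulfate_reduction
  category: "anaerobic:assim_sulfate_reduction"
  key_genes: [sat, aprA, aprB, dsrA, dsrB]
  min_markers_present: 1
- name: dissim_sulfate_reduction
  category: "anaerobic:dissim_sulfate_reduction"
  key_genes: [aprA, aprB]
  min_markers_present: 1
- name: nitrification
  category: "chemolithotrophy:nitrification"
  key_genes: [amoA, amoB, amoC, hao, nxrA]
  min_markers_present: 1
- name: CO_oxidation
  category: "chemolithotrophy:CO_oxidation"
  key_genes: [coxL]
  min_markers_present: 1
- name: sulfide_oxidation
  category: "chemolithotrophy:sulfide_oxidation"
  key_genes: [sqr, fccB]
  min_markers_present: 1
- name: H2_oxidation
  category: "chemolithotrophy:H2_oxidation"
  key_genes: [hyaB, hybC]
  min_markers_present: 1
- name: iron_oxidation
  category: "chemolithotrophy:iron_oxidation"
  key_genes: [cyc2]
  min_markers_present: 1
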