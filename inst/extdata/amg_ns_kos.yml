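# Nitrogen/sulfur ortholog catalog for AMG flagging on viral ORFs.
# Deliberately minimal: only the two orthologs explicitly implicated in
# host nitrogen/sulfur modulation are shipped (nitrite reductase NirK and
# ATP sulphurylase CysN/NodQ), each under both its KEGG-style id and its
# gene symbol. Extend with a full supplementary KO list as a drop-in.
K00368: nitrogen   # nirK, copper-containing nitrite reductase
nirK: nitrogen
K00956: sulfur     # cysN/nodQ, sulfate adenylyltransferase subunit 1
cysN: sulfur
nodQ: sulfur
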