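gene_id,chrom,start,end,cellular_components
PLCXD1,1,129705000,129742000,cytoplasm;cytosol
GTPBP6,1,129768000,129791000,cytoplasm
PPP2R3B,1,129810000,129846000,nucleus;cytoplasm
CD99,1,129864000,129876000,plasma membrane;integral component of membrane;cell surface
ARSD,1,129921000,129958000,integral component of membrane;lysosome;endoplasmic reticulum
ARSE,1,129987000,130021000,integral component of membrane;endoplasmic reticulum
ASMTL,1,130220000,130261000,cytoplasm;nucleus
P2RY8,1,130455000,130478000,plasma membrane;integral component of membrane
SLC25A6,1,130702000,130724000,integral component of membrane;mitochondrial inner membrane
DHRSX,1,130980000,131034000,cytoplasm
ZBED1,1,131260000,131291000,nucleus
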