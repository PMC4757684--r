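# Synthetic MetaCyc-style organism records (hand-written test fixture).
UNIQUE-ID - ORG-PPUT
COMMON-NAME - Pseudomonas putida
LINEAGE - domain:Bacteria;phylum:Proteobacteria;genus:Pseudomonas;species:Pseudomonas putida
//
UNIQUE-ID - ORG-FLAV
COMMON-NAME - Flavobacterium
LINEAGE - domain:Bacteria;phylum:Bacteroidetes;genus:Flavobacterium
//
UNIQUE-ID - ORG-NITR
COMMON-NAME - Nitrospira
LINEAGE - domain:Bacteria;phylum:Nitrospirae;genus:Nitrospira
//
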