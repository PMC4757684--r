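lineage	copies
domain:Bacteria;phylum:Proteobacteria;class:Gammaproteobacteria;order:Pseudomonadales;family:Pseudomonadaceae;genus:Pseudomonas	4.5
domain:Bacteria;phylum:Proteobacteria;class:Gammaproteobacteria;order:Pseudomonadales;family:Moraxellaceae;genus:Acinetobacter	6
domain:Bacteria;phylum:Bacteroidetes	2.5
domain:Bacteria;phylum:Firmicutes;class:Bacilli;order:Lactobacillales;family:Streptococcaceae	6
domain:Bacteria;phylum:Nitrospirae	1
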