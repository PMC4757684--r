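sample_id	plant	compartment	date	replicate	cfu_per_ml	lineage	count
C_AS_oct_r1	WWTP-C	AS	2013-10-15	1	11500000	domain:Bacteria;phylum:Proteobacteria;class:Gammaproteobacteria;order:Pseudomonadales;family:Pseudomonadaceae;genus:Pseudomonas	420
C_AS_oct_r1	WWTP-C	AS	2013-10-15	1	11500000	domain:Bacteria;phylum:Proteobacteria;class:Gammaproteobacteria;order:Pseudomonadales;family:Moraxellaceae;genus:Acinetobacter	310
C_AS_oct_r1	WWTP-C	AS	2013-10-15	1	11500000	domain:Bacteria;phylum:Bacteroidetes;class:Flavobacteriia;order:Flavobacteriales;family:Flavobacteriaceae;genus:Flavobacterium	150
C_AS_oct_r1	WWTP-C	AS	2013-10-15	1	11500000	domain:Bacteria;phylum:Nitrospirae;class:Nitrospira;order:Nitrospirales;family:Nitrospiraceae;genus:Nitrospira	90
C_AS_oct_r1	WWTP-C	AS	2013-10-15	1	11500000	domain:Bacteria;phylum:Bacteroidetes;class:Saprospiria;order:Saprospirales;family:Saprospiraceae	55
C_AS_oct_r2	WWTP-C	AS	2013-10-15	2	11900000	domain:Bacteria;phylum:Proteobacteria;class:Gammaproteobacteria;order:Pseudomonadales;family:Pseudomonadaceae;genus:Pseudomonas	405
C_AS_oct_r2	WWTP-C	AS	2013-10-15	2	11900000	domain:Bacteria;phylum:Proteobacteria;class:Gammaproteobacteria;order:Pseudomonadales;family:Moraxellaceae;genus:Acinetobacter	330
C_AS_oct_r2	WWTP-C	AS	2013-10-15	2	11900000	domain:Bacteria;phylum:Bacteroidetes;class:Flavobacteriia;order:Flavobacteriales;family:Flavobacteriaceae;genus:Flavobacterium	140
C_AS_oct_r2	WWTP-C	AS	2013-10-15	2	11900000	domain:Bacteria;phylum:Nitrospirae;class:Nitrospira;order:Nitrospirales;family:Nitrospiraceae;genus:Nitrospira	98
C_AS_oct_r2	WWTP-C	AS	2013-10-15	2	11900000	domain:Bacteria;phylum:Bacteroidetes;class:Saprospiria;order:Saprospirales;family:Saprospiraceae	48
C_IW_oct_r1	WWTP-C	IW	2013-10-15	1	1180000	domain:Bacteria;phylum:Proteobacteria;class:Gammaproteobacteria;order:Pseudomonadales;family:Moraxellaceae;genus:Acinetobacter	620
C_IW_oct_r1	WWTP-C	IW	2013-10-15	1	1180000	domain:Bacteria;phylum:Firmicutes;class:Bacilli;order:Lactobacillales;family:Streptococcaceae;genus:Streptococcus	240
C_IW_oct_r1	WWTP-C	IW	2013-10-15	1	1180000	domain:Bacteria;phylum:Bacteroidetes;class:Flavobacteriia;order:Flavobacteriales;family:Flavobacteriaceae;genus:Flavobacterium	85
C_IW_oct_r1	WWTP-C	IW	2013-10-15	1	1180000	domain:Bacteria;phylum:Verrucomicrobia;class:Verrucomicrobiae;order:Verrucomicrobiales;family:Verrucomicrobiaceae;genus:Akkermansia	60
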