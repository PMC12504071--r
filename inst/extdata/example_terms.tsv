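gene_id	term_id	term_name
gene03	GO:0001	synthetic term near CNVs
gene04	GO:0001	synthetic term near CNVs
gene08	GO:0001	synthetic term near CNVs
gene09	GO:0001	synthetic term near CNVs
gene01	GO:0002	all genes
gene02	GO:0002	all genes
gene03	GO:0002	all genes
gene04	GO:0002	all genes
gene05	GO:0002	all genes
gene06	GO:0002	all genes
gene07	GO:0002	all genes
gene08	GO:0002	all genes
gene09	GO:0002	all genes
gene10	GO:0002	all genes
gene11	GO:0002	all genes
gene12	GO:0002	all genes
gene09	GO:0003	random five
gene04	GO:0003	random five
gene07	GO:0003	random five
gene01	GO:0003	random five
gene02	GO:0003	random five
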