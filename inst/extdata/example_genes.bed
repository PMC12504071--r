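chr1	0	8000	gene01	0	+
chr1	10000	18000	gene02	0	+
chr1	20000	28000	gene03	0	+
chr1	30000	38000	gene04	0	+
chr1	40000	48000	gene05	0	+
chr1	50000	58000	gene06	0	+
chr1	60000	68000	gene07	0	+
chr1	70000	78000	gene08	0	+
chr1	80000	88000	gene09	0	+
chr1	90000	98000	gene10	0	+
chr1	100000	108000	gene11	0	+
chr1	110000	118000	gene12	0	+
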