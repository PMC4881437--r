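chrom	arm	start	end
chr1	p	0	125000000
chr1	q	125000000	249250000
chr7	p	0	59100000
chr7	q	59100000	159140000
chr8	p	0	45600000
chr8	q	45600000	146360000
chr13	q	17900000	115170000
chr14	q	17600000	107350000
chr17	p	0	24000000
chr17	q	24000000	81200000
chr18	p	0	17200000
chr18	q	17200000	78080000
chr20	p	0	27500000
chr20	q	27500000	63030000
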