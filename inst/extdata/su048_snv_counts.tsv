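id	sample	variant_reads	total_reads	copy_number	zygosity
TET2-E1357stop	S1	7,436	19,553	2	heterozygous
SMC1A	S1	182,974	660,069	2	heterozygous
ACSM1	S1	17,149	127,236	2	heterozygous
OLFM2	S1	13,828	122,523	2	heterozygous
TET2-D1384V	S1	1,833	17,687	2	heterozygous
ZMYM3	S1	18,536	307,346	2	heterozygous
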