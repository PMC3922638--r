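id	sample	variant_reads	total_reads	copy_number	zygosity
CACNA1H	S1	12,085	24,860	2	heterozygous
TET2-T1884A	S1	4,220	8,772	2	heterozygous
TET2-Y1649stop	S1	7,792	16,211	2	heterozygous
CXorf66	S1	3,684	8,150	2	heterozygous
CXorf36	S1	3,523	8,060	2	heterozygous
DOCK9	S1	3,391	8,676	2	heterozygous
NCRNA00200	S1	9,201	25,413	2	heterozygous
CTCF	S1	10,558	30,119	2	heterozygous
GABARAPL1	S1	1,648	4,992	2	heterozygous
SCN4B	S1	5,113	16,386	2	heterozygous
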