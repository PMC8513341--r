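library	raw_reads	adaptor_and_length_removed	junk_reads	clean_reads
HO40_1	17087566	1824397	160613	15102556
HO40_2	15381430	1191349	131834	14058247
HO54_1	15504184	1464666	147468	13892050
HO54_2	18792450	2046587	134962	16610901
HO68_1	12770282	1373111	82560	11314611
HO68_2	13660269	4816480	30860	8812929
HO81_1	13489436	2151260	62326	11275850
HO81_2	10989687	2342466	74391	8572830
LO40_1	14051494	2970987	122646	10957861
LO40_2	13797449	4423308	93188	9280953
LO54_1	14790646	3030592	54704	11705350
LO54_2	14346000	2721911	108500	11515589
LO68_1	13911458	1846479	82175	11982804
LO68_2	16195799	1553201	79763	14562835
LO81_1	17910804	2992808	74723	14843273
LO81_2	15646123	5115030	61672	10469421
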