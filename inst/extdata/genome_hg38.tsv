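chromosome	length	p_end
chr1	248956422	122026459
chr2	242193529	92188145
chr3	198295559	90772458
chr4	190214555	49712061
chr5	181538259	46485900
chr6	170805979	58553888
chr7	159345973	58169653
chr8	145138636	44033744
chr9	138394717	43389635
chr10	133797422	39686682
chr11	135086622	51078348
chr12	133275309	34769407
chr13	114364328	16000000
chr14	107043718	16000000
chr15	101991189	17000000
chr16	90338345	36311158
chr17	83257441	22813679
chr18	80373285	15460899
chr19	58617616	24498980
chr20	64444167	26436232
chr21	46709983	10864560
chr22	50818468	12954788
chrX	156040895	58605579
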