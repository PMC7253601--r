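organism	gene	sequence	binding
Lactococcus lactis	ytjD1	AAATAGTTTACAAGTGTAAATTTATTT	Yes
Lactococcus lactis	ydiD	AAAATGTTTACATGTGTAAATTTTCAC	Yes
Lactococcus lactis	copR	TTAGTGTTTACACGTGTAAACTTATCT	Yes
Lactococcus lactis	copB	TGATAGTTTACAATTGTAAACTATATA	Yes
Lactococcus lactis	yahC	TTTTCGTTTACAATTGTAAACATAGAA	Yes
Lactococcus lactis	lctO	CTATCATCTACAGATGTAAACTTTATA	Yes
Lactococcus lactis	ytjD2	GATAAGATTACATATGTAAACAATAAA	Yes
Lactococcus lactis	yfhF	TAAGTATATACATCTGTAAAACTGAAA	No
Lactococcus lactis	yxdE	TTTGCTATTACACTTGTATCACATAAA	No
Streptococcus pneumoniae	Sp_0090_1	TGATTTAGGACATTTGTTTGATAGTGG	No
Streptococcus pneumoniae	Sp_0090_2	GAGTATACTAATAATGTAATCGTTATC	No
Streptococcus pneumoniae	Sp_0045	GGTGAACTAACAGATGTTTACGAAATT	No
Streptococcus pneumoniae	Sp_0530	ATTTGAGGAACAAATGTACGTTTATAA	No
Streptococcus pneumoniae	Sp_1433	GTAATTATAACAGATGTATAATAGAAA	No
Streptococcus pneumoniae	Sp_1863	ATGAATAAAACAATTGTAACACTCATC	No
Streptococcus pneumoniae	Sp_2073	AAGGCGGAAACATGTGTCAATGACTTG	No
Streptococcus pneumoniae	CopY_proximal	GTGTAATTGACAAATGTAGATTTTGGA	Yes
Streptococcus pneumoniae	CopY_distal	CTATAATTGACAAATGTAGATTTTAAG	Yes
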