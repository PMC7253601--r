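>ytjD1
AAATAGTTTACAAGTGTAAATTTATTT
>ydiD
AAAATGTTTACATGTGTAAATTTTCAC
>copR
TTAGTGTTTACACGTGTAAACTTATCT
>copB
TGATAGTTTACAATTGTAAACTATATA
>yahC
TTTTCGTTTACAATTGTAAACATAGAA
>lctO
CTATCATCTACAGATGTAAACTTTATA
>ytjD2
GATAAGATTACATATGTAAACAATAAA
>yfhF
TAAGTATATACATCTGTAAAACTGAAA
>yxdE
TTTGCTATTACACTTGTATCACATAAA
>Sp_0090_1
TGATTTAGGACATTTGTTTGATAGTGG
>Sp_0090_2
GAGTATACTAATAATGTAATCGTTATC
>Sp_0045
GGTGAACTAACAGATGTTTACGAAATT
>Sp_0530
ATTTGAGGAACAAATGTACGTTTATAA
>Sp_1433
GTAATTATAACAGATGTATAATAGAAA
>Sp_1863
ATGAATAAAACAATTGTAACACTCATC
>Sp_2073
AAGGCGGAAACATGTGTCAATGACTTG
>CopY_proximal
GTGTAATTGACAAATGTAGATTTTGGA
>CopY_distal
CTATAATTGACAAATGTAGATTTTAAG
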