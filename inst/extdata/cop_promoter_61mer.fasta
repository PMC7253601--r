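>cop_promoter_61mer
TAATTGACAAATGTAGATTTTAAGAGTATACTGATGAGTGTAATTGACAAATGTAGATTTT
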