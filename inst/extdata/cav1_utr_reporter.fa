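>hsa-CAV1-3UTR-WT CAV1 3'UTR luciferase-reporter fragment, wild type (sense strand)
TCGAGGACACTTTAATTACCAACCTGTTACCTACTTTGACTTTTTGCATTTAAAACAGACACTGGCATGG
ATATAGTTTTACTTTTAAACTGTGTACGC
>hsa-CAV1-3UTR-MUT CAV1 3'UTR luciferase-reporter fragment, seed site mutated (sense strand)
TCGAGGACACTTTAATTACCAACCTGTTACCTACTTTGACTTTTTGCATTTAAAACAGAGAGTCGCATGG
ATATAGTTTTACTTTTAAACTGTGTACGC
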