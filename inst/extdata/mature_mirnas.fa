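>hsa-miR-199a-5p mature sequence, miRBase
CCCAGUGUUCAGACUACCUGUUC
>hsa-miR-21-5p mature sequence, miRBase
UAGCUUAUCAGACUGAUGUUGA
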