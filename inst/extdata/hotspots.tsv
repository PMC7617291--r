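gene	protein_pos
CTNNB1	41
CTNNB1	45
PIK3CA	545
PIK3CA	1047
MYCN	44
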