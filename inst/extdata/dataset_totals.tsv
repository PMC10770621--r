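# Declared total nucleus counts of the three public cardiac snRNA-seq
# datasets; the consolidated analysis covers their sum (849,646 nuclei).
dataset	declared_total
SCP1303	592689
SCP1852	157273
SCP1849	99684
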