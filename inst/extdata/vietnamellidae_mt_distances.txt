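# 6 taxa, model p, lower triangle
# Published pairwise distances of the six complete Vietnamellidae
# mitochondrial genomes (proportion scale, 3 decimals as printed).
HM067837
MT-2014	0.202
JZ-2021	0.187	0.210
CN	0.058	0.209	0.183
TL	0.058	0.209	0.183	0.001
QY	0.140	0.211	0.190	0.148	0.149
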