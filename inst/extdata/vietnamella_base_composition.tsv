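record	A	T	G	C
CN/TL	32.3	38.2	11.7	17.8
QY	31.9	37.6	12.1	18.4
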