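kingdom	zn0	zn2
Archaea	5	28
Bacteria	3907	3395
Eukaryota	1041	1994
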