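W-box	TTGACY
GCC-box	GCCGCC
as-1	TGACG
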