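gene	detected	in_db	in_panel	novel
GRM7	2953	1923	374	655
PCLO	954	659	29	266
SLC6A4	119	76	3	40
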