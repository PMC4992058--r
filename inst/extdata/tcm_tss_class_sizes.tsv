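class	n_tss
full_bivalent	5539
A_partial	6210
B_partial	2186
pseudo	882
A_only	29608
B_only	13238
unmodified	14814
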