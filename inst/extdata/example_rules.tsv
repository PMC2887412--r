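target	rule
TF1	not (EX_S > 0)
G3	TF1
G5	TF1
G1A	not TF1
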