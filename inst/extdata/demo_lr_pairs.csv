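pair_id,ligand,receptor
LR01,G0101,G0501
LR02,G0142,G0688
LR03,G0233,G0755
LR04,G0319,G0821
LR05,G0404,G0913
LR06,G0477,G1040
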