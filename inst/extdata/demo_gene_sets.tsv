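set	gene
cycle_S	G0120
cycle_S	G0255
cycle_S	G0390
cycle_S	G0525
cycle_S	G0660
cycle_G2M	G0795
cycle_G2M	G0930
cycle_G2M	G1065
cycle_G2M	G1200
cycle_G2M	G1335
checkpoint	G1470
checkpoint	G1605
checkpoint	G1740
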