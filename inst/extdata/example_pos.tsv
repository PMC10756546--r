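feature_id	rt_min	mz	area
PC_38_6_p	5.001	806.5694	250000
PE_34_1_p	6.012	718.5381	80000
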