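feature_id	fragment_mz	intensity
PC_38_6_p	184.0733	1000
PE_34_1_p	577.5190	800
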