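responders	synthetic set with planted association	GENE01	GENE02	GENE03
bystanders	synthetic null set	GENE04	GENE05	GENE06	GENE07	GENE08
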