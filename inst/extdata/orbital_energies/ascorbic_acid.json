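{"molecule": "Ascorbic acid", "E_HOMO": -6.554, "E_LUMO": -1.324}
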