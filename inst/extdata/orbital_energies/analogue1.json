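{"molecule": "Analogue 1", "E_HOMO": -5.914, "E_LUMO": -0.490}
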