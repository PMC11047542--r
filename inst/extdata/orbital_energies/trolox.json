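{"molecule": "Trolox", "E_HOMO": -5.294, "E_LUMO": -0.655}
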