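{"molecule": "RvD1", "E_HOMO": -6.045, "E_LUMO": -0.959}
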