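sample,vp_ml,mw_da,mn_da,iv
Hyaluronic Acid,10.76,1160000,1052000,13.5227
Hyaluronic Acid/H2O2,11.97,217211,131579,4.7605
Hyaluronic Acid/H2O2 + RvD1,10.75,1113000,1031000,13.9877
Hyaluronic Acid/H2O2 + A1,10.71,1126000,1043000,13.9109
Hyaluronic Acid/H2O2 + A2,10.70,1112000,1026000,13.6087
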