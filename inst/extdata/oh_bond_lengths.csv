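molecule,bond,length_a
Trolox,O7-H8,0.9741
Trolox,O31-H32,0.9821
Ascorbic acid,O8-H20,0.9791
Ascorbic acid,O9-H19,0.9797
Ascorbic acid,O12-H13,0.9772
Ascorbic acid,O17-H18,0.9797
RvD1,O19-H20,0.9786
RvD1,O42-H44,0.9821
RvD1,O43-H45,0.9824
RvD1,O56-H58,0.9996
Analogue 1,O22-H23,0.9795
Analogue 1,O25-H27,0.9780
Analogue 1,O29-H30,0.9808
Analogue 1,O60-H62,0.9821
Analogue 2,O20-H21,0.9795
Analogue 2,O26-H27,0.9981
Analogue 2,O43-H44,0.9793
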