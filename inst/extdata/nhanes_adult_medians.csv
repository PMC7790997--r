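chemical,study_median_ng_ml,nhanes_median_ng_ml,printed_ratio
Hexachlorobenzene,0.0635,0.090,
"p,p'-DDE",0.564,1.24,0.5
PCB 66,0.0468,0.0081,5.8
PCB 105,0.0194,0.0064,3.0
PCB 118,0.0788,0.0307,2.6
PCB 153,0.133,0.127,1.0
PCB 156,0.0185,0.0201,0.9
PCB 170,0.0585,0.0395,1.5
PCB 180,0.130,0.1097,1.2
PCB 187,0.0568,0.0278,2.0
PCB 194,0.0397,0.0244,1.6
PCB 206,0.0455,0.0130,3.5
Trans-nonachlor,0.0864,0.0865,1.0
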