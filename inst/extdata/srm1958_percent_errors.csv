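chemical,certified,pe_batch1,pe_batch2,pe_batch3,pe_batch4,pe_batch5
alpha-HCH,0.260,-8,-6,78,-12,5
g-Chlordane,0.412,-35,1,-9,-27,15
Hexachlorobenzene,0.442,-33,-10,-17,-41,20
Mirex,0.384,-25,7,-1,3,-10
"o,p'-DDE",0.450,-14,17,-45,22,23
Oxychlordane isomer,0.226,,34,-56,51,35
"p,p'-DDE",1.25,-29,7,-30,11,0
"p,p'-DDT",0.293,,,-64,-26,-28
PBDE 28,0.462,-27,-6,-32,-2,-2
PBDE 47,0.651,76,163,199,233,38
PBDE 99,0.492,350,301,515,248,169
PBDE 100,0.475,32,47,90,29,47
PBDE 153,0.455,85,,-7,52,55
PBDE 154,0.441,30,,9,-45,50
PBDE 183,0.453,397,4622,,28,89
PCB 18,0.407,-38,-14,2,-23,4
PCB 66,0.414,-35,-16,-55,13,-9
PCB 101,0.409,-37,-25,-23,-8,5
PCB 105,0.419,-43,-28,-35,-33,-2
PCB 118,0.412,-17,-12,-13,-8,6
PCB 138,0.473,9,21,31,2,89
PCB 153,0.457,-35,-41,-18,-34,1
PCB 156,0.418,-36,-20,-34,-30,-2
PCB 157,0.420,-39,-15,-34,-30,-8
PCB 167,0.403,-45,-26,-36,-41,-15
PCB 170,0.422,-40,-10,-16,-17,1
PCB 180,0.459,-29,-30,-13,-5,6
PCB 187,0.411,-37,-25,-18,-25,-6
PCB 194,0.387,-27,-14,-6,-26,6
PCB 195,0.385,-46,-3,168,-32,-7
PCB 206,0.366,-22,-11,-7,-19,12
PCB 209,0.338,-31,-26,26,31,36
Trans-nonachlor,0.469,-34,15,-19,-5,-3
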