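# Synthetic Nav rate-constant table (authored calibration; see package docs).
# Canonical 13-state topology: C1-C5 activation ladder, O6 open,
# I7-I12 inactivated ladder, S13 long-term inactivated (O6-S13 pair
# as published, set 1). k(V) = k0 * exp(k1 * V), V in mV.
# units: per_s
from,to,k0,k1
C1,C2,160000,0.055
C2,C1,2000,-0.05
I7,I8,800000,0.055
I8,I7,400,-0.05
C2,C3,120000,0.055
C3,C2,4000,-0.05
I8,I9,600000,0.055
I9,I8,800,-0.05
C3,C4,80000,0.055
C4,C3,6000,-0.05
I9,I10,400000,0.055
I10,I9,1200,-0.05
C4,C5,40000,0.055
C5,C4,8000,-0.05
I10,I11,200000,0.055
I11,I10,1600,-0.05
C5,O6,150000,0.06
O6,C5,1036.57764,-0.03
I11,I12,750000,0.06
I12,I11,207.315528,-0.03
C1,I7,4,0
I7,C1,350,0
C2,I8,20,0
I8,C2,70,0
C3,I9,100,0
I9,C3,14,0
C4,I10,500,0
I10,C4,2.8,0
C5,I11,2500,0
I11,C5,0.56,0
O6,I12,1450,0
I12,O6,1.7711523,0
O6,S13,400.8,-0.011
S13,O6,0.207,-0.031
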