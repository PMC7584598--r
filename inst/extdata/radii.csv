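name,radius_A
H,1.20
C,1.70
N,1.55
O,1.52
S,1.80
P,1.80
BB,2.30
SC1,2.30
SC2,2.30
SC3,2.30
SC4,2.30
LP,2.30
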