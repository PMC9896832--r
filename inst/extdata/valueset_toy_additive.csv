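domain,level,decrement
constant,,1.0
mo,2,0.04
mo,3,0.07
mo,4,0.16
mo,5,0.27
sc,2,0.04
sc,3,0.07
sc,4,0.14
sc,5,0.20
ua,2,0.03
ua,3,0.05
ua,4,0.11
ua,5,0.18
pd,2,0.05
pd,3,0.08
pd,4,0.18
pd,5,0.30
ad,2,0.04
ad,3,0.07
ad,4,0.15
ad,5,0.25
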