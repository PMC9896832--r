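domain,level,count
mo,1,121
mo,2,111
mo,3,103
mo,4,94
mo,5,27
sc,1,271
sc,2,61
sc,3,62
sc,4,38
sc,5,24
ua,1,112
ua,2,116
ua,3,113
ua,4,68
ua,5,47
pd,1,38
pd,2,140
pd,3,140
pd,4,77
pd,5,61
ad,1,118
ad,2,114
ad,3,138
ad,4,48
ad,5,38
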