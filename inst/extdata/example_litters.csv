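litter_id,mother_id,birth_year,weaning_year,care_duration,litter_size,mother_primiparous
L0001,F0007,1998,2000,2.5,3,true
L0002,F0007,2001,2003,2.5,2,false
L0003,F0012,1999,2000,1.5,2,true
L0004,F0023,1997,1998,1.5,4,true
L0005,F0023,1999,2000,1.5,1,false
L0006,F0023,2002,,lost,2,false
L0007,F0031,2000,2001,1.5,3,unknown
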