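bear_id,year,age,tactic,status,survived,cause_of_death,available_for_hunting,recruits
F0007,2001,6,T25,with_offspring,true,none,false,0
F0007,2002,7,T25,with_offspring,true,none,false,2
F0007,2003,8,T25,solitary,true,none,true,0
F0012,2001,2,T15,solitary,false,hunting,true,
F0019,2001,1,T25,with_mother,true,none,false,
F0019,2002,2,T25,solitary,true,none,true,
F0023,2001,11,T15,solitary,true,none,true,1
F0023,2002,12,T15,with_offspring,false,other,false,0
F0031,2001,4,unknown,solitary,true,none,true,
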