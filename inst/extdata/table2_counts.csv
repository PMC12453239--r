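variable,level,fri,control
sex,Male,10,6
sex,Female,3,7
implant,IMN,9,3
implant,Plate,4,10
fracture_type,Open,4,0
fracture_type,Closed,9,13
nsaid_steroid,Yes,1,0
nsaid_steroid,No,12,13
diabetes,Yes,1,4
diabetes,No,12,9
mrsa_history,Yes,2,0
mrsa_history,No,11,13
tobacco,Yes,4,3
tobacco,No,9,10
alcohol_abuse,Yes,2,0
alcohol_abuse,No,11,13
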