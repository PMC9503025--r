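id,age,sex,height,weight,bmi,general_condition,extraspinal_foci,vertebral_mets,visceral_mets,primary_site,palsy,target_therapy,chemotherapy,hormone_therapy,survival_months,event
ex01,63,male,165.0,58.9,21.63,moderate,one_two,two,removable,tier0,incomplete,1,1,0,4.6,1
ex02,55,female,158.0,57.2,22.91,good,none,one,none,tier5,none,1,1,1,24,0
ex03,71,male,170.0,63.6,22.0,poor,three_plus,three_plus,unremovable,tier1,complete,0,1,0,1.2,1
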