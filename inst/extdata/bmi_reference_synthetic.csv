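# synthetic BMI population reference (illustrative values, not a national table)
sex,age_min,age_max,mean,sd
male,18,44,23.8,3.4
male,45,64,24.2,3.3
male,65,120,23.6,3.2
female,18,44,22.3,3.5
female,45,64,23.1,3.4
female,65,120,23.0,3.3
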