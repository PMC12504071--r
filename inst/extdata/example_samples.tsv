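sample	population
pop1_s01	pop1
pop1_s02	pop1
pop1_s03	pop1
pop2_s01	pop2
pop2_s02	pop2
pop2_s03	pop2
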