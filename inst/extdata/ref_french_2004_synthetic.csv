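sex,age_class,weight
female,0-9,6.100
female,10-19,6.344
female,20-29,6.262
female,30-39,6.891
female,40-49,7.047
female,50-59,6.783
female,60-69,4.620
female,70-79,4.294
female,80+,3.128
male,0-9,6.400
male,10-19,6.656
male,20-29,6.338
male,30-39,6.809
male,40-49,6.853
male,50-59,6.517
male,60-69,4.180
male,70-79,3.306
male,80+,1.472
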