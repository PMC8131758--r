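dataset,class,tp,fp,fn
training,MONO,3561,149,39
training,MONO_MN,1189,43,11
training,BN,3522,97,78
training,BN_MN,1193,77,7
training,POLY,2724,115,76
training,IRREG,3175,155,425
validation,MONO,982,21,18
validation,MONO_MN,148,11,2
validation,BN,986,20,14
validation,BN_MN,147,12,3
validation,POLY,341,19,9
validation,IRREG,430,33,70
testing,MONO,972,19,28
testing,MONO_MN,146,16,4
testing,BN,978,21,22
testing,BN_MN,147,16,3
testing,POLY,333,15,17
testing,IRREG,435,52,65
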