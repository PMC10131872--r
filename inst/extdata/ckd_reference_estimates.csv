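component,parameter,term,estimate,lower,upper
binary,alpha1,intercept,-0.4169,-0.4501,-0.3835
binary,alpha2,diagnosis,-0.03515,-0.0668,-0.0035
binary,alpha3,region,0.1875,0.1533,0.2218
binary,alpha4,time,0.0260,0.0244,0.0275
binary,alpha5,diagnosis_region,-0.1124,-0.1839,-0.0408
binary,alpha6,diagnosis_after_time,-0.0888,-0.0910,-0.0867
binary,alpha7,region_time,-0.0151,-0.0172,-0.0130
binary,alpha8,diagnosis_region_after_time,0.0112,0.0091,0.0133
binary,gamma1,age,0.0116,0.0161,0.0171
binary,gamma2,sex,-0.0816,-0.0962,-0.0671
binary,gamma3,cci,0.3348,0.3257,0.3440
overall_mean,beta1,intercept,11.1894,11.1561,11.2226
overall_mean,beta2,diagnosis,0.0123,-0.0119,0.0366
overall_mean,beta3,region,-0.0356,-0.0611,-0.0101
overall_mean,beta4,time,0.0652,0.0641,0.0664
overall_mean,beta5,diagnosis_region,0.0884,0.0332,0.1435
overall_mean,beta6,diagnosis_after_time,-0.0825,-0.0843,-0.0807
overall_mean,beta7,region_time,0.0178,0.0159,0.0197
overall_mean,beta8,diagnosis_region_after_time,-0.0152,-0.0171,-0.0133
overall_mean,delta1,age,-0.0002,-0.0006,0.0003
overall_mean,delta2,sex,-0.0635,-0.0762,-0.0507
overall_mean,delta3,cci,0.3734,0.3650,0.3818
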