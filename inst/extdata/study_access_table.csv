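subject,group,set,accuracy,t_w_opt,feasible,best,t_on_mean,t_on_sd,t_off_mean,t_off_sd
A1,A,set1,92.5,8,TRUE,TRUE,2.43,0.8,2.57,1.7
A1,A,set2,85.5,5,TRUE,FALSE,2.43,0.8,2.57,1.7
A1,A,set3,83.5,4,TRUE,FALSE,2.43,0.8,2.57,1.7
A2,A,set1,72,8,TRUE,FALSE,2.74,1.1,1.82,0.5
A2,A,set2,69.5,5,TRUE,FALSE,2.74,1.1,1.82,0.5
A2,A,set3,72,4,TRUE,TRUE,2.74,1.1,1.82,0.5
A3,A,set1,93.0,4,TRUE,TRUE,3.3,2,1.8,0.3
A3,A,set2,89.5,4,TRUE,FALSE,3.3,2,1.8,0.3
A3,A,set3,78.5,5,TRUE,FALSE,3.3,2,1.8,0.3
A4,A,set1,67.5,15,FALSE,FALSE,3.14,1.1,2.02,0.6
A4,A,set2,72,8,TRUE,TRUE,3.14,1.1,2.02,0.6
A4,A,set3,54,6,TRUE,FALSE,3.14,1.1,2.02,0.6
B2,B,set1,73,5,TRUE,TRUE,3.24,1.9,2.5,1.3
B2,B,set2,70,5,TRUE,FALSE,3.24,1.9,2.5,1.3
B2,B,set3,66,4,TRUE,FALSE,3.24,1.9,2.5,1.3
B3,B,set1,79.0,5,TRUE,TRUE,2.6,0.9,2.64,1
B3,B,set2,62.0,5,TRUE,FALSE,2.6,0.9,2.64,1
B3,B,set3,58.0,3,TRUE,FALSE,2.6,0.9,2.64,1
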