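subject,group,condition,ss,t_i_mean,t_i_se,t_s_mean,t_s_se
A1,A,attention,86.0,2.48,0.87,19.3,3.7
A1,A,non_attention,85.4,2.08,1.02,18.6,5.8
A2,A,attention,79.1,4.29,1.44,18.8,4
A2,A,non_attention,83.6,2.19,0.62,17.7,1.9
A3,A,attention,80.8,2.06,0.30,16.1,1.5
A3,A,non_attention,86.0,1.69,0.19,12.5,0.8
A4,A,attention,57.9,2.91,0.66,10.7,2.5
A4,A,non_attention,63.1,4.63,1.67,11.4,2.0
B2,B,attention,71.9,2.2,0.60,12.4,1.8
B2,B,non_attention,46.8,5.0,2.14,7.8,2.8
B3,B,attention,69.5,2.0,0.46,11.0,1.3
B3,B,non_attention,63.7,2.6,0.62,11.0,2.5
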