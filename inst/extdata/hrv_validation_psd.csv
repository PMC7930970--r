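subject,band,psd_ref,psd_cecg,error_rate
A,vlf,8.9283,8.9286,0.004
B,vlf,8.0537,8.0543,0.008
C,vlf,8.1603,8.1624,0.026
F,vlf,11.9863,11.986,0.002
G,vlf,15.3784,15.378,0.000
H,vlf,13.2398,13.244,0.028
A,lf,62.607,62.615,0.014
B,lf,54.646,54.645,0.002
C,lf,56.258,56.273,0.027
F,lf,82.874,82.879,0.006
G,lf,105.311,105.247,0.061
H,lf,88.198,88.259,0.070
A,hf,16.102,16.098,0.02
B,hf,14.659,14.657,0.02
C,hf,15.446,15.435,0.08
F,hf,23.857,23.815,0.17
G,hf,29.195,29.141,0.19
H,hf,23.870,23.837,0.14
A,vhf,8.539,8.531,0.09
B,vhf,7.804,7.811,0.10
C,vhf,7.714,7.747,0.43
F,vhf,11.395,11.415,0.17
G,vhf,15.340,15.299,0.27
H,vhf,12.350,12.333,0.14
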