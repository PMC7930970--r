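subject,p_sns,p_acc,p_ppv,n_tp_plus_n_fn
A,100,100,100,163
B,100,100,100,174
C,100,100,100,172
D,92.5,85.4,91.8,133
E,33.1,14.3,20.2,118
F,100,100,100,141
G,100,100,100,122
H,100,100,100,135
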