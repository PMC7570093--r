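response,p_label,r_squared,sd,cv
tgs,<0.0001,0.983,6.22,11.86
k,<0.0001,0.984,0.31,6.42
e,<0.0001,0.94,0.00682,10.61
b,0.0018,0.833,0.04,23.25
tg_prime,<0.0001,0.999,0.61,1.2
tm_prime,<0.0001,0.994,0.69,2.02
ws_prime,0.2143,0.921,0.02,2.94
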