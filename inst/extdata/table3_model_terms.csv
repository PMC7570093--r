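response,term,coefficient
tgs,XF,8.31
tgs,XG,29.98
tgs,XS,58.68
tgs,XP,1295.36
tgs,XA,-885.31
tgs,XM,10.52
tgs,XFXP,-2139.92
tgs,XFXA,1653.18
tgs,XGXP,-2555.95
tgs,XGXA,2109.04
tgs,XGXM,122.3
tgs,XSXP,-3002.49
tgs,XSXA,2526.09
tgs,XSXM,468.11
k,XF,2.9
k,XG,3.76
k,XS,4.48
k,XP,-130.1
k,XA,119.4
k,XM,3.59
k,XFXP,109.55
k,XFXA,-106.31
k,XGXP,72.36
k,XGXA,-67.19
k,XGXM,12.55
k,XSXM,28.65
k,XPXA,119.8
k,XPXM,249.97
k,XAXM,-248.14
e,XF,0.946
e,XG,0.1019
e,XS,0.0617
e,XP,0.0543
e,XA,0.0648
e,XM,-0.0003
e,XFXP,-0.1471
e,XSXM,-0.0719
b,XF,0.1413
b,XG,0.0645
b,XS,0.0956
b,XP,-9.0225
b,XA,3.9767
b,XM,-0.0164
b,XFXP,8.3373
b,XGXP,8.0965
b,XSXP,7.8839
b,XSXM,1.0128
b,XPXM,14.3016
b,XAXM,-9.8217
tg_prime,XF,-55.95
tg_prime,XG,-55.56
tg_prime,XS,-43.16
tg_prime,XP,-2063.09
tg_prime,XA,1103.46
tg_prime,XM,-34.36
tg_prime,XFXG,4.43
tg_prime,XFXS,-1.41
tg_prime,XFXP,2027.37
tg_prime,XFXA,-1249.55
tg_prime,XFXM,-23.35
tg_prime,XGXS,-11.19
tg_prime,XGXP,1899.63
tg_prime,XGXA,-1130.07
tg_prime,XGXM,-22.25
tg_prime,XSXP,1921.26
tg_prime,XSXA,-1169.78
tg_prime,XSXM,-4.93
tg_prime,XPXA,1987.27
tg_prime,XPXM,2819.84
tg_prime,XAXM,-2024.59
tm_prime,XF,-42.92
tm_prime,XG,-42.31
tm_prime,XS,-33.39
tm_prime,XP,-72.78
tm_prime,XA,13.8
tm_prime,XM,-10.8
tm_prime,XFXM,-17.99
tm_prime,XGXM,-21.09
tm_prime,XSXA,-15.8
tm_prime,XPXM,134.61
tm_prime,XAXM,-172.4
ws_prime,XF,0.75
ws_prime,XG,0.78
ws_prime,XS,0.80
ws_prime,XP,51.35
ws_prime,XA,-36.73
ws_prime,XM,0.72
ws_prime,XFXG,0.08
ws_prime,XFXS,0.03
ws_prime,XFXP,-53.72
ws_prime,XFXA,39.01
ws_prime,XFXM,0.05
ws_prime,XGXS,0.02
ws_prime,XGXP,-52.92
ws_prime,XGXA,38.22
ws_prime,XGXM,-0.30
ws_prime,XSXP,-53.85
ws_prime,XSXA,39.16
ws_prime,XSXM,-0.40
ws_prime,XPXA,-19.73
ws_prime,XPXM,-65.01
ws_prime,XAXM,57.76
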