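sample_id,component,concentration_mg_m3,ln_oav,measured_oi
TE-1,T,,3.36,5.4
TE-1,E,,3.54,5.4
TE-2,T,,3.03,4.0
TE-2,E,,2.44,4.0
TE-3,T,,2.67,3.3
TE-3,E,,2.44,3.3
TS-1,T,,1.65,2.7
TS-1,S,,2.04,2.7
TS-2,T,,3.36,4.5
TS-2,S,,2.04,4.5
TS-3,T,,2.34,6.2
TS-3,S,,4.53,6.2
TEM-1,T,,2.34,3.8
TEM-1,E,,3.54,3.8
TEM-1,M,,2.80,3.8
TEM-2,T,,2.34,5.0
TEM-2,E,,2.44,5.0
TEM-2,M,,3.49,5.0
TEM-3,T,,1.65,3.5
TEM-3,E,,1.78,3.5
TEM-3,M,,2.15,3.5
EPS-1,E,,3.54,5.4
EPS-1,P,,2.20,5.4
EPS-1,S,,3.83,5.4
EPS-2,E,,4.24,6.8
EPS-2,P,,2.20,6.8
EPS-2,S,,4.53,6.8
EPS-3,E,,2.82,4.5
EPS-3,P,,2.20,4.5
EPS-3,S,,2.65,4.5
TEMS-1,T,,4.24,4.8
TEMS-1,E,,2.20,4.8
TEMS-1,M,,3.83,4.8
TEMS-1,S,,2.15,4.8
TEMS-2,T,,2.20,4.5
TEMS-2,E,,3.15,4.5
TEMS-2,M,,2.20,4.5
TEMS-2,S,,2.15,4.5
TEMS-3,T,,1.85,3.5
TEMS-3,E,,1.77,3.5
TEMS-3,M,,2.20,3.5
TEMS-3,S,,2.15,3.5
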