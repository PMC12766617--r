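condition,n
AMYLOID,31
DCM,45
Fabry's Disease,11
HCM G+P-,48
HCM,66
hDCM,4
Healthy,197
Acute MI,246
Marfan's Syndrome,7
rDCM,89
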